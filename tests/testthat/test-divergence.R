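test_that("codon partitioning frames on the anchor and drops gapped codons", {
  set.seed(21)
  a <- random_cds(33)  # 99 nt
  aln <- global_align(a, a)
  ca <- codon_align(aln)
  expect_equal(length(ca$codons_a), 33L)
  expect_equal(ca$dropped, 0L)
  expect_null(ca$excluded)

  # one in-frame 3 nt deletion -> exactly one codon dropped
  b <- paste0(substr(a, 1, 45), substr(a, 49, 99))
  ca2 <- codon_align(global_align(a, b))
  expect_equal(ca2$dropped, 1L)
  expect_equal(length(ca2$codons_a), 32L)

  # 1 nt gap: frame unrecoverable
  b3 <- paste0(substr(a, 1, 46), substr(a, 48, 99))
  ca3 <- codon_align(global_align(a, b3))
  expect_equal(ca3$excluded, "frame_break")
})

test_that("site counts match neighbor enumeration over all sense codons", {
  expect_equal(unname(ng_sites("TTT")), c(1 / 3, 8 / 3))
  expect_error(ng_sites("TAA"), "stop")
  expect_error(ng_sites("ANT"), "N")
  for (cd in sense_codons()) {
    expect_equal(ng_sites(cd), oracle_ng_sites(cd), info = cd)
    sn <- sum(ng_sites(cd))
    expect_lte(sn, 3 + 1e-12)
    # s + n = 3 exactly when no neighbor is a stop codon
    nbs <- unlist(lapply(1:3, function(p) vapply(
      setdiff(c("A", "C", "G", "T"), substr(cd, p, p)),
      function(x) { y <- cd; substr(y, p, p) <- x; y }, character(1))))
    has_stop_nb <- any(Biostrings::GENETIC_CODE[nbs] == "*")
    if (has_stop_nb) expect_lt(sn, 3) else expect_equal(sn, 3)
  }
})

test_that("pathway averaging matches enumeration on random codon pairs", {
  expect_equal(ng_substitutions("TTT", "TTC")[c("sd", "nd")],
               list(sd = 1, nd = 0))
  expect_equal(ng_substitutions("TTT", "GTA")[c("sd", "nd")],
               list(sd = 0.5, nd = 1.5))
  for (cd in sample(sense_codons(), 8))
    expect_equal(ng_substitutions(cd, cd)[c("sd", "nd")],
                 list(sd = 0, nd = 0))
  set.seed(23)
  sc <- sense_codons()
  for (i in 1:200) {
    ca <- sample(sc, 1); cb <- sample(sc, 1)
    got <- ng_substitutions(ca, cb)
    want <- oracle_ng_subs(ca, cb)
    expect_equal(c(got$sd, got$nd), unname(want),
                 info = paste(ca, cb))
  }
})

test_that("per-gene Ka/Ks matches a site-by-site brute-force recomputation", {
  set.seed(25)
  sc <- sense_codons()
  a_cod <- sample(sc, 1000, replace = TRUE)
  b_cod <- a_cod
  flip <- sample(1000, 60)
  b_cod[flip] <- sample(sc, 60, replace = TRUE)
  a <- paste(a_cod, collapse = ""); b <- paste(b_cod, collapse = "")
  s <- gene_ka_ks(global_align(a, b))

  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(1000)) {
    sa <- oracle_ng_sites(a_cod[i]); sb <- oracle_ng_sites(b_cod[i])
    S <- S + (sa["s"] + sb["s"]) / 2
    N <- N + (sa["n"] + sb["n"]) / 2
    d <- oracle_ng_subs(a_cod[i], b_cod[i])
    Sd <- Sd + d["sd"]; Nd <- Nd + d["nd"]
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  expect_equal(s$S, unname(S), tolerance = 1e-12)
  expect_equal(s$N, unname(N), tolerance = 1e-12)
  expect_equal(s$Sd, unname(Sd), tolerance = 1e-12)
  expect_equal(s$Nd, unname(Nd), tolerance = 1e-12)
  expect_equal(s$Ks, unname(jc(Sd / S)), tolerance = 1e-12)
  expect_equal(s$Ka, unname(jc(Nd / N)), tolerance = 1e-12)
})

test_that("identical genes give zero distances with undefined omega", {
  set.seed(26)
  a <- random_cds(60)
  s <- gene_ka_ks(global_align(a, a))
  expect_equal(s$Ks, 0)
  expect_equal(s$Ka, 0)
  expect_false(s$omega_defined)
  expect_true(is.na(s$omega))
})

test_that("alignments shorter than 30 codons are excluded", {
  set.seed(27)
  a <- random_cds(30)  # 29 amino acids plus the stop codon
  s <- gene_ka_ks(global_align(a, a))
  expect_equal(s$excluded, "too_short")
  x <- random_cds(31)  # 30 amino acids: first length retained
  s30 <- gene_ka_ks(global_align(x, x))
  expect_true(is.na(s30$excluded))
  expect_equal(s30$codons_compared, 30L)
})

test_that("gene summaries are exactly symmetric in their arguments", {
  set.seed(28)
  sc <- sense_codons()
  a_cod <- sample(sc, 100, replace = TRUE)
  b_cod <- a_cod
  b_cod[sample(100, 10)] <- sample(sc, 10, replace = TRUE)
  a <- paste(a_cod, collapse = ""); b <- paste(b_cod, collapse = "")
  s1 <- gene_ka_ks(global_align(a, b))
  s2 <- gene_ka_ks(global_align(b, a))
  for (col in c("S", "N", "Sd", "Nd", "Ks", "Ka", "snp_count",
                "syn_snp_count"))
    expect_identical(s1[[col]], s2[[col]], info = col)
})

test_that("the Jukes-Cantor correction is increasing and above p", {
  p <- seq(0.001, 0.74, by = 0.01)
  jc <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(jc) > 0))
  expect_true(all(jc >= p))
  # saturation flagged rather than propagated as NaN: a synonymous-site
  # pS of 6/7 (Leu CTT vs CTG family), anchored gapless by Trp flanks
  flank <- paste(rep("TGG", 3), collapse = "")
  sat <- gene_ka_ks(global_align(
    paste0(flank, paste(rep("CTT", 40), collapse = ""), flank),
    paste0(flank, paste(rep("CTG", 40), collapse = ""), flank)))
  expect_true(sat$saturated)
  expect_true(is.na(sat$Ks))
})

test_that("pooling one gene reproduces that gene's statistics", {
  set.seed(29)
  sc <- sense_codons()
  a_cod <- sample(sc, 200, replace = TRUE)
  b_cod <- a_cod
  b_cod[sample(200, 12)] <- sample(sc, 12, replace = TRUE)
  s <- gene_ka_ks(global_align(paste(a_cod, collapse = ""),
                               paste(b_cod, collapse = "")))
  pooled <- pool_divergence(s)
  expect_equal(pooled$ks_concat, s$Ks)
  expect_equal(pooled$ka_concat, s$Ka)
  expect_equal(pooled$snp_total, s$snp_count)
})

test_that("pipeline-estimated pooled Ks recovers the simulated value", {
  cfg <- evolution_config(
    n_genes = 500L, target_ks = 0.005, seed = 11L,
    phage_regions = list(), region_deletions = list(),
    fragmentation_events = 0L, repeat_insertions = 0L,
    relocations = list(), indel_gene_fraction = 0,
    n_scaffolds_b = 1L, outgroup = FALSE)
  sim <- simulate_genomes(cfg)
  map <- reciprocal_best_hits(sim$genome_a, sim$genome_b)
  d <- genome_wide_divergence(map)
  se <- sqrt(d$pS * (1 - d$pS) / d$S)
  expect_lt(abs(d$ks_concat - 0.005), 3 * se)
})

test_that("omega-class recovery: rank order per seed, pooled within 30%", {
  classes <- c(core = 0.2, hypothetical = 1.0, phage = 4.0)
  seeds <- 1:20
  per_seed <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    cfg <- evolution_config(
      n_genes = 600L, target_ks = 0.01, seed = seeds[i],
      phage_regions = list(c(401L, 200L)), hypothetical_fraction = 0.5,
      repeat_gene_fraction = 0,
      omega_by_class = c(core = 0.2, hypothetical = 1.0, phage = 4.0,
                         "repeat" = 1.0, pseudogene = 1.0),
      region_deletions = list(), fragmentation_events = 0L,
      repeat_insertions = 0L, relocations = list(),
      indel_gene_fraction = 0, n_scaffolds_b = 1L, outgroup = FALSE)
    sim <- simulate_genomes(cfg)
    pr <- sim$truth$pairing
    est <- vapply(names(classes), function(cl) {
      loci <- pr$ancestor_locus[pr$category == cl]
      S <- 0; N <- 0; Sd <- 0; Nd <- 0
      for (l in loci) {
        a <- sim$genome_a$cds[[sub("ANC", "GA", l)]]
        b <- sim$genome_b$cds[[sub("ANC", "GB", l)]]
        s <- gene_ka_ks(global_align(a, b, band = 30L))
        if (!is.na(s$excluded)) next
        S <- S + s$S; N <- N + s$N; Sd <- Sd + s$Sd; Nd <- Nd + s$Nd
      }
      (Nd / N) / (Sd / S)
    }, numeric(1))
    expect_equal(order(est), order(classes),
                 info = sprintf("seed %d rank order", seeds[i]))
    per_seed[[i]] <- est
  }
  pooled <- Reduce(`+`, per_seed) / length(seeds)
  for (cl in names(classes))
    expect_lt(abs(pooled[[cl]] - classes[[cl]]) / classes[[cl]], 0.30,
              label = sprintf("pooled omega for class %s", cl))
})

test_that("the synonymous clock dates divergence as Ks% / rate", {
  t1 <- estimate_divergence_time(0.314, clock_model(0.9))
  expect_equal(round(t1$years_raw), 348889)
  expect_equal(t1$years_rounded, 350000)
  expect_equal(estimate_divergence_time(0, clock_model(0.9))$years_raw, 0)
  expect_equal(estimate_divergence_time(0.9, clock_model(0.9))$years_raw,
               1e6)
  expect_error(clock_model(0), "positive")
  expect_error(clock_model(-1), "positive")
})
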