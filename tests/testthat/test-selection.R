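test_that("the divergence screen applies a strict identity threshold", {
  tab <- data.frame(locus_a = c("g1", "g2", "g3"),
                    identity = c(97.9, 98.0, 99.2))
  out <- screen_divergent_genes(tab, screen_config())
  expect_equal(out$locus_a, "g1")        # 97.9 in, exactly 98.0 out
  hi <- data.frame(locus_a = c("g1", "g2"), identity = c(99.0, 99.9))
  expect_equal(nrow(screen_divergent_genes(hi)), 0L)
})

test_that("screen output is order-invariant and deterministically sorted", {
  tab <- data.frame(locus_a = c("g3", "g1", "g2"),
                    identity = c(92.0, 97.0, 92.0))
  o1 <- screen_divergent_genes(tab)
  o2 <- screen_divergent_genes(tab[c(2, 3, 1), ])
  expect_identical(o1, o2)
  expect_equal(o1$locus_a, c("g2", "g3", "g1"))  # identity asc, then tag
})

test_that("positive-selection flags require defined omega above 1", {
  s <- data.frame(locus_a = c("gA", "gB", "gC", "gD"),
                  omega = c(1.59, 0.42, NA, 1.0),
                  omega_defined = c(TRUE, TRUE, FALSE, TRUE))
  fl <- flag_positive_selection(s)
  expect_equal(fl$flagged$locus_a, "gA")          # 0.42 and exactly 1.0 out
  expect_equal(fl$undefined$locus_a, "gC")        # Ks = 0 listed, not flagged
})

test_that("indel annotation reports gap runs with a net-length identity", {
  set.seed(31)
  a <- random_dna(1626)
  b <- paste0(substr(a, 1, 800), random_dna(189), substr(a, 801, 1626))
  ev <- annotate_indels(global_align(a, b))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length, 189L)
  expect_equal(ev$side, "b")  # the 1,815 nt sequence gained 189 bp

  same <- annotate_indels(global_align(substr(a, 1, 300), substr(a, 1, 300)))
  expect_equal(nrow(same), 0L)

  # two gap runs of 9 and 3 on the same side: two events, net +12
  c2 <- paste0(substr(a, 1, 200), random_dna(9),
               substr(a, 201, 400), random_dna(3), substr(a, 401, 600))
  ev2 <- annotate_indels(global_align(substr(a, 1, 600), c2))
  expect_equal(sort(ev2$length), c(3L, 9L))
  expect_equal(unique(ev2$side), "b")
  expect_equal(sum(ev2$length), 612L - 600L)
})

test_that("outgroup polarization counts are conserved site by site", {
  set.seed(32)
  base <- strsplit(random_dna(100), "")[[1]]
  diffs <- sort(sample(100, 25))
  alt <- function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1)
  b <- base
  for (p in diffs) b[p] <- alt(base[p])
  og <- base
  # outgroup: matches a's allele at 18 diverged sites, b's at 4, neither at 3
  match_b <- diffs[19:22]
  third <- diffs[23:25]
  for (p in match_b) og[p] <- b[p]
  for (p in third) og[p] <- alt(base[p])  # may equal b -> recount below
  for (p in third) while (og[p] == b[p] || og[p] == base[p])
    og[p] <- sample(c("A", "C", "G", "T"), 1)
  res <- polarize_with_outgroup(paste(base, collapse = ""),
                                paste(b, collapse = ""),
                                paste(og, collapse = ""))
  expect_equal(res$diverged_sites, 25L)
  expect_equal(res$matches_outgroup_a, 18L)
  expect_equal(res$matches_outgroup_b, 4L)
  expect_equal(res$unpolarizable, 3L)
  expect_equal(res$matches_outgroup_a + res$matches_outgroup_b +
                 res$unpolarizable, res$diverged_sites)
  expect_equal(res$derived_enriched, "b")  # a's alleles look ancestral
})

test_that("degenerate polarization inputs behave as documented", {
  set.seed(33)
  a <- random_cds(40)
  same <- polarize_with_outgroup(a, a, a)
  expect_equal(same$diverged_sites, 0L)

  b <- a
  substr(b, 50, 50) <- if (substr(a, 50, 50) == "A") "C" else "A"
  og <- b
  substr(og, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                c(substr(a, 50, 50), substr(b, 50, 50)))[1]
  three <- polarize_with_outgroup(a, b, og)
  expect_equal(three$diverged_sites, 1L)
  expect_equal(three$unpolarizable, 1L)  # third allele

  no_og <- polarize_with_outgroup(a, b, NULL)
  expect_equal(no_og$diverged_sites, 1L)
  expect_equal(no_og$unpolarizable, 1L)  # outgroup gene missing
})

test_that("most truth-recorded derived alleles are attributed correctly", {
  cfg <- small_sim_config(seed = 34L, n_genes = 80L, target_ks = 0.02,
                          region_deletions = list(), repeat_insertions = 0L,
                          fragmentation_events = 0L, indel_gene_fraction = 0,
                          outgroup = TRUE, outgroup_ks_multiplier = 3)
  sim <- simulate_genomes(cfg)
  ev <- sim$truth$events
  ev <- ev[ev$lineage %in% c("a", "b"), ]
  # drop sites hit more than once across lineages (back-mutation overlap)
  key <- paste(ev$locus, ev$nt_pos)
  ev <- ev[!(key %in% key[duplicated(key)]), ]
  correct <- 0L; total <- 0L
  for (l in unique(ev$locus)) {
    res <- polarize_with_outgroup(
      sim$genome_a$cds[[sub("ANC", "GA", l)]],
      sim$genome_b$cds[[sub("ANC", "GB", l)]],
      sim$outgroup$cds[[sub("ANC", "OG", l)]])
    sites <- res$sites
    for (i in which(ev$locus == l)) {
      row <- sites[sites$pos_a == ev$nt_pos[i], ]
      if (nrow(row) != 1L || is.na(row$allele_og)) next
      total <- total + 1L
      derived_lineage <- if (row$allele_og == row$allele_a) "b"
                         else if (row$allele_og == row$allele_b) "a"
                         else NA_character_
      if (!is.na(derived_lineage) && derived_lineage == ev$lineage[i])
        correct <- correct + 1L
    }
  }
  expect_gt(total, 50L)
  expect_gte(correct / total, 0.8)
})
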