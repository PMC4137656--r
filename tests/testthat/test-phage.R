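# shared fixture: one simulated pair under the default-style conditions,
# small enough for fast reuse across the phage-inventory tests
phage_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_sim_config(
        seed = 41L, n_genes = 80L,
        phage_regions = list(c(11L, 14L), c(41L, 10L), c(61L, 6L)),
        region_deletions = list(c(1L, 8L), c(2L, 4L), c(3L, 0L)),
        fragmentation_events = 1L, repeat_insertions = 2L,
        n_scaffolds_b = 3L)
      sim <- simulate_genomes(cfg)
      map <- reciprocal_best_hits(sim$genome_a, sim$genome_b)
      ev <- detect_fragmentation(map, sim$genome_a, sim$genome_b)
      phage_loci <- sim$genome_a$features$locus_tag[
        sim$genome_a$features$category == "phage"]
      fl <- label_phage_homologs(sim$genome_b, phage_loci, map,
                                 fragments = ev)
      cache <<- list(sim = sim, map = map, events = ev, flags = fl,
                     phage_loci = phage_loci)
    }
    cache
  }
})

test_that("phage flags follow the reference ortholog, repeats stay separate", {
  fx <- phage_fixture()
  truth <- fx$sim$truth
  retained_phage <- setdiff(
    truth$pairing$ancestor_locus[truth$pairing$category == "phage"],
    truth$deleted)
  flagged <- fx$flags$locus[fx$flags$is_phage]
  expect_setequal(flagged, sub("ANC", "GB", retained_phage))
  expect_equal(length(flagged), 8L + 4L + 0L)
  # inserted repeats sit inside phage runs but are never phage-flagged
  ins <- truth$inserted_repeats$locus
  expect_true(all(fx$flags$is_repeat[fx$flags$locus %in% ins]))
  expect_false(any(fx$flags$is_phage[fx$flags$locus %in% ins]))
})

test_that("a contiguous phage run forms a single region with that count", {
  cfg <- small_sim_config(seed = 42L, n_genes = 40L,
                          phage_regions = list(c(6L, 21L)),
                          region_deletions = list(), repeat_insertions = 0L,
                          fragmentation_events = 0L, n_scaffolds_b = 1L,
                          indel_gene_fraction = 0)
  sim <- simulate_genomes(cfg)
  map <- reciprocal_best_hits(sim$genome_a, sim$genome_b)
  fl <- label_phage_homologs(
    sim$genome_b,
    sim$genome_a$features$locus_tag[sim$genome_a$features$category == "phage"],
    map)
  regs <- delineate_regions(sim$genome_b, fl, reference = sim$genome_a)
  expect_equal(length(regs), 1L)
  expect_equal(regs[[1]]$gene_count, 21L)
  expect_equal(length(regs[[1]]$interrupting_loci), 0L)
})

test_that("gap tolerance separates or joins runs as configured", {
  # construct loci flags directly on a hand-built genome: phage run,
  # 5 core genes, phage run -> two regions at tolerance 2
  set.seed(43)
  cats <- c(rep("phage", 4), rep("core", 5), rep("phage", 3))
  g <- genome_from_cds("t", vapply(rep(40, 12), random_cds, character(1)),
                       categories = cats)
  fl <- data.frame(locus = g$features$locus_tag,
                   scaffold_id = g$features$scaffold_id,
                   ref_locus = g$features$locus_tag,
                   is_phage = cats == "phage",
                   is_repeat = FALSE, stringsAsFactors = FALSE)
  regs <- delineate_regions(g, fl, gap_tolerance = 2L)
  expect_equal(length(regs), 2L)
  expect_equal(vapply(regs, `[[`, numeric(1), "gene_count"), c(4, 3))

  # phage run interrupted by 2 repeats -> one region, repeats recorded
  cats2 <- c(rep("phage", 3), rep("repeat", 2), rep("phage", 4))
  g2 <- genome_from_cds("t2", vapply(rep(40, 9), random_cds, character(1)),
                        categories = cats2)
  fl2 <- data.frame(locus = g2$features$locus_tag,
                    scaffold_id = g2$features$scaffold_id,
                    ref_locus = ifelse(cats2 == "phage",
                                       g2$features$locus_tag, NA),
                    is_phage = cats2 == "phage",
                    is_repeat = cats2 == "repeat", stringsAsFactors = FALSE)
  regs2 <- delineate_regions(g2, fl2, gap_tolerance = 2L)
  expect_equal(length(regs2), 1L)
  expect_equal(length(regs2[[1]]$interrupting_loci), 2L)
  expect_equal(regs2[[1]]$gene_count, 7L)
  expect_equal(length(regs2[[1]]$members), 9L)

  # the same run splits when tolerance is below the interruption size
  regs3 <- delineate_regions(g2, fl2, gap_tolerance = 1L)
  expect_equal(length(regs3), 2L)
})

test_that("regions continue across scaffold breaks", {
  fx <- phage_fixture()
  ord <- order_scaffolds_by_reference(fx$sim$genome_b, fx$map,
                                      fx$sim$genome_a)
  regs <- delineate_regions(fx$sim$genome_b, fx$flags, gap_tolerance = 2L,
                            scaffold_order = ord,
                            reference = fx$sim$genome_a)
  expect_equal(length(regs), 2L)  # regions 1 and 2 retained, 3 fully deleted
  counts <- sort(vapply(regs, `[[`, numeric(1), "gene_count"))
  expect_equal(counts, c(4, 8))
  # every phage-flagged locus belongs to exactly one region
  phage_members <- unlist(lapply(regs, function(r)
    setdiff(r$members, r$interrupting_loci)))
  expect_equal(sort(phage_members),
               sort(fx$flags$locus[fx$flags$is_phage]))
  expect_equal(anyDuplicated(phage_members), 0L)
})

test_that("premature stops are located at the exact codon", {
  set.seed(44)
  ref_cds <- random_cds(300)
  mut <- ref_cds
  substr(mut, 148, 150) <- "TAA"  # codon 50
  ref <- genome_from_cds("ref", c(ref_cds, random_cds(60)))
  tgt <- genome_from_cds("tgt", c(mut, random_cds(60)), tag_prefix = "T")
  map <- reciprocal_best_hits(ref, tgt)
  ev <- detect_fragmentation(map, ref, tgt)
  stops <- Filter(function(e) e$cause == "premature_stop", ev)
  expect_equal(length(stops), 1L)
  expect_equal(stops[[1]]$ref_locus, "G_001")
  expect_equal(stops[[1]]$positions$nt_start, 148L)
  expect_equal(stops[[1]]$positions$nt_end, 150L)

  none <- detect_fragmentation(reciprocal_best_hits(ref, ref), ref, ref)
  expect_equal(length(none), 0L)
})

test_that("split annotations merge fragments to one reference gene", {
  set.seed(45)
  ref_cds <- random_cds(1030)
  frag1 <- substr(ref_cds, 1, 2100)        # codons 1-700
  frag2 <- substr(ref_cds, 2128, 3090)     # codons 710-1030
  ref <- genome_from_cds("ref", c(ref_cds, random_cds(80)))
  tgt <- genome_from_cds("tgt", c(frag1, frag2, random_cds(80)),
                         tag_prefix = "T")
  map <- reciprocal_best_hits(ref, tgt)
  ev <- detect_fragmentation(map, ref, tgt)
  splits <- Filter(function(e) e$cause == "split_annotation", ev)
  expect_equal(length(splits), 1L)
  expect_equal(splits[[1]]$ref_locus, "G_001")
  expect_setequal(splits[[1]]$fragments, c("T_001", "T_002"))
})

test_that("short orthologs mid-scaffold are truncations, not edge artifacts", {
  set.seed(46)
  ref_cds <- random_cds(300)
  trunc <- paste0(substr(ref_cds, 1, 717), "TAA")  # first 240 codons
  ref <- genome_from_cds("ref", c(ref_cds, random_cds(70)))
  tgt <- genome_from_cds("tgt", c(trunc, random_cds(70)), tag_prefix = "T",
                         spacer = paste(rep("ACGT", 20), collapse = ""))
  map <- reciprocal_best_hits(ref, tgt)
  ev <- detect_fragmentation(map, ref, tgt)
  truncs <- Filter(function(e) e$cause == "truncation", ev)
  expect_equal(length(truncs), 1L)
  expect_equal(truncs[[1]]$ref_locus, "G_001")
})

test_that("the reduction report classifies regions and counts the census", {
  fx <- phage_fixture()
  red <- reduction_report(fx$sim$genome_a, fx$sim$genome_b, fx$map,
                          events = fx$events)
  expect_equal(nrow(red$regions), 3L)
  expect_equal(red$regions$status, c("reduced", "reduced", "absent"))
  expect_equal(red$regions$retained, c(8L, 4L, 0L))
  expect_equal(red$census, 12L)
  # absent region reports its flanking loci
  ab <- red$regions[red$regions$status == "absent", ]
  expect_false(is.na(ab$flank_prev))
  expect_false(is.na(ab$flank_next))
  # lost span agrees with the truth within one average gene length
  rf <- fx$sim$genome_a$features
  lost_truth <- sub("ANC", "GA", fx$sim$truth$deleted)
  pos <- sort(match(lost_truth, rf$locus_tag))
  runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
  span_truth <- sum(vapply(runs, function(g)
    max(rf$end[g]) - min(rf$start[g]) + 1L, numeric(1)))
  expect_lt(abs(red$lost_span_bp - span_truth),
            mean(rf$end - rf$start + 1))
  expect_setequal(red$lost_loci, lost_truth)
})

test_that("with nothing deleted every region is intact and census full", {
  cfg <- small_sim_config(seed = 47L, n_genes = 50L,
                          phage_regions = list(c(11L, 8L), c(31L, 5L)),
                          region_deletions = list(), repeat_insertions = 0L,
                          fragmentation_events = 0L)
  sim <- simulate_genomes(cfg)
  map <- reciprocal_best_hits(sim$genome_a, sim$genome_b)
  red <- reduction_report(sim$genome_a, sim$genome_b, map)
  expect_true(all(red$regions$status == "intact"))
  expect_equal(red$census, 13L)
})

test_that("the census is invariant to target scaffold order", {
  fx <- phage_fixture()
  g <- fx$sim$genome_b
  perm <- annotated_genome(g$genome_id, rev(g$scaffolds), g$features)
  map2 <- reciprocal_best_hits(fx$sim$genome_a, perm)
  red1 <- reduction_report(fx$sim$genome_a, g, fx$map)
  red2 <- reduction_report(fx$sim$genome_a, perm, map2)
  expect_equal(red2$census, red1$census)
})
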