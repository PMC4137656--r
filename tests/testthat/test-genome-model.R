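test_that("FASTA + GFF3 loads in coordinate order with strand-resolved CDS", {
  fx <- tiny_genome_files()
  g <- load_genome(fx$fasta, fx$gff3, genome_id = "tiny")
  expect_s3_class(g, "annotated_genome")
  expect_equal(g$features$locus_tag, c("g1", "g2", "g3"))
  expect_equal(unname(g$cds["g1"]), "ATGAAATAA")
  expect_equal(unname(g$cds["g3"]), "ATGGGGTAA")  # minus strand resolved
  expect_equal(g$features$category, c("core", "phage", "hypothetical"))
  expect_false(any(g$features$frame_warning))
})

test_that("a feature on an absent scaffold fails naming the locus tag", {
  expect_error(
    annotated_genome("x", c(s1 = "ATGAAATAA"),
                     data.frame(locus_tag = "gX", scaffold_id = "chrX",
                                start = 1, end = 9, strand = "+")),
    "gX.*chrX")
})

test_that("CDS length not a multiple of 3 is kept but flagged", {
  expect_warning(
    g <- annotated_genome("x", c(s1 = "ATGAAATAAC"),
                          data.frame(locus_tag = "g1", scaffold_id = "s1",
                                     start = 1, end = 10, strand = "+")),
    "frame_warning")
  expect_true(g$features$frame_warning)
  expect_equal(nrow(g$features), 1L)
})

test_that("write then load round-trips features and sequences exactly", {
  cfg <- small_sim_config(seed = 5L, n_genes = 20L,
                          phage_regions = list(c(6L, 5L)),
                          region_deletions = list())
  g <- generate_ancestor(cfg)
  d <- tempfile("rt_")
  dir.create(d)
  write_genome(g, file.path(d, "g.fasta"), file.path(d, "g.gff3"))
  g2 <- load_genome(file.path(d, "g.fasta"), file.path(d, "g.gff3"),
                    genome_id = g$genome_id)
  for (col in c("locus_tag", "scaffold_id", "start", "end", "strand",
                "category"))
    expect_equal(g2$features[[col]], g$features[[col]], info = col)
  expect_equal(g2$cds, g$cds)
  expect_equal(g2$scaffolds, g$scaffolds)
})

test_that("genome_summary computes GC, CDS and intergenic means", {
  g <- annotated_genome("gc", c(s1 = "GGCC"),
                        data.frame(locus_tag = "g1", scaffold_id = "s1",
                                   start = 1, end = 3, strand = "+"))
  expect_equal(genome_summary(g)$gc_percent, 100)

  suppressWarnings(
    g2 <- annotated_genome("one", c(s1 = "ATGC"),
                           data.frame(locus_tag = "g1", scaffold_id = "s1",
                                      start = 1, end = 4, strand = "+")))
  s <- genome_summary(g2)
  expect_equal(s$mean_cds_len, 4)
  expect_true(is.na(s$mean_intergenic_len))  # undefined with one feature

  # N excluded from the GC denominator
  g3 <- annotated_genome("n", c(s1 = "GCNNAT"),
                         data.frame(locus_tag = "g1", scaffold_id = "s1",
                                    start = 1, end = 3, strand = "+"))
  expect_equal(genome_summary(g3)$gc_percent, 50)

  expect_error(genome_summary(
    structure(list(genome_id = "e", scaffolds = character(0),
                   features = data.frame(), cds = character(0)),
              class = "annotated_genome")), "empty")
})

test_that("generated fixtures hit the configured GC within one point", {
  g <- generate_ancestor(small_sim_config(seed = 9L, n_genes = 120L,
                                          gc_content = 0.35,
                                          region_deletions = list()))
  expect_lt(abs(genome_summary(g)$gc_percent - 35), 1)
})

test_that("GC percent is invariant under scaffold order permutation", {
  fx <- tiny_genome_files()
  g <- load_genome(fx$fasta, fx$gff3)
  g_perm <- annotated_genome(g$genome_id, rev(g$scaffolds), g$features)
  expect_equal(genome_summary(g_perm)$gc_percent,
               genome_summary(g)$gc_percent)
})

test_that("GenBank flat files parse single-interval CDS and reject joins", {
  gb <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       sA           40 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "     CDS             5..13",
    '                     /locus_tag="gb1"',
    '                     /product="demo protein"',
    '                     /note="category:phage"',
    "     CDS             complement(20..28)",
    '                     /locus_tag="gb2"',
    "ORIGIN",
    paste0("        1 gggg", tolower("ATGAAATAA"), " tttttt",
           tolower(revcomp_chr("ATGCCCTAA")), " tt"),
    "//"), gb)
  g <- load_genome(annotation_path = gb, genome_id = "gb")
  expect_equal(g$features$locus_tag, c("gb1", "gb2"))
  expect_equal(unname(g$cds["gb1"]), "ATGAAATAA")
  expect_equal(unname(g$cds["gb2"]), "ATGCCCTAA")
  expect_equal(g$features$category[1], "phage")

  gb2 <- tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       sB           40 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(1..9,20..28)",
    '                     /locus_tag="gb3"',
    "ORIGIN",
    paste0("        1 ", tolower(paste(rep("acgt", 10), collapse = ""))),
    "//"), gb2)
  expect_error(load_genome(annotation_path = gb2), "join")
})

test_that("locus_range expands consecutive tag intervals", {
  expect_equal(locus_range("WD_0005", "WD_0007"),
               c("WD_0005", "WD_0006", "WD_0007"))
  expect_equal(length(locus_range("WREC_0559", "WREC_0568")), 10L)
  expect_error(locus_range("WD_0007", "WD_0005"), "precedes")
  expect_error(locus_range("WD_0005", "WR_0007"), "prefixes")
})
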