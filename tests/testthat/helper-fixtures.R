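# Small fixture builders shared across test files.

# two-scaffold genome with three CDS, one on the minus strand whose
# genomic slice is the reverse complement of "ATGAAATAA"
tiny_genome_files <- function(dir = tempfile("tiny_")) {
  dir.create(dir)
  s1 <- paste0("GGGG", "ATGAAATAA", "TTTT", "ATGCCCTAA", "GG")
  s2 <- paste0("AA", revcomp_chr("ATGGGGTAA"), "CCCC")
  fa <- file.path(dir, "genome.fasta")
  writeLines(c(">s1", s1, ">s2", s2), fa)
  gff <- file.path(dir, "genome.gff3")
  writeLines(c(
    "##gff-version 3",
    paste("s1", "test", "CDS", 5, 13, ".", "+", "0",
          "ID=g1;locus_tag=g1;product=protein one;category=core",
          sep = "\t"),
    paste("s1", "test", "CDS", 18, 26, ".", "+", "0",
          "ID=g2;locus_tag=g2;product=protein two;category=phage",
          sep = "\t"),
    paste("s2", "test", "CDS", 3, 11, ".", "-", "0",
          "ID=g3;locus_tag=g3;product=protein three",
          sep = "\t")), gff)
  list(fasta = fa, gff3 = gff, s1 = s1, s2 = s2)
}

revcomp_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# an annotated genome built directly from a list of CDS sequences laid
# head-to-tail on one scaffold with fixed 10 bp spacers
genome_from_cds <- function(id, cds, categories = NULL, spacer = "ACGTACGTAC",
                            tag_prefix = "G") {
  n <- length(cds)
  if (is.null(categories)) categories <- rep("core", n)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  parts <- character(0)
  for (i in seq_len(n)) {
    parts <- c(parts, spacer)
    pos <- pos + nchar(spacer)
    starts[i] <- pos + 1L
    ends[i] <- pos + nchar(cds[i])
    parts <- c(parts, cds[i])
    pos <- ends[i]
  }
  feats <- data.frame(locus_tag = sprintf("%s_%03d", tag_prefix, seq_len(n)),
                      scaffold_id = "sc_1", start = starts, end = ends,
                      strand = "+", product = "protein",
                      category = categories, stringsAsFactors = FALSE)
  annotated_genome(id, c(sc_1 = paste(parts, collapse = "")), feats)
}

# fast small simulation presets
small_sim_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_genes = 60L, mean_gene_len = 300, phage_regions = list(c(21L, 12L)),
    region_deletions = list(c(1L, 6L)), fragmentation_events = 1L,
    repeat_insertions = 1L, relocations = list(), n_scaffolds_b = 2L,
    indel_gene_fraction = 0.05, outgroup = FALSE, seed = seed)
  overrides <- list(...)
  args <- defaults
  args[names(overrides)] <- overrides
  do.call(evolution_config, args)
}
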