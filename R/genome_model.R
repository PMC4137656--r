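# Annotated-genome container and I/O plumbing shared by every stage.
#
# Coordinates are 1-based inclusive throughout (the GenBank/GFF3 and
# IRanges convention), on file and in memory.

GENE_CATEGORIES <- c("core", "phage", "repeat", "hypothetical", "pseudogene")

#' Construct an annotated genome
#'
#' The container every pipeline stage consumes: named scaffold sequences
#' plus an ordered table of single-interval CDS features. Strand-resolved
#' CDS sequences (5'->3') are extracted on construction; minus-strand
#' features are reverse-complemented. A CDS whose length is not a multiple
#' of 3 is kept but flagged `frame_warning`.
#'
#' @param genome_id Genome identifier.
#' @param scaffolds Named character vector (or `DNAStringSet`) of scaffold
#'   sequences over \{A,C,G,T,N\}.
#' @param features `data.frame` with columns `locus_tag`, `scaffold_id`,
#'   `start`, `end` (1-based inclusive), `strand` (`+`/`-`); optional
#'   `product` and `category` (one of core, phage, repeat, hypothetical,
#'   pseudogene; missing values become `hypothetical`).
#' @param metadata Optional free-form list.
#' @return An object of class `annotated_genome` with elements `genome_id`,
#'   `scaffolds`, `features` (sorted by scaffold, then start, with a
#'   `frame_warning` column) and `cds` (named character vector of
#'   strand-resolved CDS sequences).
#' @export
annotated_genome <- function(genome_id, scaffolds, features, metadata = list()) {
  if (methods::is(scaffolds, "DNAStringSet"))
    scaffolds <- setNames(as.character(scaffolds), names(scaffolds))
  if (is.null(names(scaffolds)) || anyNA(names(scaffolds)))
    stopf("scaffolds must be named")
  scaffolds <- vapply(scaffolds, check_dna, character(1), what = "scaffold")

  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("locus_tag", "scaffold_id", "start", "end", "strand")
  miss <- setdiff(req, names(features))
  if (length(miss)) stopf("features lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(features$product)) features$product <- "hypothetical protein"
  if (is.null(features$category)) features$category <- "hypothetical"
  features$category[is.na(features$category) | features$category == ""] <-
    "hypothetical"
  bad_cat <- setdiff(unique(features$category), GENE_CATEGORIES)
  if (length(bad_cat))
    stopf("unknown gene category: %s", paste(bad_cat, collapse = ", "))
  if (anyDuplicated(features$locus_tag))
    stopf("duplicated locus tag: %s",
          features$locus_tag[duplicated(features$locus_tag)][1])
  if (!all(features$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  absent <- !(features$scaffold_id %in% names(scaffolds))
  if (any(absent))
    stopf("feature %s references absent scaffold '%s'",
          features$locus_tag[absent][1], features$scaffold_id[absent][1])
  if (any(features$end < features$start))
    stopf("feature %s has end < start",
          features$locus_tag[features$end < features$start][1])
  too_long <- features$end > nchar(scaffolds)[match(features$scaffold_id,
                                                    names(scaffolds))]
  if (any(too_long))
    stopf("feature %s extends past the end of scaffold '%s'",
          features$locus_tag[too_long][1], features$scaffold_id[too_long][1])

  features <- features[order(match(features$scaffold_id, names(scaffolds)),
                             features$start), , drop = FALSE]
  rownames(features) <- NULL

  len <- features$end - features$start + 1L
  features$frame_warning <- (len %% 3L) != 0L
  if (any(features$frame_warning))
    warnf("%d CDS length(s) not a multiple of 3 (flagged frame_warning)",
          sum(features$frame_warning))

  cds <- substring(scaffolds[features$scaffold_id], features$start,
                   features$end)
  minus <- features$strand == "-"
  if (any(minus))
    cds[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(cds[minus])))
  names(cds) <- features$locus_tag

  structure(list(genome_id = genome_id, scaffolds = scaffolds,
                 features = features, cds = cds, metadata = metadata),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d scaffold(s), %s bp, %d CDS\n",
              x$genome_id, length(x$scaffolds),
              format(sum(nchar(x$scaffolds)), big.mark = ","),
              nrow(x$features)))
  invisible(x)
}

#' Load a genome from FASTA plus GFF3 or GenBank annotation
#'
#' @param fasta_path Multi-record nucleotide FASTA of scaffolds. For
#'   GenBank input (which embeds its sequence) this may be `NULL`.
#' @param annotation_path GFF3 or GenBank flat file; the format is detected
#'   from content unless `format` is given. Joined/compound CDS locations
#'   are out of scope and raise an error.
#' @param format `"auto"`, `"gff3"` or `"genbank"`.
#' @param genome_id Identifier; defaults to the annotation file stem.
#' @param category_key GFF3 attribute carrying the gene category
#'   (default `"category"`); a `Note` of the form `category:<x>` and a
#'   GenBank `/note="category:<x>"` are also recognized. Features without
#'   a category load as `hypothetical`.
#' @return An [annotated_genome()].
#' @export
load_genome <- function(fasta_path = NULL, annotation_path, format = "auto",
                        genome_id = NULL, category_key = "category") {
  format <- match.arg(format, c("auto", "gff3", "genbank"))
  if (format == "auto") {
    first <- readLines(annotation_path, n = 1L)
    format <- if (grepl("^LOCUS", first)) "genbank" else "gff3"
  }
  if (is.null(genome_id))
    genome_id <- sub("\\.[^.]*$", "", basename(annotation_path))

  if (format == "genbank") {
    gb <- read_genbank(annotation_path)
    scaffolds <- gb$scaffolds
    features <- gb$features
    if (!is.null(fasta_path)) {
      scaffolds <- setNames(as.character(Biostrings::readDNAStringSet(fasta_path)),
                            NULL)
      names(scaffolds) <- names(Biostrings::readDNAStringSet(fasta_path))
    }
  } else {
    if (is.null(fasta_path)) stopf("GFF3 annotation requires a FASTA file")
    ss <- Biostrings::readDNAStringSet(fasta_path)
    names(ss) <- sub("\\s.*$", "", names(ss))
    scaffolds <- setNames(as.character(ss), names(ss))
    features <- read_gff3_cds(annotation_path, category_key)
  }
  annotated_genome(genome_id, scaffolds, features)
}

read_gff3_cds <- function(path, category_key = "category") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (length(gr) == 0L) stopf("no CDS features in %s", path)
  mc <- S4Vectors::mcols(gr)
  tag <- if ("locus_tag" %in% names(mc)) as.character(mc$locus_tag)
         else as.character(mc$ID)
  if (anyNA(tag)) stopf("CDS feature without locus_tag/ID in %s", path)
  dup <- duplicated(tag) | duplicated(tag, fromLast = TRUE)
  if (any(dup))
    stopf("joined/compound CDS locations are out of scope (locus %s)",
          tag[dup][1])
  category <- rep(NA_character_, length(gr))
  if (category_key %in% names(mc))
    category <- as.character(mc[[category_key]])
  if ("Note" %in% names(mc)) {
    notes <- vapply(mc$Note, function(n) {
      hit <- grep("^category:", n, value = TRUE)
      if (length(hit)) sub("^category:", "", hit[1]) else NA_character_
    }, character(1))
    category <- ifelse(is.na(category), notes, category)
  }
  product <- if ("product" %in% names(mc)) as.character(mc$product)
             else NA_character_
  data.frame(
    locus_tag = tag,
    scaffold_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", "-", "+"),
    product = ifelse(is.na(product), "hypothetical protein", product),
    category = category,
    stringsAsFactors = FALSE
  )
}

# Minimal GenBank flat-file reader: LOCUS/FEATURES/ORIGIN records with
# single-interval CDS only (join/order locations are an error). No installed
# R package parses GenBank flat files, hence this purpose-built reader.
read_genbank <- function(path) {
  lines <- readLines(path)
  rec_starts <- grep("^LOCUS", lines)
  if (!length(rec_starts)) stopf("no LOCUS record in %s", path)
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  scaffolds <- character(0)
  feats <- list()
  for (r in seq_along(rec_starts)) {
    chunk <- lines[rec_starts[r]:rec_ends[r]]
    sid <- strsplit(trimws(chunk[1]), "\\s+")[[1]][2]
    ori <- grep("^ORIGIN", chunk)
    if (!length(ori)) stopf("record %s has no ORIGIN section", sid)
    seq_lines <- chunk[(ori + 1):length(chunk)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seqtxt <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
    scaffolds[sid] <- seqtxt
    fstart <- grep("^FEATURES", chunk)
    if (!length(fstart)) next
    fl <- chunk[(fstart + 1):(ori - 1)]
    is_new <- grepl("^ {5}\\S", fl)
    idx <- cumsum(is_new)
    for (g in split(fl, idx)) {
      key <- strsplit(trimws(g[1]), "\\s+")[[1]]
      if (key[1] != "CDS") next
      loc <- paste0(key[2], paste(trimws(g[-1][!grepl("^\\s*/", trimws(g[-1]))
                                              & !grepl("/", g[-1])]),
                                  collapse = ""))
      loc <- gsub("\\s", "", sub("/.*$", "", loc))
      if (grepl("join|order", loc))
        stopf("joined/compound CDS locations are out of scope (%s)", loc)
      strand <- if (grepl("^complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      if (length(nums) != 2L) stopf("unparseable CDS location '%s'", loc)
      qual_txt <- paste(trimws(g[-1]), collapse = " ")
      getq <- function(q) {
        m <- regmatches(qual_txt,
                        regexec(sprintf('/%s="([^"]*)"', q), qual_txt))[[1]]
        if (length(m) == 2L) m[2] else NA_character_
      }
      note <- getq("note")
      category <- if (!is.na(note) && grepl("category:", note))
        sub(".*category:([a-z]+).*", "\\1", note) else NA_character_
      feats[[length(feats) + 1L]] <- data.frame(
        locus_tag = getq("locus_tag"), scaffold_id = sid,
        start = nums[1], end = nums[2], strand = strand,
        product = getq("product") %||% NA_character_,
        category = category, stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats)
  features$product[is.na(features$product)] <- "hypothetical protein"
  list(scaffolds = scaffolds, features = features)
}

#' Write a genome as FASTA + GFF3
#'
#' Emits the scaffolds as multi-record FASTA and the CDS features as GFF3
#' with `locus_tag`, `product` and `category` attributes, such that
#' [load_genome()] round-trips the feature list exactly.
#'
#' @param g An [annotated_genome()].
#' @param fasta_path,gff3_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(g, fasta_path, gff3_path) {
  ss <- Biostrings::DNAStringSet(g$scaffolds)
  Biostrings::writeXStringSet(ss, fasta_path)
  f <- g$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$scaffold_id,
    ranges = IRanges::IRanges(start = f$start, end = f$end),
    strand = f$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "orthodiverge"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- f$locus_tag
  S4Vectors::mcols(gr)$locus_tag <- f$locus_tag
  S4Vectors::mcols(gr)$product <- f$product
  S4Vectors::mcols(gr)$category <- f$category
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(c(fasta = fasta_path, gff3 = gff3_path))
}

#' Genome summary statistics
#'
#' @param g An [annotated_genome()].
#' @return One-row `data.frame`: `genome_id`, `size_bp`, `n_cds`,
#'   `mean_cds_len`, `mean_intergenic_len` (NA when fewer than two features
#'   share a scaffold; negative gaps from overlapping CDS count as 0) and
#'   `gc_percent` (G+C over A+C+G+T, N excluded from the denominator).
#' @export
genome_summary <- function(g) {
  if (!inherits(g, "annotated_genome")) stopf("not an annotated_genome")
  if (length(g$scaffolds) == 0L || sum(nchar(g$scaffolds)) == 0L)
    stopf("empty genome")
  lf <- Biostrings::letterFrequency(Biostrings::DNAStringSet(g$scaffolds),
                                    letters = c("A", "C", "G", "T"))
  counts <- colSums(lf)
  acgt <- sum(counts)
  gc <- if (acgt > 0) 100 * sum(counts[c("G", "C")]) / acgt else NA_real_
  f <- g$features
  gaps <- numeric(0)
  for (sid in unique(f$scaffold_id)) {
    fs <- f[f$scaffold_id == sid, , drop = FALSE]
    if (nrow(fs) >= 2L)
      gaps <- c(gaps, pmax(0L, fs$start[-1] - fs$end[-nrow(fs)] - 1L))
  }
  data.frame(
    genome_id = g$genome_id,
    size_bp = sum(nchar(g$scaffolds)),
    n_cds = nrow(f),
    mean_cds_len = if (nrow(f)) mean(f$end - f$start + 1) else NA_real_,
    mean_intergenic_len = if (length(gaps)) mean(gaps) else NA_real_,
    gc_percent = gc,
    stringsAsFactors = FALSE
  )
}
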