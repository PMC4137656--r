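#' @useDynLib orthodiverge, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median rnorm rpois runif setNames
#' @importFrom utils head tail write.table read.delim
NULL

# let data.table's [ dispatch work inside this package
.datatable.aware <- TRUE

# Round a percentage to 1 decimal for reporting (the package-wide convention).
pct1 <- function(x) round(x, 1)

# Two-significant-figure rounding used for divergence-time reporting.
signif2 <- function(x) signif(x, 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Validate a nucleotide string over {A,C,G,T,N}; returns the uppercased string.
check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stopf("%s must be a single non-empty character string", what)
  x <- toupper(x)
  if (grepl("[^ACGTN]", x))
    stopf("%s contains characters outside {A,C,G,T,N}", what)
  x
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a nucleotide string into its codon triplets (length must be %% 3 == 0).
split_codons <- function(x) {
  n <- nchar(x)
  if (n %% 3L != 0L) stopf("sequence length %d is not a multiple of 3", n)
  substring(x, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Expand a consecutive locus-tag interval
#'
#' Locus tags in bacterial annotations carry a shared prefix and a
#' zero-padded ordinal (e.g. `WD_0276`), with consecutive numbering
#' reflecting gene order. `locus_range()` expands the closed interval
#' between two such tags into the full vector of tags, which is how
#' published prophage and accessory regions are usually specified
#' (e.g. the 21-gene interval `WD_0276`--`WD_0296`).
#'
#' @param from,to First and last locus tag of the interval (same prefix,
#'   `to`'s ordinal not smaller than `from`'s).
#' @return Character vector of locus tags, in order, including both ends.
#' @examples
#' locus_range("WD_0276", "WD_0296")
#' @export
locus_range <- function(from, to) {
  parse_tag <- function(tag) {
    m <- regmatches(tag, regexec("^(.*?)([0-9]+)$", tag))[[1]]
    if (length(m) != 3L) stopf("locus tag '%s' has no trailing ordinal", tag)
    list(prefix = m[2], num = as.integer(m[3]), width = nchar(m[3]))
  }
  a <- parse_tag(from); b <- parse_tag(to)
  if (a$prefix != b$prefix)
    stopf("locus tags '%s' and '%s' have different prefixes", from, to)
  if (b$num < a$num) stopf("'%s' precedes '%s'", to, from)
  sprintf(paste0(a$prefix, "%0", a$width, "d"), seq(a$num, b$num))
}
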