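# Codon-level divergence: codon partitioning of pairwise alignments,
# Nei-Gojobori counting with Jukes-Cantor correction per gene and pooled
# ("concatenated") across the ortholog map, and synonymous-clock dating.

#' Partition a pairwise alignment into codon columns
#'
#' Codons are framed on the anchored sequence's ungapped coordinates. Any
#' codon whose three columns contain an alignment gap, or are interrupted
#' by an insertion in the other sequence, is dropped and counted. Gap runs
#' whose length is not a multiple of 3, or ungapped sequence lengths not
#' multiples of 3, make the frame unrecoverable: the gene is excluded with
#' reason `frame_break`.
#'
#' @param aln A `pairwise_alignment` (see [global_align()]).
#' @param anchor Which side defines the reading frame, `"a"` or `"b"`.
#' @return List with `codons_a`, `codons_b` (equal-length codon vectors),
#'   `dropped` (codons lost to gaps), and `excluded` (`NULL`, or
#'   `"frame_break"` with empty codon vectors).
#' @export
codon_align <- function(aln, anchor = c("a", "b")) {
  anchor <- match.arg(anchor)
  # gapless fast path (the overwhelming case between close genomes)
  if (!grepl("-", aln$aligned_a, fixed = TRUE) &&
      !grepl("-", aln$aligned_b, fixed = TRUE)) {
    if (nchar(aln$aligned_a) %% 3L != 0L)
      return(list(codons_a = character(0), codons_b = character(0),
                  dropped = 0L, excluded = "frame_break"))
    return(list(codons_a = split_codons(aln$aligned_a),
                codons_b = split_codons(aln$aligned_b),
                dropped = 0L, excluded = NULL))
  }
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  if (anchor == "b") { tmp <- ca; ca <- cb; cb <- tmp }
  bad_frame <- function(x) {
    r <- rle(x == "-")
    any(r$lengths[r$values] %% 3L != 0L) || sum(x != "-") %% 3L != 0L
  }
  excluded_result <- list(codons_a = character(0), codons_b = character(0),
                          dropped = 0L, excluded = "frame_break")
  if (bad_frame(ca) || bad_frame(cb)) return(excluded_result)

  anchor_pos <- cumsum(ca != "-")          # anchor ungapped position per column
  codon_id <- ifelse(ca != "-", (anchor_pos - 1L) %/% 3L + 1L, NA_integer_)
  n_codons <- max(codon_id, na.rm = TRUE)
  cols_by_codon <- split(which(!is.na(codon_id)), codon_id[!is.na(codon_id)])
  keep_a <- keep_b <- character(0)
  dropped <- 0L
  for (cols in cols_by_codon) {
    contiguous <- length(cols) == 3L && cols[3] - cols[1] == 2L
    if (!contiguous || any(cb[cols] == "-")) { dropped <- dropped + 1L; next }
    keep_a <- c(keep_a, paste(ca[cols], collapse = ""))
    keep_b <- c(keep_b, paste(cb[cols], collapse = ""))
  }
  out <- list(codons_a = keep_a, codons_b = keep_b, dropped = dropped,
              excluded = NULL)
  if (anchor == "b") names(out)[1:2] <- c("codons_b", "codons_a")
  out[c("codons_a", "codons_b", "dropped", "excluded")]
}

# Empty / excluded substitution-summary row.
.empty_summary <- function(locus_a, locus_b, excluded) {
  data.frame(locus_a = locus_a %||% NA_character_,
             locus_b = locus_b %||% NA_character_,
             codons_compared = 0L, dropped_codons = 0L, stop_codons = 0L,
             S = NA_real_, N = NA_real_, Sd = NA_real_, Nd = NA_real_,
             pS = NA_real_, pN = NA_real_, Ks = NA_real_, Ka = NA_real_,
             omega = NA_real_, omega_defined = FALSE,
             snp_count = NA_integer_, syn_snp_count = NA_real_,
             blocked_pairs = 0L, saturated = FALSE,
             excluded = excluded, stringsAsFactors = FALSE)
}

#' Per-gene Ka/Ks by Nei-Gojobori counting with Jukes-Cantor correction
#'
#' Sites `S`, `N` are averaged over the two sequences; substitution counts
#' `Sd`, `Nd` are pathway-averaged ([ng_substitutions()]); `Ks`/`Ka` apply
#' the Jukes-Cantor correction `-(3/4) log(1 - 4p/3)` to `pS = Sd/S` and
#' `pN = Nd/N`. `omega = Ka/Ks` is carried as `NA` with
#' `omega_defined = FALSE` when `Ks` is 0 or undefined, never as a number.
#' Alignments with fewer than `min_codons` comparable codons are excluded
#' (`too_short`); codons containing `N` or a stop codon are dropped and
#' counted in `stop_codons`/`dropped_codons`; `pS >= 0.75` flags
#' saturation.
#'
#' Integer SNP counts: `snp_count` is the number of differing aligned
#' positions within compared codons; a SNP counts as synonymous when its
#' pathway-averaged synonymous weight exceeds 1/2 (exact ties count 0.5).
#'
#' @param aln A `pairwise_alignment`.
#' @param anchor Frame anchor passed to [codon_align()].
#' @param min_codons Minimum comparable codons (default 30, i.e. 30 amino
#'   acids).
#' @return One-row `data.frame` (a substitution summary).
#' @export
gene_ka_ks <- function(aln, anchor = "a", min_codons = 30L) {
  ca <- codon_align(aln, anchor)
  if (!is.null(ca$excluded))
    return(.empty_summary(aln$locus_a, aln$locus_b, ca$excluded))
  has_n <- grepl("N", ca$codons_a) | grepl("N", ca$codons_b)
  a <- ca$codons_a[!has_n]; b <- ca$codons_b[!has_n]
  ia <- match(a, CODONS); ib <- match(b, CODONS)
  is_stop <- IS_STOP[ia] | IS_STOP[ib]
  n_stop <- sum(is_stop)
  ia <- ia[!is_stop]; ib <- ib[!is_stop]
  ncod <- length(ia)
  if (ncod < min_codons) {
    out <- .empty_summary(aln$locus_a, aln$locus_b, "too_short")
    out$codons_compared <- ncod
    out$dropped_codons <- ca$dropped + sum(has_n)
    out$stop_codons <- n_stop
    return(out)
  }
  S <- (sum(S_SITES[ia]) + sum(S_SITES[ib])) / 2
  N <- (sum(N_SITES[ia]) + sum(N_SITES[ib])) / 2
  Sd <- sum(SD_MAT[cbind(ia, ib)])
  Nd <- sum(ND_MAT[cbind(ia, ib)])
  snp <- sum(NDIFF_MAT[cbind(ia, ib)])
  syn_snp <- 0
  for (pos in 1:3) {
    w <- SYNW_ARR[cbind(ia, ib, pos)]
    w <- w[!is.na(w)]
    syn_snp <- syn_snp + sum(w > 0.5) + 0.5 * sum(w == 0.5)
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  saturated <- !is.na(pS) && pS >= 0.75
  Ks <- jc(pS); Ka <- jc(pN)
  omega_defined <- !is.na(Ks) && Ks > 0 && !is.na(Ka)
  data.frame(locus_a = aln$locus_a %||% NA_character_,
             locus_b = aln$locus_b %||% NA_character_,
             codons_compared = ncod,
             dropped_codons = ca$dropped + sum(has_n),
             stop_codons = n_stop,
             S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka,
             omega = if (omega_defined) Ka / Ks else NA_real_,
             omega_defined = omega_defined,
             snp_count = as.integer(snp), syn_snp_count = syn_snp,
             blocked_pairs = sum(BLOCKED_MAT[cbind(ia, ib)]),
             saturated = saturated,
             excluded = NA_character_, stringsAsFactors = FALSE)
}

#' Pool per-gene substitution summaries into concatenated statistics
#'
#' Pools `Sd`, `Nd`, `S`, `N` across genes, then applies one Jukes-Cantor
#' correction (the "concatenated alignment" convention), and aggregates
#' integer SNP totals and the per-gene omega mean.
#'
#' @param summaries `data.frame` of per-gene rows as from [gene_ka_ks()];
#'   rows with a non-`NA` `excluded` reason are ignored for the pooled
#'   statistics but reported in the unfiltered SNP totals when countable.
#' @return List of class `divergence_report`: `ks_concat`, `ka_concat`
#'   (and `ks_percent`, `ka_percent`), `omega_concat`, `snp_total`,
#'   `syn_snp_total`, `syn_snp_percent` (one decimal), `mean_gene_omega`
#'   (unweighted over genes with defined omega),
#'   `mean_gene_omega_weighted` (codon-weighted), `n_genes`,
#'   `snp_total_unfiltered`, `syn_snp_total_unfiltered`, and `per_gene`.
#' @export
pool_divergence <- function(summaries) {
  if (!is.data.frame(summaries) || nrow(summaries) == 0L)
    stopf("no substitution summaries supplied")
  if (is.null(summaries$excluded)) summaries$excluded <- NA_character_
  ok <- is.na(summaries$excluded) & !summaries$saturated %in% TRUE
  if (!any(ok)) stopf("no eligible genes after filtering")
  el <- summaries[ok, , drop = FALSE]
  S <- sum(el$S); N <- sum(el$N); Sd <- sum(el$Sd); Nd <- sum(el$Nd)
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(pS); ka <- jc(pN)
  def <- el$omega_defined %in% TRUE
  cnt <- !is.na(summaries$snp_count)
  structure(list(
    n_genes = nrow(el),
    S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
    ks_concat = ks, ka_concat = ka,
    ks_percent = 100 * ks, ka_percent = 100 * ka,
    omega_concat = if (!is.na(ks) && ks > 0) ka / ks else NA_real_,
    snp_total = sum(el$snp_count),
    syn_snp_total = sum(el$syn_snp_count),
    syn_snp_percent = pct1(100 * sum(el$syn_snp_count) / sum(el$snp_count)),
    mean_gene_omega = mean(el$omega[def]),
    mean_gene_omega_weighted =
      sum(el$omega[def] * el$codons_compared[def]) /
      sum(el$codons_compared[def]),
    snp_total_unfiltered = sum(summaries$snp_count[cnt]),
    syn_snp_total_unfiltered = sum(summaries$syn_snp_count[cnt]),
    per_gene = summaries
  ), class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<divergence_report> %d genes pooled\n",
    "  Ks (concat, JC) %.4f%%   Ka %.4f%%   Ka/Ks %.3f\n",
    "  SNPs %d (synonymous %s = %.1f%%)   mean per-gene Ka/Ks %.3f\n"),
    x$n_genes, x$ks_percent, x$ka_percent, x$omega_concat,
    x$snp_total, format(x$syn_snp_total), x$syn_snp_percent,
    x$mean_gene_omega))
  invisible(x)
}

#' Genome-wide divergence over an ortholog map
#'
#' Computes [gene_ka_ks()] for every ortholog pair (using the alignments
#' stored in the map) and pools them with [pool_divergence()].
#'
#' @param map An `ortholog_map` from [reciprocal_best_hits()].
#' @param min_codons Per-gene minimum comparable codons (default 30).
#' @param anchor Frame anchor, `"a"` (default) or `"b"`.
#' @return A `divergence_report` (see [pool_divergence()]).
#' @export
genome_wide_divergence <- function(map, min_codons = 30L, anchor = "a") {
  if (!inherits(map, "ortholog_map")) stopf("not an ortholog_map")
  if (nrow(map$pairs) == 0L) stopf("ortholog map has no pairs")
  rows <- lapply(seq_len(nrow(map$pairs)), function(i) {
    p <- map$pairs[i, ]
    aln <- structure(list(locus_a = p$locus_a, locus_b = p$locus_b,
                          aligned_a = p$aligned_a, aligned_b = p$aligned_b,
                          score = p$score, identity_pct = p$identity,
                          indel_events = gap_events(p$aligned_a, p$aligned_b)),
                     class = "pairwise_alignment")
    gene_ka_ks(aln, anchor = anchor, min_codons = min_codons)
  })
  pool_divergence(do.call(rbind, rows))
}

#' Synonymous molecular-clock model
#'
#' @param rate_percent_per_myr Synonymous substitution rate in percent per
#'   million years (default 0.9, the established endosymbiont rate used
#'   for *Wolbachia*).
#' @return List of class `clock_model`.
#' @export
clock_model <- function(rate_percent_per_myr = 0.9) {
  if (!is.numeric(rate_percent_per_myr) || rate_percent_per_myr <= 0)
    stopf("clock rate must be positive")
  structure(list(rate_percent_per_myr = rate_percent_per_myr),
            class = "clock_model")
}

#' Date a divergence from synonymous distance
#'
#' `T = Ks% / rate * 1e6` years, reported raw and rounded to two
#' significant figures (the reporting convention for such estimates).
#'
#' @param ks_percent Genome-wide synonymous divergence, in percent.
#' @param clock A [clock_model()].
#' @return List with `years_raw` and `years_rounded`.
#' @examples
#' estimate_divergence_time(0.314, clock_model(0.9))
#' @export
estimate_divergence_time <- function(ks_percent, clock = clock_model()) {
  if (!inherits(clock, "clock_model")) stopf("not a clock_model")
  if (!is.numeric(ks_percent) || ks_percent < 0)
    stopf("ks_percent must be non-negative")
  raw <- ks_percent / clock$rate_percent_per_myr * 1e6
  list(years_raw = raw, years_rounded = signif2(raw))
}
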