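# Threshold screens for divergent and positively selected ortholog pairs,
# indel annotation, and outgroup polarization of derived alleles.

#' Screen thresholds
#'
#' @param identity_threshold Percent identity below which a pair is
#'   reported as divergent (default 98, strict less-than).
#' @param omega_threshold Ka/Ks above which a gene is flagged as a
#'   positive-selection candidate (default 1, strict greater-than).
#' @return List of class `screen_config`.
#' @export
screen_config <- function(identity_threshold = 98, omega_threshold = 1) {
  if (identity_threshold <= 0 || omega_threshold <= 0)
    stopf("thresholds must be positive")
  structure(list(identity_threshold = identity_threshold,
                 omega_threshold = omega_threshold),
            class = "screen_config")
}

#' Divergent-gene screen
#'
#' Reports ortholog pairs whose percent identity falls strictly below the
#' threshold, with lengths, SNP counts, omega and indel annotations --
#' the classic divergent-gene table of a close-pair genome comparison.
#' Output is deterministically sorted by identity ascending, then locus
#' tag.
#'
#' @param x An `ortholog_map` (alignments and substitution summaries are
#'   computed as needed), or a plain `data.frame` already carrying an
#'   `identity` column (plus whatever descriptive columns it has), e.g. a
#'   published divergent-gene table.
#' @param cfg A [screen_config()].
#' @param summaries Optional precomputed per-gene summaries (as from
#'   [gene_ka_ks()]) when `x` is an `ortholog_map`.
#' @return `data.frame` of screened rows.
#' @export
screen_divergent_genes <- function(x, cfg = screen_config(),
                                   summaries = NULL) {
  UseMethod("screen_divergent_genes")
}

#' @export
screen_divergent_genes.data.frame <- function(x, cfg = screen_config(),
                                              summaries = NULL) {
  if (is.null(x$identity)) stopf("table lacks an 'identity' column")
  out <- x[x$identity < cfg$identity_threshold, , drop = FALSE]
  key <- if (!is.null(out$locus_a)) out$locus_a else rownames(out)
  out <- out[order(out$identity, key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
screen_divergent_genes.ortholog_map <- function(x, cfg = screen_config(),
                                                summaries = NULL) {
  p <- x$pairs
  if (nrow(p) == 0L)
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      identity = numeric(0)))
  if (is.null(summaries)) summaries <- genome_wide_divergence(x)$per_gene
  rows <- list()
  for (i in which(p$identity < cfg$identity_threshold)) {
    aln <- structure(list(locus_a = p$locus_a[i], locus_b = p$locus_b[i],
                          aligned_a = p$aligned_a[i],
                          aligned_b = p$aligned_b[i], score = p$score[i],
                          identity_pct = p$identity[i],
                          indel_events = gap_events(p$aligned_a[i],
                                                    p$aligned_b[i])),
                     class = "pairwise_alignment")
    ind <- annotate_indels(aln)
    s <- summaries[summaries$locus_a == p$locus_a[i], , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      locus_a = p$locus_a[i], locus_b = p$locus_b[i],
      identity = p$identity[i], len_a = p$len_a[i], len_b = p$len_b[i],
      snp_count = if (nrow(s)) s$snp_count else NA_integer_,
      nonsyn_snp_count = if (nrow(s)) s$snp_count - s$syn_snp_count
                         else NA_real_,
      omega = if (nrow(s)) s$omega else NA_real_,
      omega_defined = if (nrow(s)) s$omega_defined else FALSE,
      indel_note = if (nrow(ind)) paste(
        sprintf("%d bp %s", ind$length,
                ifelse(ind$side == "a", "deletion", "insertion")),
        collapse = ", ") else "",
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(locus_a = character(0), locus_b = character(0),
               identity = numeric(0))
  out <- out[order(out$identity, out$locus_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag positive-selection candidates
#'
#' Genes whose Ka/Ks is defined and strictly exceeds the threshold are
#' flagged; genes with undefined omega (Ks = 0, shown as "-" in published
#' tables) are never flagged and are listed separately.
#'
#' @param summaries `data.frame` with an `omega` column (`NA` = undefined;
#'   an `omega_defined` logical column is honored when present) and a
#'   locus identifier column (`locus_a`, `locus_b` or `locus`).
#' @param cfg A [screen_config()].
#' @return List with `flagged` (rows with omega > threshold) and
#'   `undefined` (rows with undefined omega).
#' @export
flag_positive_selection <- function(summaries, cfg = screen_config()) {
  if (is.null(summaries$omega)) stopf("summaries lack an 'omega' column")
  defined <- if (!is.null(summaries$omega_defined)) summaries$omega_defined
             else !is.na(summaries$omega)
  flagged <- summaries[defined & !is.na(summaries$omega) &
                         summaries$omega > cfg$omega_threshold, ,
                       drop = FALSE]
  undefined <- summaries[!defined | is.na(summaries$omega), , drop = FALSE]
  rownames(flagged) <- rownames(undefined) <- NULL
  list(flagged = flagged, undefined = undefined)
}

#' Indel events of an alignment
#'
#' Maximal gap runs, reported as (side gaining sequence, length, position
#' in ungapped coordinates of the other sequence). Satisfies the net-length
#' identity: sum of a-side insertions minus sum of b-side insertions equals
#' `len_a - len_b`.
#'
#' @param aln A `pairwise_alignment`.
#' @return `data.frame` with columns `side`, `position`, `length`.
#' @export
annotate_indels <- function(aln) {
  if (!inherits(aln, "pairwise_alignment")) stopf("not a pairwise_alignment")
  ev <- aln$indel_events
  len_a <- sum(strsplit(aln$aligned_a, "")[[1]] != "-")
  len_b <- sum(strsplit(aln$aligned_b, "")[[1]] != "-")
  net <- sum(ev$length[ev$side == "a"]) - sum(ev$length[ev$side == "b"])
  stopifnot(net == len_a - len_b)
  ev
}

#' Polarize diverged sites with an outgroup
#'
#' A three-way comparison built by aligning genome B's gene and the
#' outgroup's gene each onto gene A (the reference) and projecting onto
#' A's coordinates -- deterministic and adequate at the <3% divergence
#' this package targets. For every aligned non-gap site where A and B
#' differ: the outgroup allele matching A increments `matches_outgroup_a`
#' (evidence that B's allele is derived), matching B increments
#' `matches_outgroup_b`, anything else (third allele, or gap/absence in
#' the outgroup) is `unpolarizable`. Indel columns are excluded from
#' `diverged_sites` and counted separately.
#'
#' @param gene_a,gene_b Nucleotide CDS strings.
#' @param gene_og Outgroup CDS string, or `NULL` when the outgroup lacks
#'   the gene (every diverged site is then unpolarizable).
#' @param scoring An [align_scoring()].
#' @return List of class `polarization_result`: `diverged_sites`,
#'   `matches_outgroup_a`, `matches_outgroup_b`, `unpolarizable`,
#'   `indel_sites`, `derived_enriched` (`"a"`, `"b"` or `NA`: the lineage
#'   whose alleles are derived in a strict majority of polarizable sites)
#'   and the per-site table.
#' @export
polarize_with_outgroup <- function(gene_a, gene_b, gene_og,
                                   scoring = align_scoring()) {
  aln_ab <- global_align(gene_a, gene_b, scoring)
  a_cols <- strsplit(aln_ab$aligned_a, "")[[1]]
  b_cols <- strsplit(aln_ab$aligned_b, "")[[1]]
  # project b onto a's ungapped coordinates
  apos <- cumsum(a_cols != "-")
  b_on_a <- rep(NA_character_, sum(a_cols != "-"))
  keep <- a_cols != "-" & b_cols != "-"
  b_on_a[apos[keep]] <- b_cols[keep]
  indel_sites <- sum(a_cols == "-") + sum(a_cols != "-" & b_cols == "-")

  og_on_a <- rep(NA_character_, length(b_on_a))
  if (!is.null(gene_og)) {
    aln_ao <- global_align(gene_a, gene_og, scoring)
    a2 <- strsplit(aln_ao$aligned_a, "")[[1]]
    o2 <- strsplit(aln_ao$aligned_b, "")[[1]]
    apos2 <- cumsum(a2 != "-")
    keep2 <- a2 != "-" & o2 != "-"
    og_on_a[apos2[keep2]] <- o2[keep2]
  }

  a_seq <- a_cols[a_cols != "-"]
  div <- which(!is.na(b_on_a) & a_seq != b_on_a)
  og <- og_on_a[div]
  m_a <- sum(!is.na(og) & og == a_seq[div])
  m_b <- sum(!is.na(og) & og == b_on_a[div])
  unpol <- length(div) - m_a - m_b
  derived <- if (m_a > m_b) "b" else if (m_b > m_a) "a" else NA_character_
  # strict majority of all diverged sites required for an enrichment call
  if (!is.na(derived) && max(m_a, m_b) * 2L <= length(div))
    derived <- NA_character_
  structure(list(
    diverged_sites = length(div),
    matches_outgroup_a = m_a, matches_outgroup_b = m_b,
    unpolarizable = unpol, indel_sites = indel_sites,
    derived_enriched = derived,
    sites = data.frame(pos_a = div, allele_a = a_seq[div],
                       allele_b = b_on_a[div], allele_og = og,
                       stringsAsFactors = FALSE)
  ), class = "polarization_result")
}

#' @export
print.polarization_result <- function(x, ...) {
  cat(sprintf("<polarization_result> %d diverged site(s): outgroup matches a at %d, b at %d, unpolarizable %d\n",
              x$diverged_sites, x$matches_outgroup_a, x$matches_outgroup_b,
              x$unpolarizable))
  invisible(x)
}
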