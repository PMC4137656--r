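# Prophage relic inventory: flag phage-homologous loci in the target
# genome, delineate contiguous prophage regions tolerant of repeat-element
# interruptions and scaffold breaks, detect pseudogene fragmentation, and
# report genome reduction region by region.

#' Flag phage homologs in a target genome
#'
#' A target locus is phage-flagged iff its ortholog -- or, for a gene
#' fragment, its parent reference gene -- belongs to the reference phage
#' locus set. Repeat-class loci are flagged separately (they interrupt,
#' but do not belong to, phage regions).
#'
#' @param target An [annotated_genome()].
#' @param phage_reference_loci Character vector of reference loci that are
#'   phage/phage-associated.
#' @param map `ortholog_map` with the reference as genome A and `target`
#'   as genome B.
#' @param fragments Optional fragmentation events (see
#'   [detect_fragmentation()]) used to map fragment loci to their parent.
#' @return `data.frame` in genome order: `locus`, `scaffold_id`,
#'   `ref_locus` (NA if unmapped), `is_phage`, `is_repeat`.
#' @export
label_phage_homologs <- function(target, phage_reference_loci, map,
                                 fragments = NULL) {
  f <- target$features
  ref_of <- setNames(map$pairs$locus_a, map$pairs$locus_b)
  if (!is.null(fragments)) {
    fp <- fragment_parent_map(fragments)
    add <- setdiff(fp$target_locus, names(ref_of))
    ref_of[fp$target_locus[fp$target_locus %in% add]] <-
      fp$ref_locus[fp$target_locus %in% add]
  }
  ref_locus <- unname(ref_of[f$locus_tag])
  data.frame(
    locus = f$locus_tag, scaffold_id = f$scaffold_id,
    ref_locus = ref_locus,
    is_phage = !is.na(ref_locus) & ref_locus %in% phage_reference_loci,
    is_repeat = f$category == "repeat",
    stringsAsFactors = FALSE)
}

#' Delineate prophage regions
#'
#' Maximal runs of phage-flagged loci in target genome order, tolerating
#' up to `gap_tolerance` interleaved repeat-class loci (recorded as
#' interrupting members) and scaffold breaks between consecutive members;
#' any other locus closes the region. `gene_count` is ortholog-level:
#' fragments mapping to one reference gene count once.
#'
#' @param target An [annotated_genome()].
#' @param flags Output of [label_phage_homologs()].
#' @param gap_tolerance Maximum consecutive interleaved repeat loci
#'   (default 2).
#' @param scaffold_order Optional scaffold ordering (e.g. from
#'   [order_scaffolds_by_reference()]) applied before walking loci.
#' @param reference Optional reference [annotated_genome()], used to
#'   report each region's matched reference block.
#' @return List of `phage_region` lists: `region_id`, `members`,
#'   `interrupting_loci`, `gene_count`, `span_bp`, `scaffold_ids`,
#'   `reference_block`.
#' @export
delineate_regions <- function(target, flags, gap_tolerance = 2L,
                              scaffold_order = NULL, reference = NULL) {
  f <- target$features
  if (!is.null(scaffold_order))
    f <- f[order(match(f$scaffold_id, scaffold_order), f$start), ,
           drop = FALSE]
  fl <- flags[match(f$locus_tag, flags$locus), ]

  regions <- list()
  members <- character(0); interrupting <- character(0)
  pending <- character(0)
  close_region <- function() {
    if (length(members)) {
      regions[[length(regions) + 1L]] <<- list(members = members,
                                               interrupting = interrupting)
    }
    members <<- character(0); interrupting <<- character(0)
    pending <<- character(0)
  }
  for (i in seq_len(nrow(f))) {
    if (fl$is_phage[i]) {
      if (length(pending)) {  # repeats turned out to be interior
        members <- c(members, pending)
        interrupting <- c(interrupting, pending)
        pending <- character(0)
      }
      members <- c(members, f$locus_tag[i])
    } else if (fl$is_repeat[i] && length(members)) {
      pending <- c(pending, f$locus_tag[i])
      if (length(pending) > gap_tolerance) close_region()
    } else {
      close_region()
    }
  }
  close_region()

  ref_rank <- if (!is.null(reference))
    setNames(seq_len(nrow(reference$features)),
             reference$features$locus_tag) else NULL

  out <- vector("list", length(regions))
  for (k in seq_along(regions)) {
    mem <- regions[[k]]$members
    ff <- f[match(mem, f$locus_tag), ]
    span <- sum(vapply(split(ff, ff$scaffold_id), function(x)
      max(x$end) - min(x$start) + 1L, numeric(1)))
    phage_mem <- setdiff(mem, regions[[k]]$interrupting)
    refs <- flags$ref_locus[match(phage_mem, flags$locus)]
    gene_count <- length(unique(refs[!is.na(refs)])) + sum(is.na(refs))
    ref_block <- NA_character_
    if (!is.null(ref_rank)) {
      rr <- ref_rank[refs[!is.na(refs)]]
      if (length(rr))
        ref_block <- paste(names(sort(rr))[c(1L, length(rr))],
                           collapse = "--")
    }
    out[[k]] <- structure(list(
      region_id = sprintf("region_%02d", k),
      members = mem, interrupting_loci = regions[[k]]$interrupting,
      gene_count = gene_count, span_bp = span,
      scaffold_ids = unique(ff$scaffold_id),
      reference_block = ref_block), class = "phage_region")
  }
  out
}

#' @export
print.phage_region <- function(x, ...) {
  cat(sprintf("<phage_region> %s: %d loci (%d genes, %d interrupting), %s bp, scaffolds %s, ref %s\n",
              x$region_id, length(x$members), x$gene_count,
              length(x$interrupting_loci), format(x$span_bp, big.mark = ","),
              paste(x$scaffold_ids, collapse = ","), x$reference_block))
  invisible(x)
}

# target-fragment -> parent reference locus pairs from fragmentation events
fragment_parent_map <- function(events) {
  rows <- lapply(events, function(e)
    data.frame(target_locus = e$fragments, ref_locus = e$ref_locus,
               stringsAsFactors = FALSE))
  do.call(rbind, rows) %||%
    data.frame(target_locus = character(0), ref_locus = character(0),
               stringsAsFactors = FALSE)
}

# Reference-CDS interval covered by an alignment, in ref ungapped
# coordinates (plus `offset - 1` when the aligned ref string is a local
# window of the full CDS). Isolated coincidental matches beyond a long
# gap would inflate a min/max rule, so covered positions are clustered
# (gaps > 50 split) and the largest cluster taken.
.ref_segment <- function(aligned_ref, aligned_other, offset = 1L) {
  ra <- strsplit(aligned_ref, "")[[1]]
  ro <- strsplit(aligned_other, "")[[1]]
  rpos <- cumsum(ra != "-")
  both <- ra != "-" & ro != "-"
  if (!any(both)) return(c(NA_integer_, NA_integer_))
  pos <- rpos[both]
  cl <- split(pos, cumsum(c(1L, diff(pos) > 50L)))
  main <- cl[[which.max(lengths(cl))]]
  range(main) + offset - 1L
}

#' Detect gene fragmentation in the target genome
#'
#' Emits events of three causes: `split_annotation` when two or more
#' target loci align to disjoint segments of one reference CDS;
#' `premature_stop` when a paired target CDS carries an internal stop
#' codon in its annotated frame while the reference CDS has none
#' (positions reported in 1-based target-CDS nucleotides); `truncation`
#' when the aligned target covers less than `truncation_coverage` of the
#' reference length with flush genomic sequence beyond the gene (i.e. not
#' at a scaffold edge, where shortness is an assembly artifact).
#'
#' @param map `ortholog_map` (reference = genome A, target = genome B);
#'   its unpaired target loci are re-examined as fragment candidates.
#' @param reference,target [annotated_genome()] objects.
#' @param min_identity Identity floor for fragment placement (default 60).
#' @param truncation_coverage Reference-coverage threshold (default 0.9).
#' @param edge_margin Minimum bp of scaffold beyond the gene for flushness
#'   (default 30).
#' @param scoring An [align_scoring()].
#' @return List of events: `ref_locus`, `fragments`, `cause`, `positions`.
#' @export
detect_fragmentation <- function(map, reference, target, min_identity = 60,
                                 truncation_coverage = 0.9,
                                 edge_margin = 30L,
                                 scoring = align_scoring()) {
  events <- list()
  pairs <- map$pairs
  ref_of <- setNames(pairs$locus_a, pairs$locus_b)

  # --- premature stops in paired target CDS ---------------------------------
  internal_stops <- function(cds) {
    n <- nchar(cds)
    if (n %% 3L != 0L || n < 6L) return(integer(0))
    cod <- split_codons(cds)
    idx <- match(cod, CODONS)
    which(head(IS_STOP[idx], -1L))
  }
  for (i in seq_len(nrow(pairs))) {
    st <- internal_stops(target$cds[[pairs$locus_b[i]]])
    if (length(st) && length(internal_stops(reference$cds[[pairs$locus_a[i]]])) == 0L) {
      events[[length(events) + 1L]] <- list(
        ref_locus = pairs$locus_a[i], fragments = pairs$locus_b[i],
        cause = "premature_stop",
        positions = data.frame(codon = st, nt_start = (st - 1L) * 3L + 1L,
                               nt_end = st * 3L))
    }
  }

  # --- split annotations: place unpaired target loci into reference CDS -----
  seg_by_ref <- list()
  add_seg <- function(ref_locus, target_locus, seg) {
    seg_by_ref[[ref_locus]] <<- rbind(
      seg_by_ref[[ref_locus]],
      data.frame(target_locus = target_locus, seg_start = seg[1],
                 seg_end = seg[2], stringsAsFactors = FALSE))
  }
  for (i in seq_len(nrow(pairs)))
    add_seg(pairs$locus_a[i], pairs$locus_b[i],
            .ref_segment(pairs$aligned_a[i], pairs$aligned_b[i]))

  if (length(map$unpaired_b)) {
    cand <- seed_candidates(target$cds[map$unpaired_b], reference$cds,
                            k = map$params$k %||% 12L, query_stride = 8L)
    for (i in seq_len(nrow(cand))) {
      tl <- cand$query[i]; rl <- cand$subject[i]
      p <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(target$cds[[tl]]),
        Biostrings::DNAString(reference$cds[[rl]]),
        type = "global-local", substitutionMatrix = .subst_matrix(scoring),
        gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
      pa <- as.character(Biostrings::alignedPattern(p))
      sa <- as.character(Biostrings::alignedSubject(p))
      ident <- 100 * sum(strsplit(pa, "")[[1]] == strsplit(sa, "")[[1]]) /
        nchar(pa)
      if (ident < min_identity) next
      add_seg(rl, tl, .ref_segment(sa, pa,
                                   offset = Biostrings::start(
                                     Biostrings::subject(p))))
    }
  }
  for (rl in names(seg_by_ref)) {
    segs <- seg_by_ref[[rl]]
    segs <- segs[!is.na(segs$seg_start), , drop = FALSE]
    if (nrow(segs) < 2L) next
    segs <- segs[order(segs$seg_start), , drop = FALSE]
    lens <- segs$seg_end - segs$seg_start + 1
    ov <- segs$seg_end[-nrow(segs)] - segs$seg_start[-1] + 1
    overlaps <- any(ov > 0.1 * pmin(lens[-length(lens)], lens[-1]))
    if (!overlaps)
      events[[length(events) + 1L]] <- list(
        ref_locus = rl, fragments = segs$target_locus,
        cause = "split_annotation",
        positions = segs[, c("seg_start", "seg_end")])
  }

  # --- truncations ----------------------------------------------------------
  split_refs <- vapply(Filter(function(e) e$cause == "split_annotation",
                              events), `[[`, character(1), "ref_locus")
  for (i in seq_len(nrow(pairs))) {
    seg <- .ref_segment(pairs$aligned_a[i], pairs$aligned_b[i])
    if (anyNA(seg)) next
    cov <- (seg[2] - seg[1] + 1) / nchar(reference$cds[[pairs$locus_a[i]]])
    if (cov >= truncation_coverage) next
    if (pairs$locus_a[i] %in% split_refs) next
    ft <- target$features[target$features$locus_tag == pairs$locus_b[i], ]
    scaf_len <- nchar(target$scaffolds[[ft$scaffold_id]])
    flush <- ft$start > edge_margin && ft$end <= scaf_len - edge_margin
    if (flush)
      events[[length(events) + 1L]] <- list(
        ref_locus = pairs$locus_a[i], fragments = pairs$locus_b[i],
        cause = "truncation",
        positions = data.frame(seg_start = seg[1], seg_end = seg[2]))
  }
  events
}

#' Genome-reduction report
#'
#' For each reference phage region (maximal run of phage-category loci in
#' reference order, or regions supplied explicitly): retained fraction,
#' lost loci, and a status of `intact` (nothing lost), `absent` (nothing
#' retained; flanking loci reported) or `reduced`. The census is the
#' ortholog-level count of reference phage genes retained in the target
#' (fragments merged).
#'
#' @param reference,target [annotated_genome()] objects.
#' @param map `ortholog_map` (reference = A, target = B).
#' @param events Fragmentation events from [detect_fragmentation()].
#' @param missing Missing-locus table from [find_missing_genes()] (or a
#'   character vector); defaults to reference loci with neither ortholog
#'   nor fragment.
#' @param ref_regions Optional list of character vectors of reference loci
#'   defining the regions explicitly.
#' @return List of class `reduction_report`: `regions` (data.frame),
#'   `census`, `lost_loci`, `lost_span_bp`.
#' @export
reduction_report <- function(reference, target, map, events = list(),
                             missing = NULL, ref_regions = NULL) {
  rf <- reference$features
  if (is.null(ref_regions)) {
    r <- rle(rf$category == "phage")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ref_regions <- lapply(which(r$values), function(k)
      rf$locus_tag[starts[k]:ends[k]])
  }
  fp <- fragment_parent_map(events)
  retained_refs <- unique(c(map$pairs$locus_a, fp$ref_locus))
  if (is.null(missing)) {
    missing <- setdiff(rf$locus_tag, retained_refs)
  } else if (is.data.frame(missing)) missing <- missing$locus

  ortho_of <- setNames(map$pairs$locus_b, map$pairs$locus_a)
  rows <- list(); lost_all <- character(0); lost_span <- 0
  for (k in seq_along(ref_regions)) {
    loci <- ref_regions[[k]]
    retained <- intersect(loci, retained_refs)
    lost <- intersect(loci, missing)
    status <- if (length(retained) == 0L) "absent"
              else if (length(lost) == 0L) "intact" else "reduced"
    # span of contiguous lost runs, in reference coordinates
    span <- 0
    if (length(lost)) {
      pos <- sort(match(lost, rf$locus_tag))
      run <- cumsum(c(1L, diff(pos) != 1L))
      for (g in split(pos, run))
        span <- span + max(rf$end[g]) - min(rf$start[g]) + 1L
    }
    lost_span <- lost_span + span
    lost_all <- c(lost_all, lost)
    idx <- match(loci, rf$locus_tag)
    flank_prev <- if (min(idx) > 1L) rf$locus_tag[min(idx) - 1L] else NA
    flank_next <- if (max(idx) < nrow(rf)) rf$locus_tag[max(idx) + 1L] else NA
    rows[[k]] <- data.frame(
      region_id = sprintf("ref_region_%02d", k),
      first_locus = loci[1], last_locus = loci[length(loci)],
      n_genes = length(loci), retained = length(retained),
      lost = length(lost),
      retained_fraction = length(retained) / length(loci),
      status = status, lost_span_bp = span,
      flank_prev = flank_prev, flank_next = flank_next,
      flank_prev_target = unname(ortho_of[flank_prev]) %||% NA_character_,
      flank_next_target = unname(ortho_of[flank_next]) %||% NA_character_,
      stringsAsFactors = FALSE)
  }
  phage_loci <- rf$locus_tag[rf$category == "phage"]
  structure(list(
    regions = do.call(rbind, rows) %||% data.frame(),
    census = length(intersect(phage_loci, retained_refs)),
    lost_loci = unique(lost_all),
    lost_span_bp = lost_span
  ), class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report> %d reference region(s); phage census %d; %d loci lost (%s bp)\n",
              nrow(x$regions), x$census, length(x$lost_loci),
              format(x$lost_span_bp, big.mark = ",")))
  if (nrow(x$regions))
    print(x$regions[, c("region_id", "first_locus", "last_locus", "n_genes",
                        "retained", "lost", "status")])
  invisible(x)
}
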