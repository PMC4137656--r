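# Gene-order synteny: order target scaffolds by reference gene order,
# compute within-scaffold collinear blocks, flag displaced segments.
# Block logic runs on gene ranks, not bp, so in-frame indels and small
# length changes cannot break blocks; bp spans are reported alongside.

#' Order target scaffolds by reference gene order
#'
#' Each scaffold is keyed by the median reference position (gene rank) of
#' its orthologs -- the "order in which the majority of its genes appear"
#' in the reference; scaffolds without orthologs go last, sorted by ID.
#'
#' @param target An [annotated_genome()].
#' @param map `ortholog_map` with the reference as genome A and `target`
#'   as genome B.
#' @param reference The reference [annotated_genome()].
#' @return Character vector of scaffold IDs in reference-concatenation
#'   order.
#' @export
order_scaffolds_by_reference <- function(target, map, reference) {
  ref_rank <- setNames(seq_len(nrow(reference$features)),
                       reference$features$locus_tag)
  rank_of_target <- setNames(unname(ref_rank[map$pairs$locus_a]),
                             map$pairs$locus_b)
  f <- target$features
  keys <- vapply(names(target$scaffolds), function(sid) {
    r <- rank_of_target[f$locus_tag[f$scaffold_id == sid]]
    r <- r[!is.na(r)]
    if (length(r)) median(r) else Inf
  }, numeric(1))
  names(target$scaffolds)[order(keys, names(target$scaffolds))]
}

#' Within-scaffold synteny blocks
#'
#' Maximal runs of ortholog pairs whose reference ranks (among paired
#' genes, so lineage-specific losses cannot break a run) are
#' consecutive-monotone, ascending or descending, allowing up to
#' `max_gap` unpaired target loci between members. A block whose
#' reference interval lies further than `displaced_distance` gene ranks
#' from its flanking blocks on the same scaffold is flagged displaced.
#'
#' @param map `ortholog_map` (reference = genome A, target = genome B).
#' @param reference,target [annotated_genome()] objects.
#' @param scaffold_order Optional scaffold ordering from
#'   [order_scaffolds_by_reference()].
#' @param max_gap Unpaired target loci tolerated inside a block
#'   (default 1).
#' @param displaced_distance Rank distance beyond which a block is
#'   displaced (default 50 genes).
#' @return List of `synteny_block` lists: `block_id`, `scaffold`, `pairs`
#'   (locus_b, locus_a, ref rank, genome-order index), `ref_range`,
#'   `target_span_bp`, `orientation` (`same`/`inverted`), `displaced`.
#' @export
synteny_blocks <- function(map, reference, target, scaffold_order = NULL,
                           max_gap = 1L, displaced_distance = 50L) {
  f <- target$features
  if (!is.null(scaffold_order))
    f <- f[order(match(f$scaffold_id, scaffold_order), f$start), ,
           drop = FALSE]
  ref_order <- reference$features$locus_tag
  paired_ref <- intersect(ref_order, map$pairs$locus_a)
  prank <- setNames(seq_along(paired_ref), paired_ref)  # rank among paired
  prank_of_target <- setNames(unname(prank[map$pairs$locus_a]),
                              map$pairs$locus_b)

  blocks <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && nrow(cur$pairs)) blocks[[length(blocks) + 1L]] <<- cur
    cur <<- NULL
  }
  for (sid in unique(f$scaffold_id)) {
    flush()
    fs <- f[f$scaffold_id == sid, , drop = FALSE]
    gap_run <- 0L
    for (i in seq_len(nrow(fs))) {
      lt <- fs$locus_tag[i]
      q <- prank_of_target[lt]
      if (is.na(q)) {
        gap_run <- gap_run + 1L
        if (gap_run > max_gap) flush()
        next
      }
      row <- data.frame(locus_b = lt,
                        locus_a = map$pairs$locus_a[match(lt, map$pairs$locus_b)],
                        ref_rank = unname(q), start = fs$start[i],
                        end = fs$end[i], stringsAsFactors = FALSE)
      if (is.null(cur)) {
        cur <- list(scaffold = sid, pairs = row, dir = 0L)
      } else {
        last <- cur$pairs$ref_rank[nrow(cur$pairs)]
        step <- q - last
        ok <- (step == 1L && cur$dir %in% c(0L, 1L)) ||
              (step == -1L && cur$dir %in% c(0L, -1L))
        if (ok) {
          cur$dir <- sign(step)
          cur$pairs <- rbind(cur$pairs, row)
        } else {
          flush()
          cur <- list(scaffold = sid, pairs = row, dir = 0L)
        }
      }
      gap_run <- 0L
    }
  }
  flush()

  out <- vector("list", length(blocks))
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    rr <- range(b$pairs$ref_rank)
    out[[k]] <- structure(list(
      block_id = sprintf("block_%03d", k),
      scaffold = b$scaffold, pairs = b$pairs,
      ref_range = rr,
      target_span_bp = max(b$pairs$end) - min(b$pairs$start) + 1L,
      orientation = if (b$dir == -1L) "inverted" else "same",
      displaced = FALSE), class = "synteny_block")
  }

  # displaced: the block's reference interval is far (edge-to-edge rank
  # distance) from every same-scaffold neighbor block
  scafs <- vapply(out, `[[`, character(1), "scaffold")
  first_rank <- vapply(out, function(b) b$pairs$ref_rank[1], numeric(1))
  last_rank <- vapply(out, function(b)
    b$pairs$ref_rank[nrow(b$pairs)], numeric(1))
  np <- vapply(out, function(b) nrow(b$pairs), integer(1))
  for (k in seq_along(out)) {
    nbrs <- c(if (k > 1L && scafs[k - 1L] == scafs[k]) k - 1L,
              if (k < length(out) && scafs[k + 1L] == scafs[k]) k + 1L)
    if (!length(nbrs)) next
    d <- vapply(nbrs, function(j)
      if (j < k) abs(first_rank[k] - last_rank[j])
      else abs(first_rank[j] - last_rank[k]), numeric(1))
    # far from every physical neighbor, and the smaller party of the
    # break (the relocated segment, not the backbone it interrupts)
    if (all(d > displaced_distance) && np[k] < max(np[nbrs]))
      out[[k]]$displaced <- TRUE
  }
  out
}

#' @export
print.synteny_block <- function(x, ...) {
  cat(sprintf("<synteny_block> %s on %s: %d pairs, ref ranks %d--%d, %s%s\n",
              x$block_id, x$scaffold, nrow(x$pairs), x$ref_range[1],
              x$ref_range[2], x$orientation,
              if (x$displaced) ", displaced" else ""))
  invisible(x)
}

#' Summarize synteny blocks as a data frame
#'
#' @param blocks Output of [synteny_blocks()].
#' @return One row per block.
#' @export
synteny_summary <- function(blocks) {
  do.call(rbind, lapply(blocks, function(b) data.frame(
    block_id = b$block_id, scaffold = b$scaffold, n_pairs = nrow(b$pairs),
    ref_start = b$ref_range[1], ref_end = b$ref_range[2],
    target_span_bp = b$target_span_bp, orientation = b$orientation,
    displaced = b$displaced, stringsAsFactors = FALSE)))
}

#' Synteny gradient plot
#'
#' Target genes drawn as tick marks in target genome order (scaffolds
#' concatenated in the given order), colored on a yellow-to-blue gradient
#' by the reference rank of each gene's ortholog; genes without orthologs
#' are grey. The visual analogue of a synteny-gradient viewer track.
#'
#' @param map `ortholog_map` (reference = A, target = B).
#' @param reference,target [annotated_genome()] objects.
#' @param scaffold_order Optional scaffold ordering.
#' @return A ggplot object.
#' @export
plot_synteny_gradient <- function(map, reference, target,
                                  scaffold_order = NULL) {
  f <- target$features
  if (!is.null(scaffold_order))
    f <- f[order(match(f$scaffold_id, scaffold_order), f$start), ,
           drop = FALSE]
  ref_rank <- setNames(seq_len(nrow(reference$features)),
                       reference$features$locus_tag)
  rk <- ref_rank[map$pairs$locus_a[match(f$locus_tag, map$pairs$locus_b)]]
  d <- data.frame(idx = seq_len(nrow(f)), ref_rank = unname(rk),
                  scaffold = f$scaffold_id)
  ggplot2::ggplot(d, ggplot2::aes(x = idx, y = 1, fill = ref_rank)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_fill_gradient(low = "#ffe866", high = "#1f4e9c",
                                 na.value = "grey85",
                                 name = "reference rank") +
    ggplot2::labs(x = "target gene order (scaffolds concatenated)",
                  y = NULL,
                  title = sprintf("%s vs %s gene-order synteny",
                                  target$genome_id, reference$genome_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
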