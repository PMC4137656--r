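# Synthetic ancestor construction and codon-aware descent simulation with
# ground truth, emulating the divergence structure of a pair of very
# closely related endosymbiont genomes (a ~1.1 Mb, ~1200-CDS reduced
# genome; sub-1% substitution density; prophage-region deletion; repeat
# insertion; premature-stop fragmentation; in-frame indels).
#
# RNG discipline: one global stream. generate_ancestor() seeds
# set.seed(cfg$seed); evolve_pair() seeds set.seed(cfg$seed + 1). Within
# each, sub-processes draw in a fixed documented order (outgroup, lineage
# a, lineage b substitutions; then indels, fragmentation, deletions,
# repeat insertions, relocations, scaffold layout), so runs are
# reproducible byte for byte.

#' Simulation configuration
#'
#' Defaults describe the study conditions this package is validated under:
#' a 1,200-gene ancestor with mean CDS 764 bp and mean intergenic gap
#' 130 bp at 35.2% GC; pairwise synonymous divergence 0.0031 (0.31%);
#' omega 0.7 in every gene class; three ancestral phage/accessory regions
#' of 34, 29 and 8 genes of which the descendant retains 21, 7 and 0 genes
#' (43 deleted loci); two premature-stop fragmentations; two repeat genes
#' inserted into surviving phage runs; in-frame indels of 3--189 bp in
#' about 10 genes; one relocated 10-gene segment; a 43-scaffold descendant
#' assembly; and an outgroup three times as divergent as the pair.
#'
#' @param n_genes Number of ancestral genes.
#' @param mean_gene_len Mean CDS length in bp (start and stop included).
#' @param mean_intergenic_len Mean intergenic spacer, bp.
#' @param gc_content Target GC proportion.
#' @param phage_regions List of `c(start, n)` gene-index intervals laid
#'   out as contiguous phage-category runs (must not overlap).
#' @param repeat_gene_fraction Proportion of non-phage genes of category
#'   `repeat`.
#' @param hypothetical_fraction Proportion of non-phage, non-repeat genes
#'   of category `hypothetical` (the rest are `core`).
#' @param target_ks Expected pairwise synonymous divergence per synonymous
#'   site between the two descendants (must be < 0.75 for the
#'   Jukes-Cantor correction to exist).
#' @param omega_by_class Named vector mapping category to target Ka/Ks.
#' @param indel_gene_fraction Proportion of surviving genes receiving one
#'   in-frame indel.
#' @param indel_len_range `c(min, max)` indel length in bp; multiples of 3.
#' @param region_deletions List of `c(region, retain)`: for phage region
#'   `region`, retain the first `retain` genes and delete the rest from
#'   the descendant.
#' @param fragmentation_events Number of genes interrupted by a premature
#'   stop codon in the descendant.
#' @param repeat_insertions Number of new repeat-category genes inserted
#'   inside surviving phage runs of the descendant.
#' @param relocations List of `c(start, n)` gene segments relocated in the
#'   descendant.
#' @param n_scaffolds_b Number of scaffolds the descendant assembly is
#'   split into (scaffold order is shuffled).
#' @param outgroup Simulate an outgroup branching before the pair's split?
#' @param outgroup_ks_multiplier Outgroup branch length as a multiple of
#'   `target_ks`.
#' @param seed Integer RNG seed.
#' @return List of class `evolution_config`.
#' @export
evolution_config <- function(n_genes = 1200L,
                             mean_gene_len = 764,
                             mean_intergenic_len = 130,
                             gc_content = 0.352,
                             phage_regions = list(c(201L, 34L),
                                                  c(501L, 29L),
                                                  c(801L, 8L)),
                             repeat_gene_fraction = 0.06,
                             hypothetical_fraction = 0.25,
                             target_ks = 0.0031,
                             omega_by_class = c(core = 0.7, phage = 0.7,
                                                "repeat" = 0.7,
                                                hypothetical = 0.7,
                                                pseudogene = 0.7),
                             indel_gene_fraction = 10 / 1200,
                             indel_len_range = c(3L, 189L),
                             region_deletions = list(c(1L, 21L), c(2L, 7L),
                                                     c(3L, 0L)),
                             fragmentation_events = 2L,
                             repeat_insertions = 2L,
                             relocations = list(c(42L, 10L)),
                             n_scaffolds_b = 43L,
                             outgroup = TRUE,
                             outgroup_ks_multiplier = 3,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), mean_gene_len = mean_gene_len,
              mean_intergenic_len = mean_intergenic_len,
              gc_content = gc_content, phage_regions = phage_regions,
              repeat_gene_fraction = repeat_gene_fraction,
              hypothetical_fraction = hypothetical_fraction,
              target_ks = target_ks, omega_by_class = omega_by_class,
              indel_gene_fraction = indel_gene_fraction,
              indel_len_range = as.integer(indel_len_range),
              region_deletions = region_deletions,
              fragmentation_events = as.integer(fragmentation_events),
              repeat_insertions = as.integer(repeat_insertions),
              relocations = relocations,
              n_scaffolds_b = as.integer(n_scaffolds_b),
              outgroup = isTRUE(outgroup),
              outgroup_ks_multiplier = outgroup_ks_multiplier,
              seed = as.integer(seed))
  validate_evolution_config(cfg)
  structure(cfg, class = "evolution_config")
}

validate_evolution_config <- function(cfg) {
  props <- c(cfg$repeat_gene_fraction, cfg$hypothetical_fraction,
             cfg$indel_gene_fraction, cfg$gc_content)
  if (any(props < 0 | props > 1)) stopf("proportions must lie in [0, 1]")
  if (cfg$target_ks < 0) stopf("target_ks must be >= 0")
  if (cfg$target_ks >= 0.75)
    stopf("target_ks %.3f leaves the Jukes-Cantor correction undefined (pS >= 0.75)",
          cfg$target_ks)
  if (any(cfg$indel_len_range %% 3L != 0L))
    stopf("indel lengths must be multiples of 3")
  if (length(cfg$phage_regions)) {
    iv <- do.call(rbind, cfg$phage_regions)
    if (any(iv[, 1] < 1L) || any(iv[, 1] + iv[, 2] - 1L > cfg$n_genes))
      stopf("phage region outside gene range")
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1L &&
        any(iv[-1, 1] <= iv[-nrow(iv), 1] + iv[-nrow(iv), 2] - 1L))
      stopf("phage regions overlap")
  }
  for (rd in cfg$region_deletions) {
    if (rd[1] < 1L || rd[1] > length(cfg$phage_regions))
      stopf("region deletion references missing phage region %d", rd[1])
    if (rd[2] > cfg$phage_regions[[rd[1]]][2])
      stopf("cannot retain more genes than region %d contains", rd[1])
  }
  invisible(cfg)
}

# Codon sampling probabilities hitting the target GC content in
# expectation. Excluding stop codons (AT-rich) from the sense pool shifts
# composition upward, so the per-nucleotide GC used for codon sampling is
# solved for rather than taken at face value.
.codon_probs <- function(gc) {
  codon_p <- function(g) {
    p_nt <- setNames(c((1 - g) / 2, g / 2, g / 2, (1 - g) / 2), NT)
    vapply(CODONS, function(cd)
      prod(p_nt[strsplit(cd, "")[[1]]]), numeric(1))
  }
  gc_frac <- vapply(CODONS, function(cd)
    (nchar(gsub("[AT]", "", cd))) / 3, numeric(1))
  sense_gc <- function(g) {
    p <- codon_p(g); p[IS_STOP] <- 0; p <- p / sum(p)
    sum(p * gc_frac)
  }
  g_adj <- stats::uniroot(function(g) sense_gc(g) - gc,
                          c(0.02, 0.98), tol = 1e-9)$root
  p <- codon_p(g_adj)
  sense <- p; sense[IS_STOP] <- 0
  p0 <- codon_p(gc)
  stops <- p0; stops[!IS_STOP] <- 0
  list(sense = sense / sum(sense), stops = stops / sum(stops))
}

#' Generate a random ancestral genome
#'
#' Builds a single-scaffold genome of `n_genes` CDS: ATG start, random
#' sense codons (no internal stops) at the configured GC content, a stop
#' codon, random strand, intergenic spacers, phage regions laid out
#' contiguously and repeat/hypothetical categories scattered elsewhere.
#' Deterministic for a given `cfg$seed`.
#'
#' @param cfg An [evolution_config()].
#' @return An [annotated_genome()] with locus tags `ANC_0001`, ...
#' @export
generate_ancestor <- function(cfg) {
  validate_evolution_config(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_genes
  probs <- .codon_probs(cfg$gc_content)
  atg <- match("ATG", CODONS)

  category <- rep("core", n)
  for (pr in cfg$phage_regions)
    category[pr[1]:(pr[1] + pr[2] - 1L)] <- "phage"
  non_phage <- which(category != "phage")
  n_rep <- round(cfg$repeat_gene_fraction * n)
  rep_idx <- sort(sample(non_phage, min(n_rep, length(non_phage))))
  category[rep_idx] <- "repeat"
  rest <- which(category == "core")
  n_hyp <- round(cfg$hypothetical_fraction * length(rest))
  category[sort(sample(rest, n_hyp))] <- "hypothetical"

  mean_codons <- cfg$mean_gene_len / 3
  n_codons <- pmax(35L, round(rnorm(n, mean_codons, mean_codons / 4)))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  genes <- vector("list", n)
  for (i in seq_len(n)) {
    internal <- sample(64L, n_codons[i] - 2L, replace = TRUE,
                       prob = probs$sense)
    stop_cd <- sample(64L, 1L, prob = probs$stops)
    genes[[i]] <- c(atg, internal, stop_cd)
  }

  spacer_len <- rpois(n + 1L, cfg$mean_intergenic_len)
  p_nt <- c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
            cfg$gc_content / 2, (1 - cfg$gc_content) / 2)
  spacers <- vapply(spacer_len, function(L)
    paste(sample(NT, L, replace = TRUE, prob = p_nt), collapse = ""),
    character(1))

  tags <- sprintf("ANC_%04d", seq_len(n))
  products <- ifelse(category == "phage", "phage protein",
              ifelse(category == "repeat", "transposase/reverse transcriptase",
              ifelse(category == "hypothetical", "hypothetical protein",
                     "conserved protein")))
  assemble_genome("ancestor", tags, genes, strand, category, products,
                  spacers, scaffold_assign = rep(1L, n),
                  scaffold_prefix = "anc_scaffold")
}

# Assemble an annotated_genome from per-gene codon-index vectors, strands,
# spacers (length n+1, spacer i precedes gene i) and a contiguous scaffold
# assignment. Minus-strand genes are embedded reverse-complemented.
assemble_genome <- function(genome_id, tags, genes, strand, category,
                            products, spacers, scaffold_assign,
                            scaffold_prefix = "scaffold",
                            scaffold_order = NULL) {
  n <- length(genes)
  cds <- vapply(genes, function(g) paste(CODONS[g], collapse = ""),
                character(1))
  emb <- cds
  minus <- strand == "-"
  if (any(minus))
    emb[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(emb[minus])))

  scafs <- character(0)
  rows <- vector("list", length(unique(scaffold_assign)))
  for (sc in unique(scaffold_assign)) {
    idx <- which(scaffold_assign == sc)
    sid <- sprintf("%s_%02d", scaffold_prefix, sc)
    gene_len <- nchar(emb[idx])
    sp_len <- nchar(spacers[idx])
    starts <- cumsum(sp_len + c(0L, gene_len[-length(idx)])) + 1L
    ends <- starts + gene_len - 1L
    rows[[sc]] <- data.frame(locus_tag = tags[idx], scaffold_id = sid,
                             start = starts, end = ends,
                             strand = strand[idx], product = products[idx],
                             category = category[idx],
                             stringsAsFactors = FALSE)
    parts <- as.vector(rbind(spacers[idx], emb[idx]))
    if (scaffold_assign[n] == sc) parts <- c(parts, spacers[n + 1L])
    scafs[sid] <- paste(parts, collapse = "")
  }
  if (!is.null(scaffold_order)) scafs <- scafs[scaffold_order]
  annotated_genome(genome_id, scafs, do.call(rbind, rows))
}

# Substitution process on one lineage: per gene, draw Poisson numbers of
# synonymous and nonsynonymous events (expectations ks*S and omega*ks*N)
# and realize each as a uniformly chosen currently available synonymous /
# nonsynonymous single-nucleotide codon change (site-category-aware
# proposal; stop-creating changes are never available). Returns the edited
# genes and the event ledger.
.mutate_lineage <- function(genes, omega_gene, ks_branch, lineage, tags) {
  ev <- list()
  for (i in seq_along(genes)) {
    cod <- genes[[i]]
    S <- sum(S_SITES[cod], na.rm = TRUE)
    N <- sum(N_SITES[cod], na.rm = TRUE)
    n_syn <- rpois(1L, ks_branch * S)
    n_non <- rpois(1L, omega_gene[i] * ks_branch * N)
    for (cls in c("syn", "nonsyn")) {
      n_ev <- if (cls == "syn") n_syn else n_non
      if (n_ev == 0L) next
      chg <- if (cls == "syn") SYN_CHANGES else NONSYN_CHANGES
      chg_n <- if (cls == "syn") SYN_N else NONSYN_N
      for (e in seq_len(n_ev)) {
        w <- chg_n[cod]
        if (sum(w) == 0L) break
        j <- sample.int(length(cod), 1L, prob = w)
        opts <- chg[[cod[j]]]
        r <- opts[sample.int(nrow(opts), 1L), ]
        from_cd <- CODONS[cod[j]]
        ev[[length(ev) + 1L]] <- data.frame(
          lineage = lineage, locus = tags[i], codon = j, pos = r[1],
          nt_pos = (j - 1L) * 3L + r[1],
          from_nt = substr(from_cd, r[1], r[1]), to_nt = NT[r[2]],
          class = cls, stringsAsFactors = FALSE)
        cod[j] <- r[3]
      }
    }
    genes[[i]] <- cod
  }
  events <- do.call(rbind, ev) %||%
    data.frame(lineage = character(0), locus = character(0),
               codon = integer(0), pos = integer(0), nt_pos = integer(0),
               from_nt = character(0), to_nt = character(0),
               class = character(0), stringsAsFactors = FALSE)
  list(genes = genes, events = events)
}

#' Evolve a genome pair (plus optional outgroup) with ground truth
#'
#' Two descendants diverge from `ancestor` by codon-aware substitution
#' (each lineage carries half of `target_ks`); an optional outgroup
#' branches off first. Structural events -- in-frame indels, premature-stop
#' fragmentation, phage-region deletion, repeat-gene insertion, segment
#' relocation, multi-scaffold layout -- are applied to genome B only. Every
#' event is recorded in the returned truth table.
#'
#' @param ancestor An [annotated_genome()] from [generate_ancestor()].
#' @param cfg The [evolution_config()] used to generate it.
#' @return List of class `sim_pair`: `genome_a`, `genome_b`, `outgroup`
#'   (or `NULL`) and `truth` (a `truth_table`).
#' @export
evolve_pair <- function(ancestor, cfg) {
  validate_evolution_config(cfg)
  set.seed(cfg$seed + 1L)
  f <- ancestor$features
  n <- nrow(f)
  tags <- f$locus_tag
  genes0 <- lapply(ancestor$cds[tags], function(s) codon_index(split_codons(s)))
  names(genes0) <- NULL
  omega_gene <- unname(cfg$omega_by_class[f$category])
  if (anyNA(omega_gene)) stopf("omega_by_class lacks a category present in the genome")
  spacers <- .extract_spacers(ancestor)

  ks_half <- cfg$target_ks / 2

  out_og <- NULL
  og_res <- NULL
  if (cfg$outgroup) {
    og_res <- .mutate_lineage(genes0, omega_gene,
                              cfg$target_ks * cfg$outgroup_ks_multiplier,
                              "outgroup", tags)
  }
  a_res <- .mutate_lineage(genes0, omega_gene, ks_half, "a", tags)
  b_res <- .mutate_lineage(genes0, omega_gene, ks_half, "b", tags)

  genes_a <- a_res$genes
  genes_b <- b_res$genes

  # --- structural events on lineage b ---------------------------------------
  region_members <- lapply(cfg$phage_regions, function(pr)
    pr[1]:(pr[1] + pr[2] - 1L))
  deleted_idx <- integer(0)
  regions_truth <- list()
  for (k in seq_along(cfg$region_deletions)) {
    rd <- cfg$region_deletions[[k]]
    mem <- region_members[[rd[1]]]
    retained <- head(mem, rd[2])
    del <- setdiff(mem, retained)
    deleted_idx <- c(deleted_idx, del)
    regions_truth[[k]] <- data.frame(
      region = rd[1], start_gene = mem[1], n_genes = length(mem),
      retained = rd[2], deleted = length(del), stringsAsFactors = FALSE)
  }
  deleted_idx <- sort(unique(deleted_idx))
  surviving <- setdiff(seq_len(n), deleted_idx)

  # in-frame indels on surviving genes
  indel_truth <- list()
  n_indel <- round(cfg$indel_gene_fraction * n)
  indel_genes <- sort(sample(surviving, min(n_indel, length(surviving))))
  probs <- .codon_probs(cfg$gc_content)
  for (i in indel_genes) {
    len_opts <- seq(cfg$indel_len_range[1], cfg$indel_len_range[2], by = 3L)
    L <- if (length(len_opts) == 1L) len_opts else sample(len_opts, 1L)
    k3 <- L %/% 3L
    cod <- genes_b[[i]]
    nc <- length(cod)
    type <- sample(c("insertion", "deletion"), 1L)
    if (type == "deletion" && nc - 2L <= k3) type <- "insertion"
    if (type == "insertion") {
      at <- sample(2:(nc - 1L), 1L)  # insert before codon `at`
      ins <- sample(64L, k3, replace = TRUE, prob = probs$sense)
      genes_b[[i]] <- append(cod, ins, after = at - 1L)
    } else {
      at <- sample(2:(nc - 1L - k3), 1L)
      genes_b[[i]] <- cod[-(at:(at + k3 - 1L))]
    }
    indel_truth[[length(indel_truth) + 1L]] <- data.frame(
      locus = tags[i], type = type, length_bp = L, at_codon = at,
      stringsAsFactors = FALSE)
  }

  # premature-stop fragmentation, preferentially in surviving phage genes
  frag_truth <- list()
  phage_pool <- intersect(surviving, which(f$category == "phage"))
  pool <- if (length(phage_pool) >= cfg$fragmentation_events) phage_pool
          else surviving
  frag_genes <- sort(sample(pool, cfg$fragmentation_events))
  stop_idx <- which(CODONS == "TAA")
  for (i in frag_genes) {
    nc <- length(genes_b[[i]])
    j <- sample(5:(nc - 5L), 1L)
    genes_b[[i]][j] <- stop_idx
    frag_truth[[length(frag_truth) + 1L]] <- data.frame(
      locus = tags[i], stop_codon = j,
      nt_start = (j - 1L) * 3L + 1L, nt_end = j * 3L,
      stringsAsFactors = FALSE)
  }

  # --- build descendant gene orders -----------------------------------------
  tags_a <- sprintf("GA_%04d", seq_len(n))
  tags_b <- sprintf("GB_%04d", seq_len(n))
  tags_og <- sprintf("OG_%04d", seq_len(n))

  ord_b <- surviving
  # repeat-gene insertions inside surviving phage runs
  inserted_truth <- list()
  ins_entries <- list()
  surv_phage <- intersect(ord_b, which(f$category == "phage"))
  if (cfg$repeat_insertions > 0L && length(surv_phage) >= 2L) {
    # insertion slots: between two consecutive surviving phage genes
    slot_after <- surv_phage[which(diff(match(surv_phage, ord_b)) == 1L)]
    if (!length(slot_after)) slot_after <- surv_phage
    slots <- sample(rep(slot_after, length.out = max(cfg$repeat_insertions,
                                                     length(slot_after))),
                    cfg$repeat_insertions)
    for (m in seq_len(cfg$repeat_insertions)) {
      tag_r <- sprintf("GB_R%02d", m)
      ncod <- max(35L, round(rnorm(1, 300, 40)))
      cds <- c(match("ATG", CODONS),
               sample(64L, ncod - 2L, replace = TRUE, prob = probs$sense),
               sample(64L, 1L, prob = probs$stops))
      ins_entries[[m]] <- list(after = slots[m], tag = tag_r, codons = cds)
      inserted_truth[[m]] <- data.frame(locus = tag_r,
                                        after_ancestor_locus = tags[slots[m]],
                                        stringsAsFactors = FALSE)
    }
  }

  # relocations: move segments elsewhere in the order
  relocated <- character(0)
  for (rl in cfg$relocations) {
    seg <- rl[1]:(rl[1] + rl[2] - 1L)
    seg <- intersect(seg, ord_b)
    if (!length(seg)) next
    pos <- match(seg, ord_b)
    rest <- ord_b[-pos]
    # destination well away from the origin and never inside a phage run
    # (so relocation does not manufacture spurious region breaks)
    repeat {
      at <- sample(seq_len(length(rest) - 1L), 1L)
      at <- ((at + length(rest) %/% 2L - 1L) %% (length(rest) - 1L)) + 1L
      if (!(f$category[rest[at]] == "phage" &&
            f$category[rest[at + 1L]] == "phage")) break
    }
    ord_b <- append(rest, ord_b[pos], after = at)
    relocated <- c(relocated, tags[seg])
  }

  # --- assemble genomes ------------------------------------------------------
  ga <- assemble_genome("genome_a", tags_a, genes_a, f$strand, f$category,
                        f$product, spacers, rep(1L, n), "a_scaffold")
  if (cfg$outgroup)
    out_og <- assemble_genome("outgroup", tags_og, og_res$genes, f$strand,
                              f$category, f$product, spacers, rep(1L, n),
                              "og_scaffold")

  # genome b: element sequence in ord_b with repeat insertions spliced in
  b_tags <- tags_b[ord_b]
  b_genes <- genes_b[ord_b]
  b_strand <- f$strand[ord_b]
  b_cat <- f$category[ord_b]
  b_prod <- f$product[ord_b]
  for (ins in rev(ins_entries)) {
    at <- match(ins$after, ord_b)
    if (is.na(at)) next
    b_tags <- append(b_tags, ins$tag, after = at)
    b_genes <- append(b_genes, list(ins$codons), after = at)
    b_strand <- append(b_strand, sample(c("+", "-"), 1L), after = at)
    b_cat <- append(b_cat, "repeat", after = at)
    b_prod <- append(b_prod, "reverse transcriptase", after = at)
  }
  nb <- length(b_genes)
  b_spacers <- vapply(rpois(nb + 1L, cfg$mean_intergenic_len), function(L)
    paste(sample(NT, L, replace = TRUE,
                 prob = c((1 - cfg$gc_content) / 2, cfg$gc_content / 2,
                          cfg$gc_content / 2, (1 - cfg$gc_content) / 2)),
          collapse = ""), character(1))
  nsc <- min(cfg$n_scaffolds_b, nb)
  scaffold_assign <- sort(rep_len(seq_len(nsc), nb))
  scaffold_order <- sprintf("b_scaffold_%02d", sample(nsc))
  gb <- assemble_genome("genome_b", b_tags, b_genes, b_strand, b_cat, b_prod,
                        b_spacers, scaffold_assign, "b_scaffold",
                        scaffold_order = scaffold_order)

  # --- truth table -----------------------------------------------------------
  events <- rbind(if (cfg$outgroup) og_res$events else NULL,
                  a_res$events, b_res$events)
  count_by <- function(evd) {
    if (nrow(evd) == 0L)
      return(data.frame(locus = character(0), syn = integer(0),
                        nonsyn = integer(0)))
    agg <- as.data.frame(table(evd$locus, evd$class))
    names(agg) <- c("locus", "class", "n")
    out <- data.frame(locus = unique(agg$locus))
    out$syn <- agg$n[match(paste(out$locus, "syn"),
                           paste(agg$locus, agg$class))] %||% 0L
    out$nonsyn <- agg$n[match(paste(out$locus, "nonsyn"),
                              paste(agg$locus, agg$class))]
    out$syn[is.na(out$syn)] <- 0L; out$nonsyn[is.na(out$nonsyn)] <- 0L
    out
  }

  # ground-truth a/b SNP accounting at ancestral coordinates (genes only;
  # structural edits excluded by comparing pre-structural codon states)
  diffs <- 0L
  for (i in seq_len(n)) {
    ia <- a_res$genes[[i]]; ib <- b_res$genes[[i]]
    d <- which(ia != ib)
    if (length(d)) diffs <- diffs + sum(NDIFF_MAT[cbind(ia[d], ib[d])])
  }
  ev_a <- a_res$events; ev_b <- b_res$events
  sites_a <- unique(paste(ev_a$locus, ev_a$nt_pos))
  sites_b <- unique(paste(ev_b$locus, ev_b$nt_pos))
  overlap_correction <- (nrow(ev_a) + nrow(ev_b)) - diffs

  truth <- structure(list(
    pairing = data.frame(ancestor_locus = tags, locus_a = tags_a,
                         locus_b = ifelse(seq_len(n) %in% deleted_idx,
                                          NA_character_, tags_b),
                         locus_og = if (cfg$outgroup) tags_og else
                           NA_character_,
                         category = f$category,
                         omega_target = omega_gene,
                         stringsAsFactors = FALSE),
    events = events,
    counts_a = count_by(a_res$events),
    counts_b = count_by(b_res$events),
    snp_accounting = list(events_a = nrow(ev_a), events_b = nrow(ev_b),
                          distinct_sites_a = length(sites_a),
                          distinct_sites_b = length(sites_b),
                          snp_total_truth = diffs,
                          overlap_correction = overlap_correction),
    deleted = tags[deleted_idx],
    deleted_b_tags = tags_b[deleted_idx],
    regions = do.call(rbind, regions_truth) %||% NULL,
    fragmented = do.call(rbind, frag_truth) %||%
      data.frame(locus = character(0), stop_codon = integer(0),
                 nt_start = integer(0), nt_end = integer(0)),
    inserted_repeats = do.call(rbind, inserted_truth) %||%
      data.frame(locus = character(0), after_ancestor_locus = character(0)),
    indels = do.call(rbind, indel_truth) %||%
      data.frame(locus = character(0), type = character(0),
                 length_bp = integer(0), at_codon = integer(0)),
    relocated = relocated
  ), class = "truth_table")

  structure(list(genome_a = ga, genome_b = gb, outgroup = out_og,
                 truth = truth, config = cfg), class = "sim_pair")
}

# Intergenic spacers of a single-scaffold module-built genome, as the
# n + 1 sequences between consecutive features.
.extract_spacers <- function(g) {
  f <- g$features
  if (length(g$scaffolds) != 1L)
    stopf("spacer extraction expects the single-scaffold ancestor")
  s <- g$scaffolds[[1]]
  n <- nrow(f)
  spacers <- character(n + 1L)
  prev_end <- 0L
  for (i in seq_len(n)) {
    spacers[i] <- substr(s, prev_end + 1L, f$start[i] - 1L)
    prev_end <- f$end[i]
  }
  spacers[n + 1L] <- substr(s, prev_end + 1L, nchar(s))
  spacers
}

#' Generate an ancestor and evolve a pair in one call
#'
#' @param cfg An [evolution_config()].
#' @return The [evolve_pair()] result with the ancestor attached.
#' @export
simulate_genomes <- function(cfg) {
  anc <- generate_ancestor(cfg)
  sim <- evolve_pair(anc, cfg)
  sim$ancestor <- anc
  sim
}

#' Write a simulation to disk
#'
#' Emits FASTA + GFF3 for each genome, the truth table as JSON and the
#' configuration as YAML.
#'
#' @param sim A `sim_pair` from [evolve_pair()] or [simulate_genomes()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gs <- Filter(Negate(is.null),
               list(ancestor = sim$ancestor, genome_a = sim$genome_a,
                    genome_b = sim$genome_b, outgroup = sim$outgroup))
  for (nm in names(gs))
    write_genome(gs[[nm]], file.path(dir, paste0(nm, ".fasta")),
                 file.path(dir, paste0(nm, ".gff3")))
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  cfg <- sim$config
  cfg$omega_by_class <- as.list(cfg$omega_by_class)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
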