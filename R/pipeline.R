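# End-to-end orchestration: (simulate | load) -> orthologs -> divergence ->
# selection screen -> phage inventory -> synteny, with per-stage outputs on
# disk and a consolidated JSON report. The report contains no timestamps,
# so a rerun under the same seed reproduces it byte for byte.

#' Pipeline configuration
#'
#' Exactly one of `genomes` (paths to reference/target, optionally
#' outgroup) or `simulation` (an [evolution_config()]) must be supplied.
#'
#' @param genomes `NULL`, or a list with elements `reference`, `target`
#'   and optionally `outgroup`, each `c(fasta = ..., annotation = ...)`.
#' @param simulation `NULL` or an [evolution_config()].
#' @param out_dir Output directory.
#' @param clock A [clock_model()].
#' @param screen A [screen_config()].
#' @param min_identity,min_coverage Homology thresholds for
#'   [reciprocal_best_hits()] / [find_missing_genes()].
#' @param gap_tolerance Repeat-interruption tolerance for
#'   [delineate_regions()].
#' @param min_codons Per-gene alignment-length floor for [gene_ka_ks()].
#' @param seed Integer seed for the run's RNG stream.
#' @param force Overwrite an existing `out_dir`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genomes = NULL, simulation = NULL,
                            out_dir = tempfile("orthodiverge_run_"),
                            clock = clock_model(),
                            screen = screen_config(),
                            min_identity = 60, min_coverage = 0.5,
                            gap_tolerance = 2L, min_codons = 30L,
                            seed = 1L, force = FALSE) {
  if (is.null(genomes) == is.null(simulation))
    stopf("supply exactly one of `genomes` or `simulation`")
  structure(list(genomes = genomes, simulation = simulation,
                 out_dir = out_dir, clock = clock, screen = screen,
                 min_identity = min_identity, min_coverage = min_coverage,
                 gap_tolerance = as.integer(gap_tolerance),
                 min_codons = as.integer(min_codons),
                 seed = as.integer(seed), force = isTRUE(force)),
            class = "pipeline_config")
}

.log_stage <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

.tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full comparative pipeline
#'
#' Stages, in fixed order: obtain genomes (simulation or load), genome
#' summaries, reciprocal-best-hit orthologs, codon-level divergence and
#' clock dating, missing-gene detection, divergent/positive-selection
#' screen (with outgroup polarization of flagged genes when an outgroup is
#' available), fragmentation detection, phage-region delineation and
#' reduction report, scaffold ordering and synteny blocks. Every stage's
#' tables are written under `cfg$out_dir`; the consolidated report is
#' `report.json`. A stage failure stops the run with the stage named;
#' earlier outputs are retained.
#'
#' @param cfg A [pipeline_config()].
#' @return The consolidated report, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stopf("not a pipeline_config")
  if (dir.exists(cfg$out_dir) && !cfg$force &&
      length(dir(cfg$out_dir)))
    stopf("output directory %s exists; use force = TRUE", cfg$out_dir)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  cat("", file = log_path)
  set.seed(cfg$seed)

  stage <- function(name, expr) {
    .log_stage(log_path, name, "start")
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  outgroup <- NULL
  truth <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- stage("simulate", {
      s <- simulate_genomes(cfg$simulation)
      write_simulation(s, file.path(cfg$out_dir, "simulation"))
      s
    })
    reference <- sim$genome_a; target <- sim$genome_b
    outgroup <- sim$outgroup; truth <- sim$truth
  } else {
    reference <- stage("load_reference",
      load_genome(cfg$genomes$reference[["fasta"]],
                  cfg$genomes$reference[["annotation"]]))
    target <- stage("load_target",
      load_genome(cfg$genomes$target[["fasta"]],
                  cfg$genomes$target[["annotation"]]))
    if (!is.null(cfg$genomes$outgroup))
      outgroup <- stage("load_outgroup",
        load_genome(cfg$genomes$outgroup[["fasta"]],
                    cfg$genomes$outgroup[["annotation"]]))
  }

  summaries <- stage("genome_summary", {
    s <- rbind(genome_summary(reference), genome_summary(target))
    .tsv(s, file.path(cfg$out_dir, "genome_summary.tsv"))
    s
  })

  map <- stage("orthologs", {
    m <- reciprocal_best_hits(reference, target,
                              min_identity = cfg$min_identity,
                              min_coverage = cfg$min_coverage)
    .tsv(m$pairs[, c("locus_a", "locus_b", "score", "identity", "coverage",
                     "len_a", "len_b")],
         file.path(cfg$out_dir, "orthologs.tsv"))
    m
  })

  div <- stage("divergence", {
    d <- genome_wide_divergence(map, min_codons = cfg$min_codons)
    .tsv(d$per_gene, file.path(cfg$out_dir, "divergence_per_gene.tsv"))
    d
  })
  dating <- estimate_divergence_time(div$ks_percent, cfg$clock)

  missing <- stage("missing_genes", {
    mg <- find_missing_genes(reference, target,
                             min_identity = cfg$min_identity,
                             min_coverage = cfg$min_coverage)
    .tsv(mg, file.path(cfg$out_dir, "missing_genes.tsv"))
    mg
  })

  screened <- stage("screen", {
    s <- screen_divergent_genes(map, cfg$screen, summaries = div$per_gene)
    .tsv(s, file.path(cfg$out_dir, "screened_genes.tsv"))
    s
  })
  flags_sel <- flag_positive_selection(div$per_gene, cfg$screen)

  polarization <- NULL
  if (!is.null(outgroup) && nrow(flags_sel$flagged)) {
    polarization <- stage("polarize", {
      og_map <- reciprocal_best_hits(reference, outgroup,
                                     min_identity = cfg$min_identity,
                                     min_coverage = cfg$min_coverage)
      og_of <- setNames(og_map$pairs$locus_b, og_map$pairs$locus_a)
      rows <- lapply(seq_len(nrow(flags_sel$flagged)), function(i) {
        la <- flags_sel$flagged$locus_a[i]
        lb <- flags_sel$flagged$locus_b[i]
        og_tag <- og_of[la]
        pr <- polarize_with_outgroup(reference$cds[[la]], target$cds[[lb]],
                                     if (is.na(og_tag)) NULL else
                                       outgroup$cds[[og_tag]])
        data.frame(locus_a = la, locus_b = lb,
                   locus_og = unname(og_tag),
                   diverged_sites = pr$diverged_sites,
                   matches_outgroup_a = pr$matches_outgroup_a,
                   matches_outgroup_b = pr$matches_outgroup_b,
                   unpolarizable = pr$unpolarizable,
                   derived_enriched = pr$derived_enriched,
                   stringsAsFactors = FALSE)
      })
      p <- do.call(rbind, rows)
      .tsv(p, file.path(cfg$out_dir, "polarization.tsv"))
      p
    })
  }

  events <- stage("fragmentation",
                  detect_fragmentation(map, reference, target))

  phage <- stage("phage_regions", {
    phage_loci <- reference$features$locus_tag[
      reference$features$category == "phage"]
    fl <- label_phage_homologs(target, phage_loci, map, fragments = events)
    ord <- order_scaffolds_by_reference(target, map, reference)
    regs <- delineate_regions(target, fl, gap_tolerance = cfg$gap_tolerance,
                              scaffold_order = ord, reference = reference)
    red <- reduction_report(reference, target, map, events = events,
                            missing = missing)
    .tsv(red$regions, file.path(cfg$out_dir, "reduction_regions.tsv"))
    list(flags = fl, scaffold_order = ord, regions = regs, reduction = red)
  })

  blocks <- stage("synteny", {
    b <- synteny_blocks(map, reference, target,
                        scaffold_order = phage$scaffold_order)
    .tsv(synteny_summary(b), file.path(cfg$out_dir, "synteny_blocks.tsv"))
    b
  })

  n_pairs <- nrow(map$pairs)
  report <- list(
    config = list(seed = cfg$seed,
                  min_identity = cfg$min_identity,
                  min_coverage = cfg$min_coverage,
                  gap_tolerance = cfg$gap_tolerance,
                  min_codons = cfg$min_codons,
                  clock_rate_percent_per_myr = cfg$clock$rate_percent_per_myr,
                  identity_threshold = cfg$screen$identity_threshold,
                  omega_threshold = cfg$screen$omega_threshold,
                  simulated = !is.null(cfg$simulation)),
    genome_summaries = summaries,
    orthologs = list(
      n_pairs = n_pairs,
      n_unpaired_reference = length(map$unpaired_a),
      n_unpaired_target = length(map$unpaired_b),
      n_ambiguous = nrow(map$ambiguous),
      frac_pairs_ge99_identity = if (n_pairs) mean(map$pairs$identity >= 99)
                                 else NA_real_),
    divergence = list(
      n_genes_pooled = div$n_genes,
      ks_percent = div$ks_percent, ka_percent = div$ka_percent,
      omega_concat = div$omega_concat,
      snp_total = div$snp_total, syn_snp_total = div$syn_snp_total,
      syn_snp_percent = div$syn_snp_percent,
      mean_gene_omega = div$mean_gene_omega,
      divergence_time_years = dating$years_raw,
      divergence_time_years_rounded = dating$years_rounded),
    missing_genes = list(n = nrow(missing), loci = missing$locus),
    screen = list(n_divergent = nrow(screened),
                  divergent = screened,
                  n_flagged_positive = nrow(flags_sel$flagged),
                  flagged_loci = flags_sel$flagged$locus_a,
                  n_omega_undefined = nrow(flags_sel$undefined)),
    polarization = polarization,
    phage = list(
      census = phage$reduction$census,
      n_regions_detected = length(phage$regions),
      regions = lapply(phage$regions, function(r)
        r[c("region_id", "gene_count", "span_bp", "scaffold_ids",
            "reference_block")]),
      reduction = phage$reduction$regions,
      lost_span_bp = phage$reduction$lost_span_bp),
    synteny = list(n_blocks = length(blocks),
                   n_displaced = sum(vapply(blocks, `[[`, logical(1),
                                            "displaced")),
                   scaffold_order = phage$scaffold_order)
  )
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns", pretty = TRUE)
  .log_stage(log_path, "done", sprintf("report written to %s",
                                       file.path(cfg$out_dir, "report.json")))
  if (!is.null(truth)) report$truth <- truth
  report$map <- map
  invisible(report)
}
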