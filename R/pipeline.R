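#' Pipeline run configuration
#'
#' Collects paths and stage settings for \code{\link{run_cryptic_pipeline}}.
#' Referenced paths are checked before any computation starts; the seed is
#' mandatory because the delta-PSI stage is Monte-Carlo.
#'
#' @param genome Path to the genome FASTA.
#' @param gtf Path to the annotation GTF.
#' @param sample_sheet Path to the sample sheet TSV (sample_id, path,
#'   condition).
#' @param crosslinks Optional crosslink BED6 path (NULL skips the CLIP
#'   stage).
#' @param ese_list Optional ESE hexamer list path.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param alpha,n_draws,v_set,threshold,min_total PSI-stage settings (see
#'   \code{\link{delta_psi}}).
#' @param tier Confidence tier used to select events.
#' @param polya_window,polya_signals,min_asymmetry Terminal-exon settings.
#' @param clip_flank,clip_k,clip_top Crosslink window half-width, k-mer
#'   size, rows in the top-pentamer report.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(genome, gtf, sample_sheet, crosslinks = NULL,
                            ese_list = NULL, out_dir = "cryptic_out",
                            seed = 1L, alpha = 1, n_draws = 10000L,
                            v_set = c(0.1, 0.2), threshold = 0.95,
                            min_total = 10L, tier = "V20",
                            polya_window = 500L, polya_signals = "AATAAA",
                            min_asymmetry = 5, clip_flank = 50L,
                            clip_k = 5L, clip_top = 10L) {
  cfg <- as.list(environment())
  for (p in c("genome", "gtf", "sample_sheet")) {
    if (!file.exists(cfg[[p]])) stop("config error: missing ", p, " file: ",
                                     cfg[[p]])
  }
  for (p in c("crosslinks", "ese_list")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config error: missing ", p, " file: ", cfg[[p]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

.write_stage_tsv <- function(x, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# crypticsplice %s seed=%d",
                     as.character(utils::packageVersion("crypticsplice")),
                     seed), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the cryptic-splicing pipeline end to end
#'
#' Stages: quantify (LSV definition, PSI/delta-PSI with high-confidence
#' calling) -> classify (event taxonomy incl. terminal-exon detection) ->
#' impact (reading-frame consequences) -> strength (splice-site percentile
#' and ESE comparison for cryptic exons) -> clip (pentamer enrichment vs
#' dinucleotide-shuffled controls and region annotation; optional) ->
#' report. Every stage writes a TSV with a provenance header; a JSON run
#' manifest records the seed, settings and stage counts.
#'
#' @param config A \code{pipeline_config}.
#' @return Invisibly, a list with all stage results (\code{calls},
#'   \code{events}, \code{impacts}, \code{strength}, \code{clip},
#'   \code{report}).
#' @export
run_cryptic_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- read_genome_fasta(config$genome)
  graph <- read_annotation_gtf(config$gtf)
  table <- read_sj_samples(config$sample_sheet, graph)

  calls <- call_delta_psi(graph, table, v_set = config$v_set,
                          n_draws = config$n_draws, alpha = config$alpha,
                          threshold = config$threshold, seed = config$seed,
                          min_total = config$min_total)
  .write_stage_tsv(calls, file.path(config$out_dir, "delta_psi_calls.tsv"),
                   config$seed)

  terminal_cfg <- list(window_nt = config$polya_window,
                       signal_set = config$polya_signals,
                       min_ratio = config$min_asymmetry)
  events <- classify_events(calls, graph, genome, table,
                            tier = config$tier, terminal_cfg = terminal_cfg)
  .write_stage_tsv(events, file.path(config$out_dir, "events.tsv"),
                   config$seed)

  impacts <- assess_events(events, graph, genome)
  .write_stage_tsv(impacts, file.path(config$out_dir, "orf_impact.tsv"),
                   config$seed)

  ese_set <- if (!is.null(config$ese_list)) read_ese_list(config$ese_list)
    else character(0)
  strength <- NULL
  if (length(ese_set) &&
      any(events$class %in% c("cryptic_internal_exon",
                              "cryptic_terminal_exon"))) {
    strength <- compare_cryptic_vs_downstream(events, graph, genome,
                                              ese_set = ese_set)
    .write_stage_tsv(strength$per_event,
                     file.path(config$out_dir, "site_strength.tsv"),
                     config$seed)
    if (!is.null(strength$tests)) {
      .write_stage_tsv(strength$tests,
                       file.path(config$out_dir, "site_strength_tests.tsv"),
                       config$seed)
    }
  }

  clip <- NULL
  if (!is.null(config$crosslinks)) {
    sites <- read_bed(config$crosslinks)
    windows <- extract_windows(sites, genome, config$clip_flank)
    ctrl <- control_windows(windows, "dinucleotide_shuffle",
                            seed = config$seed)
    enr <- enrichment_vs_control(
      kmer_window_fractions(windows, config$clip_k),
      kmer_window_fractions(ctrl, config$clip_k),
      n_obs = length(windows), n_ctrl = length(ctrl))
    regions <- annotate_region(sites, graph)
    region_tab <- as.data.frame(table(region = regions),
                                responseName = "n")
    clip <- list(enrichment = enr, regions = region_tab)
    .write_stage_tsv(enr, file.path(config$out_dir, "clip_enrichment.tsv"),
                     config$seed)
    .write_stage_tsv(region_tab,
                     file.path(config$out_dir, "clip_regions.tsv"),
                     config$seed)
  }

  rep <- pipeline_report(events, impacts, strength, clip,
                         top_k = config$clip_top)
  .write_stage_tsv(rep$event_proportions,
                   file.path(config$out_dir, "event_proportions.tsv"),
                   config$seed)
  manifest <- list(
    seed = config$seed,
    settings = unclass(config)[setdiff(names(config), "out_dir")],
    counts = list(junctions = nrow(table$junctions),
                  lsv_calls = length(unique(calls$lsv_id)),
                  high_confidence = sum(calls$tier != "none"),
                  tier_v20 = sum(calls$tier == "V20"),
                  events = nrow(events),
                  events_per_class = as.list(table(events$class))),
    disruptive_fraction = rep$disruptive_fraction)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(calls = calls, events = events, impacts = impacts,
                 strength = strength, clip = clip, report = rep,
                 graph = graph, genome = genome, table = table))
}

#' Summarise pipeline outputs
#'
#' Produces the event-class proportion table, the fraction of cryptic
#' internal exons whose splicing would disrupt the reading frame, the
#' splice-site strength comparison summary and the top-k pentamer table
#' with AA-dinucleotide flags. When no CLIP input was supplied the clip
#' section is marked absent rather than reported as empty-zero.
#'
#' @param events data.frame from \code{\link{classify_events}}.
#' @param impacts data.frame from \code{\link{assess_events}}.
#' @param strength Result of \code{\link{compare_cryptic_vs_downstream}} or
#'   NULL.
#' @param clip List with \code{enrichment} table or NULL.
#' @param top_k Rows of the pentamer table (default 10).
#' @return List: \code{event_proportions}, \code{disruptive_fraction},
#'   \code{strength_tests}, \code{top_pentamers} (or the string
#'   \code{"absent"}).
#' @export
pipeline_report <- function(events, impacts, strength = NULL, clip = NULL,
                            top_k = 10L) {
  props <- summarize_event_types(events)
  cryptic_ids <- events$event_id[events$class == "cryptic_internal_exon"]
  disr <- NA_real_
  if (length(cryptic_ids)) {
    imp <- impacts[impacts$event_id %in% cryptic_ids, , drop = FALSE]
    if (nrow(imp)) disr <- mean(imp$disruption == "disruptive")
  }
  list(event_proportions = props,
       disruptive_fraction = disr,
       strength_tests = if (is.null(strength)) "absent" else strength$tests,
       top_pentamers = if (is.null(clip)) "absent" else
         utils::head(clip$enrichment, top_k))
}
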