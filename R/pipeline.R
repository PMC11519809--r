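#' Configure a full screening run
#'
#' A run is either *simulation mode* (the default: a [simulation_config()]
#' generates the inputs, ground truth included) or *real-input mode*
#' (`inputs` names files for the count matrix, sample sheet, regional table
#' and stage table, with an optional truth file). The two modes are
#' exclusive; a partially specified `inputs` list is rejected before any
#' computation.
#'
#' @param simulation an `msz_sim_config`, used when `inputs` is `NULL`.
#' @param inputs `NULL`, or a named list with paths `counts`, `samples`,
#'   `regional`, `stages` and optionally `truth`.
#' @param scoring an `msz_scoring_params`.
#' @param selection an `msz_selection_params`.
#' @param delta_regional detection threshold of the regional screen.
#' @param delta_stage expression threshold of the marker criteria (defaults
#'   to `delta_regional`).
#' @param require_midline regional filter also requires anterior-midline
#'   detection (see [regional_specificity_filter()]).
#' @param allow_midline_at_initiation see [apply_marker_criteria()].
#' @param seed run seed; in simulation mode it overrides the simulation
#'   config's seed so one number controls the whole run.
#' @return an object of class `msz_pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            inputs = NULL,
                            scoring = scoring_params(),
                            selection = selection_params(),
                            delta_regional = 1.0,
                            delta_stage = delta_regional,
                            require_midline = FALSE,
                            allow_midline_at_initiation = FALSE,
                            seed = NULL) {
  if (!is.null(inputs)) {
    required <- c("counts", "samples", "regional", "stages")
    missing <- setdiff(required, names(inputs))
    if (length(missing) > 0L) {
      stop_field("inputs", paste0("real-input mode lacks: ",
                                  paste(missing, collapse = ", ")))
    }
    absent <- unlist(inputs[required])[!file.exists(unlist(inputs[required]))]
    if (length(absent) > 0L) {
      stop_field("inputs", paste0("file(s) not found: ",
                                  paste(absent, collapse = ", ")))
    }
  } else {
    validate_simulation_config(simulation)
  }
  stopifnot(inherits(scoring, "msz_scoring_params"),
            inherits(selection, "msz_selection_params"))
  check_scalar_number(delta_regional, "delta_regional", lower = 0)
  check_scalar_number(delta_stage, "delta_stage", lower = 0)
  if (!is.null(seed)) check_scalar_number(seed, "seed")
  structure(list(simulation = simulation, inputs = inputs,
                 scoring = scoring, selection = selection,
                 delta_regional = delta_regional, delta_stage = delta_stage,
                 require_midline = isTRUE(require_midline),
                 allow_midline_at_initiation =
                   isTRUE(allow_midline_at_initiation),
                 seed = seed),
            class = "msz_pipeline_config")
}

#' Run the whole screen: score, rank, select, localize, call markers
#'
#' Executes the cascade in order — simulate (or load) inputs, normalize,
#' score all red/white pairs, aggregate and rank, select candidates, apply
#' the six-region localization filter, apply the three stage-resolved marker
#' criteria, and (when ground truth is available) evaluate recovery. Every
#' intermediate artifact is written under `outdir`; the machine-readable
#' report excludes timestamps and hostnames so identical config + seed gives
#' a byte-identical report.
#'
#' @param config an `msz_pipeline_config`.
#' @param outdir output directory for all artifacts.
#' @param quiet suppress progress messages (they go to stderr and
#'   `run.log`).
#' @return the run report (class `msz_report`): per-stage gene counts,
#'   parameter echo, seed, stage ordering, selected/kept/marker gene ids and
#'   recovery metrics when truth is available.
#' @examples
#' cfg <- pipeline_config(simulation = simulation_config(seed = 7))
#' report <- run_pipeline(cfg, outdir = tempfile("mszrun"), quiet = TRUE)
#' report$counts_funnel
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  stopifnot(inherits(config, "msz_pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      say(stage, "ERROR: %s", conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  truth <- NULL
  if (is.null(config$inputs)) {
    sim <- config$simulation
    if (!is.null(config$seed)) sim$seed <- config$seed
    dataset <- run_stage("simulate", generate_dataset(sim))
    run_stage("simulate", write_dataset(dataset, file.path(outdir, "input")))
    counts <- dataset$counts
    sheet <- dataset$samples
    regional <- dataset$regional
    stages <- dataset$stages
    truth <- dataset$truth
    say("simulate", "%d genes x %d samples, seed %d",
        nrow(counts), ncol(counts), sim$seed)
  } else {
    counts <- run_stage("load", read_count_matrix(config$inputs$counts))
    sheet <- run_stage("load", read_sample_sheet(config$inputs$samples))
    regional <- run_stage("load", read_regional_table(config$inputs$regional))
    stages <- run_stage("load", read_stage_table(config$inputs$stages))
    if (!is.null(config$inputs$truth)) {
      truth <- run_stage("load", read_truth(config$inputs$truth))
    }
    say("load", "%d genes x %d samples", nrow(counts), ncol(counts))
  }

  abundance <- run_stage("normalize", normalize_counts(counts, config$scoring))
  pair_scores <- run_stage("score",
                           score_all_pairs(abundance, sheet, config$scoring))
  ranking <- run_stage("rank", aggregate_and_rank(pair_scores))
  readr::write_tsv(ranking, file.path(outdir, "ranking.tsv"))
  readr::write_tsv(tibble::as_tibble(pair_scores$scores,
                                     rownames = "gene_id"),
                   file.path(outdir, "pair_scores.tsv"))
  say("rank", "top gene: %s (aggregate %d)",
      ranking$gene_id[1], ranking$aggregate_score[1])

  selected <- run_stage("select",
                        select_candidates(ranking, pair_scores,
                                          config$selection))
  writeLines(selected, file.path(outdir, "selected.txt"))
  say("select", "%d candidate(s) selected", length(selected))

  presence <- run_stage("regional",
                        binarize_regions(regional, config$delta_regional))
  kept <- run_stage("regional",
                    regional_specificity_filter(presence, selected,
                                                config$require_midline))
  writeLines(kept, file.path(outdir, "regional_kept.txt"))
  say("regional", "%d candidate(s) localized to the anterior PS",
      length(kept))

  calls <- run_stage("criteria",
                     apply_marker_criteria(stages, kept, config$delta_stage,
                                           config$allow_midline_at_initiation))
  readr::write_csv(calls, file.path(outdir, "marker_calls.csv"))
  markers <- calls$gene_id[calls$is_marker]
  writeLines(markers, file.path(outdir, "markers.txt"))
  say("criteria", "%d marker(s) called", length(markers))

  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- run_stage("evaluate", evaluate_recovery(calls, truth))
    jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("evaluate", "precision %.3f, recall %.3f",
        metrics$precision, metrics$recall)
  }

  report <- list(
    stage_order = c("simulate/load", "normalize", "score", "rank", "select",
                    "regional", "criteria", "evaluate"),
    seed = if (is.null(config$inputs)) {
      config$seed %||% config$simulation$seed
    } else {
      config$seed
    },
    counts_funnel = list(
      n_input = nrow(counts),
      n_after_selection = length(selected),
      n_after_regional = length(kept),
      n_markers = length(markers)
    ),
    parameters = list(
      scoring = unclass(config$scoring),
      selection = unclass(config$selection),
      delta_regional = config$delta_regional,
      delta_stage = config$delta_stage,
      require_midline = config$require_midline,
      allow_midline_at_initiation = config$allow_midline_at_initiation,
      simulation = if (is.null(config$inputs)) {
        utils::modifyList(unclass(config$simulation), list(seed = NULL))
      }
    ),
    selected = selected,
    regional_kept = kept,
    markers = markers,
    metrics = metrics
  )
  class(report) <- "msz_report"
  jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done", "report written to %s", file.path(outdir, "report.json"))
  report
}

#' @export
print.msz_report <- function(x, ...) {
  f <- x$counts_funnel
  cat("<msz_report>\n")
  cat(sprintf("  genes in: %d -> selected: %d -> localized: %d -> markers: %d\n",
              f$n_input, f$n_after_selection, f$n_after_regional,
              f$n_markers))
  if (!is.null(x$metrics)) {
    cat(sprintf("  recovery: precision %.3f, recall %.3f\n",
                x$metrics$precision, x$metrics$recall))
  }
  invisible(x)
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments; `simulation`,
#' `scoring` and `selection` are nested maps passed to their constructors.
#'
#' @param path YAML file.
#' @return an `msz_pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  to_named <- function(x) if (is.list(x)) unlist(x) else x
  sim_args <- raw$simulation %||% list()
  for (f in c("class_counts", "dispersion_by_method",
              "dropout_prob_by_method", "contamination_by_method",
              "depth_factor_by_method")) {
    if (!is.null(sim_args[[f]])) sim_args[[f]] <- to_named(sim_args[[f]])
  }
  pipeline_config(
    simulation = do.call(simulation_config, sim_args),
    inputs = raw$inputs,
    scoring = do.call(scoring_params, raw$scoring %||% list()),
    selection = do.call(selection_params, raw$selection %||% list()),
    delta_regional = raw$delta_regional %||% 1.0,
    delta_stage = raw$delta_stage %||% raw$delta_regional %||% 1.0,
    require_midline = raw$require_midline %||% FALSE,
    allow_midline_at_initiation = raw$allow_midline_at_initiation %||% FALSE,
    seed = raw$seed
  )
}
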