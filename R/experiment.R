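# Experiment runner: YAML configuration tying the cohort, the network and the
# evaluation protocol together, with full seed/hash provenance in every
# artifact. The command-line entry point (inst/cli/thcnet.R) is a thin wrapper
# over run_generate(), run_sweep() and run_report().

#' Load an experiment configuration
#'
#' The YAML file has three blocks: `cohort` (either the synthetic generator
#' parameters or `volume_dir`/`clinical_csv` paths to real data -- exactly one
#' of the two), `network` (any [network_config()] field) and `evaluation`
#' (`alphas`, `k`, `seed`), plus `output_dir`.
#'
#' @param path YAML file path, or a list already in that shape.
#' @return An `experiment_config` object.
#' @export
load_experiment_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  cohort <- raw$cohort %||% list()
  synthetic <- is.null(cohort$volume_dir)
  if (!synthetic && !is.null(cohort$n_patients)) {
    stop("cohort block must be synthetic parameters XOR real-data paths")
  }
  ev <- raw$evaluation %||% list()
  cfg <- list(
    cohort = cohort,
    synthetic = synthetic,
    network = raw$network %||% list(),
    alphas = unlist(ev$alphas) %||% seq(0.1, 3.9, by = 0.2),
    k = ev$k %||% 5L,
    seed = ev$seed %||% 1L,
    output_dir = raw$output_dir %||% "thcnet_output"
  )
  structure(cfg, class = "experiment_config")
}

.build_cohort <- function(ecfg) {
  if (ecfg$synthetic) {
    args <- ecfg$cohort
    if (!is.null(args$volume_shape)) args$volume_shape <- unlist(args$volume_shape)
    generate_cohort(do.call(cohort_config, args))
  } else {
    read_cohort(ecfg$cohort$volume_dir)
  }
}

.build_network_config <- function(ecfg, cohort) {
  args <- ecfg$network
  if (is.null(args$volume_shape)) args$volume_shape <- dim(cohort[[1]]$volume)
  args$volume_shape <- unlist(args$volume_shape)
  do.call(network_config, args)
}

#' Generate a synthetic cohort and write it to disk
#'
#' @param config Path to a YAML experiment configuration, or an equivalent
#'   list/`experiment_config`.
#' @return The output directory, invisibly.
#' @export
run_generate <- function(config) {
  ecfg <- if (inherits(config, "experiment_config")) config else
    load_experiment_config(config)
  if (!ecfg$synthetic) stop("run_generate() needs a synthetic cohort block")
  cohort <- .build_cohort(ecfg)
  message(sprintf("generated %d patients -> %s", length(cohort),
                  ecfg$output_dir))
  write_cohort(cohort, ecfg$output_dir)
}

#' Train a single model and write its checkpoint and training log
#'
#' Trains the multitask network on the configured cohort at the configured
#' `alpha`, then writes `model.json` (checkpoint with the configuration
#' embedded) and `training_log.jsonl` (one JSON object per epoch: epoch, rec,
#' pred, total) into the output directory.
#'
#' @inheritParams run_generate
#' @return The trained model, invisibly.
#' @export
run_train <- function(config) {
  ecfg <- if (inherits(config, "experiment_config")) config else
    load_experiment_config(config)
  cohort <- .build_cohort(ecfg)
  net_cfg <- .build_network_config(ecfg, cohort)
  message(sprintf("training on %d patients (alpha = %g, %d epochs)",
                  length(cohort), net_cfg$alpha, net_cfg$epochs))
  model <- fit_recurrence_model(cohort, net_cfg)
  dir.create(ecfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  save_model(model, file.path(ecfg$output_dir, "model.json"))
  write_training_log(model, file.path(ecfg$output_dir, "training_log.jsonl"))
  invisible(model)
}

#' Write a model's training log as JSON lines
#'
#' @param model A trained `thc_model`.
#' @param path Output file (one JSON object per epoch).
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  log <- model$training_log
  if (is.null(log)) stop("model has no training log")
  lines <- vapply(seq_len(nrow(log)), function(i) {
    as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                  digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full alpha sweep experiment
#'
#' Builds (or reads) the cohort, splits it into `k` folds once, cross-validates
#' the network at every requested alpha plus the Shannon baseline, and writes
#' `sweep_report.json` and `sweep_report.csv` (plus incremental partial
#' results) into the output directory.
#'
#' @inheritParams run_generate
#' @return The `alpha_sweep_report`, invisibly.
#' @export
run_sweep <- function(config) {
  ecfg <- if (inherits(config, "experiment_config")) config else
    load_experiment_config(config)
  cohort <- .build_cohort(ecfg)
  net_cfg <- .build_network_config(ecfg, cohort)
  split <- kfold_split(length(cohort), ecfg$k, seed = ecfg$seed)
  dir.create(ecfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("sweeping %d alpha values over %d folds (n = %d)",
                  length(ecfg$alphas), ecfg$k, length(cohort)))
  report <- alpha_sweep(cohort, net_cfg, ecfg$alphas, split,
                        out_dir = ecfg$output_dir)
  attr(report, "config_hash") <- config_hash(unclass(ecfg))
  write_sweep_report(report, file.path(ecfg$output_dir, "sweep_report.json"))
  utils::write.csv(as.data.frame(report),
                   file.path(ecfg$output_dir, "sweep_report.csv"),
                   row.names = FALSE)
  writeLines(format_sweep_report(report),
             file.path(ecfg$output_dir, "sweep_report.txt"))
  invisible(report)
}

#' Render one or more sweep reports side by side
#'
#' @param paths Character vector of `sweep_report.json` paths (at least one).
#' @return Character vector of table lines, invisibly; also printed.
#' @export
run_report <- function(paths) {
  if (length(paths) < 1L) stop("at least one report path is required")
  blocks <- lapply(paths, function(p) {
    c(sprintf("== %s ==", p), format_sweep_report(read_sweep_report(p)), "")
  })
  lines <- unlist(blocks)
  cat(lines, sep = "\n")
  invisible(lines)
}
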