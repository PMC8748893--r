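# Problem and results I/O. Data interchange is PEtab-flavoured TSV
# (conditions, measurements, parameters) plus a small problem YAML and a
# ground-truth JSON for synthetic problems. Results are stored as plain-text
# per-start trace TSVs with a JSON metadata sidecar and one TSV summary --
# everything re-loadable into the same in-memory structures.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

model_from_descriptor <- function(desc) {
  switch(desc$type,
    cascade = build_cascade_model(cascade_spec(desc$n_layers,
                                               unlist(desc$observed),
                                               desc$readout %||% "per_layer")),
    viability = generate_viability_dataset(n_cell_lines = 1, n_drugs = desc$n_drugs,
                                           n_doses = 1, seed = 1,
                                           noise = FALSE)$model,
    yaml = model_from_yaml(desc$path),
    stop_config("unknown model descriptor type '%s'", desc$type %||% "?")
  )
}

#' Write a calibration problem to disk
#'
#' Emits `conditions.tsv`, `measurements.tsv`, `parameters.tsv`,
#' `problem.yaml` (with a model descriptor that [load_problem()] can
#' rebuild), and `ground_truth.json` when the problem carries a truth.
#'
#' @param problem a [calib_problem()] carrying a model descriptor (generator
#'   output does).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_problem <- function(problem, dir) {
  if (is.null(problem$descriptor)) {
    stop_config("problem carries no serializable model descriptor")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(problem$conditions, file.path(dir, "conditions.tsv"))
  write_tsv(problem$measurements, file.path(dir, "measurements.tsv"))
  pars <- data.frame(
    parameterId = problem$model$parameter_names,
    lowerBound = 10^problem$space$lower,
    upperBound = 10^problem$space$upper,
    parameterScale = "log10",
    nominalValue = if (!is.null(problem$theta_true))
      as.numeric(problem$theta_true) else 10^((problem$space$lower +
                                                 problem$space$upper) / 2),
    estimate = 1L
  )
  write_tsv(pars, file.path(dir, "parameters.tsv"))
  yaml::write_yaml(list(
    name = problem$name,
    model = problem$descriptor,
    condition_file = "conditions.tsv",
    measurement_file = "measurements.tsv",
    parameter_file = "parameters.tsv",
    scale_observables = as.list(problem$scale_observables)
  ), file.path(dir, "problem.yaml"))
  gt <- list()
  if (!is.null(problem$theta_true)) {
    gt$theta_true <- as.list(stats::setNames(as.numeric(problem$theta_true),
                                             problem$model$parameter_names))
  }
  labels <- attr(problem, "labels")
  if (!is.null(labels)) gt$labels <- labels
  if (length(gt)) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a calibration problem from disk
#'
#' Reads a `problem.yaml` bundle as written by [write_problem()] (or
#' hand-assembled in the same layout), validates the tables, and returns a
#' [calib_problem()]. Measurement rows referencing unknown conditions or
#' observables, and non-positive noise SDs, are rejected with row numbers.
#'
#' @param dir directory containing `problem.yaml`.
#' @return a [calib_problem()].
#' @export
load_problem <- function(dir) {
  yml <- file.path(dir, "problem.yaml")
  if (!file.exists(yml)) stop_config("no problem.yaml in '%s'", dir)
  spec <- yaml::read_yaml(yml)
  desc <- spec$model
  if (identical(desc$type, "yaml") && !is.null(desc$path)) {
    desc$path <- file.path(dir, desc$path)
  }
  model <- model_from_descriptor(desc)
  conditions <- read_tsv(file.path(dir, spec$condition_file %||% "conditions.tsv"))
  measurements <- read_tsv(file.path(dir, spec$measurement_file %||% "measurements.tsv"))
  pars <- read_tsv(file.path(dir, spec$parameter_file %||% "parameters.tsv"))
  pars <- pars[match(model$parameter_names, pars$parameterId), ]
  theta_true <- NULL
  gt_path <- file.path(dir, "ground_truth.json")
  labels <- NULL
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    if (!is.null(gt$theta_true)) {
      theta_true <- stats::setNames(as.numeric(unlist(gt$theta_true)),
                                    names(gt$theta_true))
    }
    labels <- gt$labels
  }
  problem <- calib_problem(
    model, conditions, measurements,
    lower = log10(pars$lowerBound), upper = log10(pars$upperBound),
    scale_observables = unlist(spec$scale_observables) %||% character(),
    theta_true = theta_true, name = spec$name %||% basename(dir)
  )
  problem$descriptor <- spec$model
  if (!is.null(labels)) attr(problem, "labels") <- labels
  problem
}

history_trace_df <- function(h) {
  df <- data.frame(step = seq_len(h$n_steps), epoch = h$epoch,
                   eta = h$eta, step_scale = h$step_scale,
                   J_batch = h$J_batch, n_records = h$n_records,
                   ls_trials = h$ls_trials, rescue_retries = h$rescue_retries,
                   cost = h$cost)
  cbind(df, as.data.frame(h$theta))
}

#' Persist multi-start results
#'
#' Writes `summary.tsv` (one row per start: final whole-dataset objective,
#' Pearson r, RMSE, termination reason, simulation cost), one
#' `traces/start_NNN.tsv` per start (per-step parameters, objective
#' estimates, learning rates, step-scale, rescue/line-search event counts)
#' plus a JSON metadata sidecar, and `epochs/start_NNN.tsv` when full-dataset
#' epoch tracking was on. [read_results()] reconstructs the histories.
#'
#' @param result a `multistart_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$finals, file.path(dir, "summary.tsv"))
  for (i in seq_along(result$histories)) {
    h <- result$histories[[i]]
    write_tsv(history_trace_df(h),
              file.path(dir, "traces", sprintf("start_%03d.tsv", i)))
    meta <- list(kind = h$kind, algorithm = h$algorithm,
                 batch_size = h$batch_size, steps_per_epoch = h$steps_per_epoch,
                 epochs_requested = h$epochs_requested,
                 termination = h$termination, total_cost = h$total_cost,
                 n_total_records = h$n_total_records, seed = h$seed,
                 final_theta = as.numeric(h$final_theta),
                 final_metrics = h$final_metrics[c("J_full", "J_full_nll",
                                                   "pearson_r", "rmse")])
    jsonlite::write_json(meta,
                         file.path(dir, "traces", sprintf("start_%03d.json", i)),
                         auto_unbox = TRUE, digits = NA)
    if (!is.null(h$epoch_full)) {
      dir.create(file.path(dir, "epochs"), showWarnings = FALSE)
      write_tsv(h$epoch_full,
                file.path(dir, "epochs", sprintf("start_%03d.tsv", i)))
    }
  }
  invisible(dir)
}

#' Reload multi-start results
#'
#' @param dir directory written by [write_results()].
#' @return a `multistart_result` (histories carry everything the ensemble
#'   and convergence tooling needs).
#' @export
read_results <- function(dir) {
  finals <- read_tsv(file.path(dir, "summary.tsv"))
  trace_files <- sort(list.files(file.path(dir, "traces"), "^start_\\d+\\.tsv$",
                                 full.names = TRUE))
  histories <- lapply(trace_files, function(tf) {
    df <- read_tsv(tf)
    meta <- jsonlite::read_json(sub("\\.tsv$", ".json", tf),
                                simplifyVector = TRUE)
    theta_cols <- setdiff(names(df), c("step", "epoch", "eta", "step_scale",
                                       "J_batch", "n_records", "ls_trials",
                                       "rescue_retries", "cost"))
    ef_path <- file.path(dir, "epochs", basename(tf))
    structure(list(
      theta = as.matrix(df[, theta_cols, drop = FALSE]),
      J_batch = df$J_batch, n_records = df$n_records, eta = df$eta,
      step_scale = df$step_scale, epoch = df$epoch,
      ls_trials = df$ls_trials, rescue_retries = df$rescue_retries,
      cost = df$cost, n_steps = nrow(df),
      kind = meta$kind, algorithm = meta$algorithm,
      batch_size = meta$batch_size, steps_per_epoch = meta$steps_per_epoch,
      epochs_requested = meta$epochs_requested,
      final_theta = as.numeric(meta$final_theta),
      final_metrics = meta$final_metrics,
      termination = meta$termination, total_cost = meta$total_cost,
      n_total_records = meta$n_total_records, seed = meta$seed,
      epoch_full = if (file.exists(ef_path)) read_tsv(ef_path) else NULL
    ), class = "mb_history")
  })
  structure(list(histories = histories, finals = finals, starts = NULL,
                 runner = histories[[1]]$kind %||% "minibatch", seed = NA),
            class = "multistart_result")
}
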