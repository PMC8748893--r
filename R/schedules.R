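# Learning-rate schedules. The benchmark protocol uses four presets:
#   1: high,   log-decreasing 1e0  -> 1e-3
#   2: medium, log-decreasing 1e-1 -> 1e-4
#   3: low,    log-decreasing 1e-2 -> 1e-5
#   4: constant 1e-3
# "Logarithmically decreasing" means geometric interpolation between the two
# endpoints over the run.

#' Create a learning-rate schedule
#'
#' @param mode `"log_decreasing"` (geometric interpolation from `eta_start`
#'   to `eta_end` over the run) or `"constant"`.
#' @param eta_start,eta_end learning-rate endpoints (`eta_end` ignored for
#'   constant schedules).
#' @return object of class `lr_schedule`.
#' @seealso [schedule_preset()], [schedule_eta()]
#' @export
lr_schedule <- function(mode = c("log_decreasing", "constant"),
                        eta_start, eta_end = eta_start) {
  mode <- match.arg(mode)
  stopifnot(eta_start > 0, eta_end > 0)
  structure(list(mode = mode, eta_start = eta_start, eta_end = eta_end),
            class = "lr_schedule")
}

#' The four benchmark schedule presets
#'
#' @param id integer 1-4.
#' @return an [lr_schedule()].
#' @export
schedule_preset <- function(id) {
  switch(as.character(id),
    "1" = lr_schedule("log_decreasing", 1e0, 1e-3),
    "2" = lr_schedule("log_decreasing", 1e-1, 1e-4),
    "3" = lr_schedule("log_decreasing", 1e-2, 1e-5),
    "4" = lr_schedule("constant", 1e-3),
    stop_config("unknown schedule preset '%s'", id)
  )
}

#' Learning rate at a given step
#'
#' @param schedule an [lr_schedule()].
#' @param r step index, 0-based (step 0 gets `eta_start`).
#' @param total_steps total number of optimization steps in the run; the last
#'   step (`r = total_steps - 1`) gets exactly `eta_end`. Degenerate runs
#'   (`total_steps < 2`) return `eta_start`.
#' @return the learning rate `eta_r`.
#' @export
schedule_eta <- function(schedule, r, total_steps) {
  if (schedule$mode == "constant" || total_steps < 2) {
    return(schedule$eta_start)
  }
  frac <- r / (total_steps - 1)
  schedule$eta_start * (schedule$eta_end / schedule$eta_start)^frac
}

#' Suggest a starting learning rate from the step-size heuristic
#'
#' Adaptive optimizers (RMSProp, Adam) produce update directions with norm
#' close to `sqrt(n_theta)` under persistent gradients, so an initial step
#' size of `kappa * sqrt(n_theta)` translates to `eta_start = kappa`. For
#' plain SGD/momentum the update norm equals the gradient norm, so a gradient
#' scale estimate is needed. `kappa` in \[0.01, 0.1\] is a reasonable first
#' choice, with smaller values for larger models.
#'
#' @param n_theta number of estimated parameters.
#' @param kappa step-size coefficient.
#' @param algorithm optimizer the schedule is intended for.
#' @param grad_norm gradient-norm estimate, used for `"sgd"`/`"momentum"`.
#' @param decades how many powers of ten the schedule decreases over.
#' @return an [lr_schedule()].
#' @export
suggest_schedule <- function(n_theta, kappa = 0.05,
                             algorithm = c("adam", "adam_balanced", "rmsprop",
                                           "sgd", "momentum"),
                             grad_norm = 1, decades = 3) {
  algorithm <- match.arg(algorithm)
  stopifnot(kappa > 0)
  target_step <- kappa * sqrt(n_theta)
  delta_norm <- if (algorithm %in% c("sgd", "momentum")) grad_norm else sqrt(n_theta)
  eta0 <- target_step / delta_norm
  lr_schedule("log_decreasing", eta0, eta0 * 10^(-decades))
}
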