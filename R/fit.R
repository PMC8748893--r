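#' Calibrate an ODE model by multi-start mini-batch optimization
#'
#' The main fitting entry point: samples start points uniformly in the log10
#' parameter box, runs one local mini-batch optimization per start (or the
#' full-batch quasi-Newton reference), and returns a fit object carrying the
#' best parameter estimate, all per-start histories and whole-dataset
#' metrics.
#'
#' @inheritParams run_minibatch
#' @param n_starts number of local optimizations (benchmark default 100).
#' @param runner `"minibatch"` (default) or `"fullbatch"`.
#' @param ... further arguments to [run_minibatch()] /
#'   [run_fullbatch_reference()].
#' @return object of class `mb_fit` with methods `print`, `summary`, `coef`
#'   (best estimate, log10 or linear scale), `plot` (waterfall of final
#'   objective values), `predict` (simulated observables per condition),
#'   `residuals` (weighted residuals at the best estimate) and `logLik`.
#' @examples
#' \donttest{
#' prob <- generate_dataset("fujita_like", seed = 1, n_conditions = 20)
#' fit <- mb_calibrate(prob, epochs = 5, batch_size = 5, n_starts = 2, seed = 1)
#' coef(fit)
#' }
#' @export
mb_calibrate <- function(problem, algorithm = "adam_balanced",
                         schedule = schedule_preset(2), batch_size = 30,
                         epochs = 50, n_starts = 100, seed = 1,
                         runner = c("minibatch", "fullbatch"), ...) {
  runner <- match.arg(runner)
  ms <- if (runner == "minibatch") {
    run_multistart(problem, n_starts = n_starts, seed = seed,
                   runner = "minibatch", algorithm = algorithm,
                   schedule = schedule, batch_size = batch_size,
                   epochs = epochs, ...)
  } else {
    run_multistart(problem, n_starts = n_starts, seed = seed,
                   runner = "fullbatch", ...)
  }
  ok <- which(is.finite(ms$finals$J_full))
  best <- if (length(ok)) ok[which.min(ms$finals$J_full[ok])] else NA_integer_
  structure(list(problem = problem, multistart = ms, best_start = best,
                 algorithm = if (runner == "minibatch") algorithm else "lbfgsb",
                 runner = runner, seed = seed),
            class = "mb_fit")
}

best_history <- function(object) {
  if (is.na(object$best_start)) stop_config("no local optimization finished")
  object$multistart$histories[[object$best_start]]
}

#' @export
print.mb_fit <- function(x, ...) {
  f <- x$multistart$finals
  cat(sprintf("Mini-batch ODE calibration (%s, %s)\n", x$runner, x$algorithm))
  cat(sprintf("  problem: %s (%d conditions, %d records, %d parameters)\n",
              x$problem$name, x$problem$n_conditions, x$problem$n_records,
              x$problem$model$n_theta))
  cat(sprintf("  starts: %d (%d finished)\n", nrow(f),
              sum(is.finite(f$J_full))))
  if (!is.na(x$best_start)) {
    b <- f[x$best_start, ]
    cat(sprintf("  best start #%d: J = %.6g, Pearson r = %.4f, RMSE = %.4g\n",
                b$start, b$J_full, b$pearson_r, b$rmse))
  }
  invisible(x)
}

#' @export
summary.mb_fit <- function(object, ...) {
  f <- object$multistart$finals
  out <- list(
    finals = f[order(f$J_full), ],
    termination = table(f$termination),
    best = if (!is.na(object$best_start)) stats::setNames(
      best_history(object)$final_theta,
      object$problem$model$parameter_names) else NULL,
    theta_true_log10 = if (!is.null(object$problem$theta_true))
      log10(object$problem$theta_true) else NULL
  )
  class(out) <- "summary.mb_fit"
  out
}

#' @export
print.summary.mb_fit <- function(x, ...) {
  cat("Final whole-dataset objective values (best first):\n")
  print(utils::head(x$finals, 10), row.names = FALSE)
  cat("\nTermination reasons:\n")
  print(x$termination)
  if (!is.null(x$best)) {
    cat("\nBest estimate (log10 scale):\n")
    print(round(x$best, 4))
    if (!is.null(x$theta_true_log10)) {
      cat("\nGround truth (log10 scale):\n")
      print(round(x$theta_true_log10, 4))
    }
  }
  invisible(x)
}

#' Best parameter estimate of a calibration fit
#'
#' @param object an `mb_fit`.
#' @param scale `"log10"` (optimization scale) or `"linear"`.
#' @param ... unused.
#' @return named parameter vector of the best start.
#' @export
coef.mb_fit <- function(object, scale = c("log10", "linear"), ...) {
  scale <- match.arg(scale)
  th <- best_history(object)$final_theta
  names(th) <- object$problem$model$parameter_names
  if (scale == "linear") 10^th else th
}

#' @export
plot.mb_fit <- function(x, ...) {
  wf <- waterfall(x$multistart$finals$J_full)
  plot(seq_len(nrow(wf)), wf$value, log = "y", pch = 16,
       xlab = "sorted start index", ylab = "final objective J",
       main = "Waterfall plot", ...)
  invisible(wf)
}

#' @export
predict.mb_fit <- function(object, conditions = NULL, ...) {
  prob <- object$problem
  theta <- 10^best_history(object)$final_theta
  ids <- conditions %||% prob$condition_ids
  out <- lapply(ids, function(id) {
    ci <- prob$index[[id]]
    if (is.null(ci)) stop_config("unknown condition id '%s'", id)
    sim <- simulate_indexed_condition(prob, ci, theta, FALSE, solver_tol())
    data.frame(conditionId = id,
               observableId = prob$measurements$observableId[ci$rows],
               time = prob$measurements$time[ci$rows],
               predicted = if (sim$status == "ok") sim$yhat else NA_real_)
  })
  do.call(rbind, out)
}

#' @export
residuals.mb_fit <- function(object, ...) {
  ev <- evaluate_objective(object$problem, best_history(object)$final_theta,
                           return_fits = TRUE)
  if (ev$status != "ok") stop_config("objective not evaluable at the estimate")
  with(ev$fits, (ybar - yfit) / sigma)
}

#' @export
logLik.mb_fit <- function(object, ...) {
  ev <- evaluate_objective(object$problem, best_history(object)$final_theta)
  structure(-ev$J_full_nll, df = object$problem$model$n_theta,
            class = "logLik")
}
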