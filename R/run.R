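# Local optimization runs and multi-start orchestration.
#
# One mini-batch run executes epochs x ceil(M / batch_size) steps of
# evaluate-with-gradient -> step_direction -> (optional line-search) ->
# apply_update. Two robustness layers guard against regions of parameter
# space where the ODE cannot be integrated:
#  * the rescue interceptor (a one-dimensional trust region): on evaluation
#    failure it undoes the previous update, halves the step-length multiplier
#    and retries on the same mini-batch, at most 10 times; after success the
#    multiplier doubles per successful step back to 1. Failure at the initial
#    point cannot be undone and ends the run.
#  * the mini-batch backtracking line-search: trial steps are re-evaluated
#    objective-only on the same mini-batch (full step first, then quadratic-
#    interpolation backtracking safeguarded to [0.1, 0.5] x the previous
#    trial), at most 3 trials; if none improves, the smallest trial is
#    accepted anyway so the stochastic process keeps moving.

new_history <- function(n_steps, n_theta, par_names) {
  list(theta = matrix(NA_real_, n_steps, n_theta,
                      dimnames = list(NULL, par_names)),
       J_batch = rep(NA_real_, n_steps),
       n_records = rep(NA_integer_, n_steps),
       eta = rep(NA_real_, n_steps),
       step_scale = rep(NA_real_, n_steps),
       epoch = rep(NA_integer_, n_steps),
       ls_trials = rep(0L, n_steps),
       rescue_retries = rep(0L, n_steps),
       cost = rep(NA_real_, n_steps))
}

finish_history <- function(h, n, extra) {
  h$theta <- h$theta[seq_len(n), , drop = FALSE]
  for (f in c("J_batch", "n_records", "eta", "step_scale", "epoch",
              "ls_trials", "rescue_retries", "cost")) {
    h[[f]] <- h[[f]][seq_len(n)]
  }
  h$n_steps <- n
  structure(c(h, extra), class = "mb_history")
}

#' @export
print.mb_history <- function(x, ...) {
  cat(sprintf("<mb_history> %d steps (%s), termination: %s\n",
              x$n_steps, x$kind, x$termination))
  if (!is.null(x$final_metrics) && !is.na(x$final_metrics$J_full)) {
    cat(sprintf("  final J = %.6g, r = %.3f, cost = %d condition simulations\n",
                x$final_metrics$J_full, x$final_metrics$pearson_r,
                as.integer(x$total_cost)))
  }
  invisible(x)
}

# mini-batch line-search; returns list(theta_new, trials, t_used, failed_all)
minibatch_line_search <- function(problem, theta, delta, eta, step_scale,
                                  g, J0, batch, space, tol, counter) {
  d <- step_scale * eta * delta
  dphi0 <- sum(g * d)                     # directional derivative at t = 0
  t_cur <- 1
  trials <- 0L
  best <- NULL
  while (trials < 3L) {
    trials <- trials + 1L
    cand <- clip_box(theta + t_cur * d, space$lower, space$upper)
    ev <- evaluate_objective(problem, cand, subset = batch,
                             with_gradient = FALSE, tol = tol)
    counter$n_sim <- counter$n_sim + ev$n_sim
    if (ev$status == "ok") {
      best <- list(theta_new = cand, t_used = t_cur)
      if (ev$J < J0) {
        return(list(theta_new = cand, trials = trials, t_used = t_cur,
                    failed_all = FALSE))
      }
      # quadratic interpolation through phi(0), phi'(0), phi(t_cur),
      # safeguarded into [0.1, 0.5] * t_cur
      denom <- 2 * (ev$J - J0 - dphi0 * t_cur)
      t_new <- if (is.finite(denom) && denom > 0) {
        -dphi0 * t_cur^2 / denom
      } else 0.5 * t_cur
      t_cur <- min(max(t_new, 0.1 * t_cur), 0.5 * t_cur)
    } else {
      # evaluation failure counts as non-improvement; back off harder
      t_cur <- 0.5 * t_cur
    }
  }
  if (is.null(best)) {
    return(list(theta_new = NULL, trials = trials, t_used = NA_real_,
                failed_all = TRUE))
  }
  # exhausted without improvement: accept the smallest evaluable trial
  list(theta_new = best$theta_new, trials = trials, t_used = best$t_used,
       failed_all = FALSE)
}

#' Run one local mini-batch optimization
#'
#' @param problem a [calib_problem()].
#' @param theta0 start point on the log10 scale (inside the box).
#' @param algorithm optimizer, see [optimizer_state()].
#' @param schedule an [lr_schedule()] (default: benchmark Schedule 2).
#' @param batch_size conditions per mini-batch.
#' @param epochs passes over the whole condition set.
#' @param seed integer seed driving the epoch shuffles.
#' @param rescue enable the rescue interceptor. With `rescue = FALSE` an
#'   evaluation failure ends the run (`termination = "evaluation_failure"`),
#'   the naive behaviour.
#' @param line_search enable the mini-batch backtracking line-search.
#' @param hyper optimizer hyperparameter overrides, see [optimizer_state()].
#' @param track_full_epoch evaluate the full-dataset objective at each epoch
#'   boundary (needed for convergence metrics; costs M simulations per
#'   epoch).
#' @param tol solver tolerances.
#' @param wall_time_limit seconds; `Inf` by default.
#' @return an `mb_history`: per-step evaluated parameters `theta`, batch
#'   objective estimates `J_batch`, learning rates, step-scale trace, event
#'   counts, cumulative condition-simulation cost; plus `final_theta`,
#'   `final_metrics` (whole-dataset objective / Pearson r / RMSE),
#'   `termination` in `{"completed", "initial_failure", "rescue_exhausted",
#'   "evaluation_failure", "wall_time"}`.
#' @export
run_minibatch <- function(problem, theta0, algorithm = "adam_balanced",
                          schedule = schedule_preset(2), batch_size = 30,
                          epochs = 50, seed = 1, rescue = TRUE,
                          line_search = FALSE, hyper = list(),
                          track_full_epoch = FALSE, tol = solver_tol(),
                          wall_time_limit = Inf) {
  stopifnot(inherits(problem, "calib_problem"))
  space <- problem$space
  theta0 <- as.numeric(theta0)
  if (any(theta0 < space$lower | theta0 > space$upper)) {
    stop_config("start point outside the parameter box")
  }
  ids <- problem$condition_ids
  M <- length(ids)
  batch_size <- min(batch_size, M)
  steps_per_epoch <- ceiling(M / batch_size)
  total_steps <- epochs * steps_per_epoch
  n_theta <- problem$model$n_theta

  state <- optimizer_state(algorithm, n_theta, hyper)
  theta <- theta0
  step_scale <- 1
  h <- new_history(total_steps, n_theta, problem$model$parameter_names)
  counter <- new.env(); counter$n_sim <- 0
  epoch_full <- list()
  prev <- NULL   # list(theta, step_vec): last accepted update, for rescue
  termination <- "completed"
  r <- 0L
  t_start <- Sys.time()

  set.seed(derive_seed(seed, 101L))
  for (epoch in seq_len(epochs)) {
    batches <- suppressWarnings(make_epoch_batches(ids, batch_size))
    for (batch in batches) {
      eta <- schedule_eta(schedule, r, total_steps)
      ev <- evaluate_objective(problem, theta, subset = batch,
                               with_gradient = TRUE, tol = tol)
      counter$n_sim <- counter$n_sim + ev$n_sim
      retries <- 0L
      while (ev$status != "ok") {
        if (is.null(prev)) { termination <- "initial_failure"; break }
        if (!rescue) { termination <- "evaluation_failure"; break }
        if (retries >= 10L) { termination <- "rescue_exhausted"; break }
        retries <- retries + 1L
        step_scale <- step_scale / 2
        theta <- clip_box(prev$theta + step_scale * prev$step_vec,
                          space$lower, space$upper)
        ev <- evaluate_objective(problem, theta, subset = batch,
                                 with_gradient = TRUE, tol = tol)
        counter$n_sim <- counter$n_sim + ev$n_sim
      }
      if (termination != "completed") break

      r <- r + 1L
      h$theta[r, ] <- theta
      h$J_batch[r] <- ev$J
      h$n_records[r] <- ev$n_records
      h$eta[r] <- eta
      h$step_scale[r] <- step_scale
      h$epoch[r] <- epoch
      h$rescue_retries[r] <- retries

      sd_res <- step_direction(state, ev$gradient)
      state <- sd_res$state
      delta <- sd_res$delta

      if (line_search) {
        ls <- minibatch_line_search(problem, theta, delta, eta, step_scale,
                                    ev$gradient, ev$J, batch, space, tol,
                                    counter)
        h$ls_trials[r] <- ls$trials
        if (ls$failed_all) {
          # no trial evaluable: hand off to the rescue logic by shrinking the
          # step and staying put (undo the proposed update)
          if (!rescue) { termination <- "evaluation_failure"; break }
          step_scale <- step_scale / 2
          theta_new <- theta
          step_vec <- numeric(n_theta)
        } else {
          theta_new <- ls$theta_new
          step_vec <- ls$t_used * eta * delta
        }
      } else {
        theta_new <- apply_update(theta, delta, eta, space, step_scale)
        step_vec <- eta * delta
      }
      prev <- list(theta = theta, step_vec = step_vec)
      theta <- theta_new
      step_scale <- min(1, 2 * step_scale)
      h$cost[r] <- counter$n_sim

      if (is.finite(wall_time_limit) &&
          as.numeric(difftime(Sys.time(), t_start, units = "secs")) >
            wall_time_limit) {
        termination <- "wall_time"
        break
      }
    }
    if (termination != "completed") break
    if (track_full_epoch) {
      fe <- evaluate_objective(problem, theta, tol = tol)
      counter$n_sim <- counter$n_sim + fe$n_sim
      epoch_full[[length(epoch_full) + 1L]] <-
        data.frame(epoch = epoch,
                   J_full = if (fe$status == "ok") fe$J else NA_real_,
                   cost = counter$n_sim)
    }
  }

  final_metrics <- if (termination %in% c("completed", "wall_time")) {
    fm <- full_dataset_metrics(problem, theta, tol)
    counter$n_sim <- counter$n_sim + fm$n_sim
    fm
  } else {
    list(J_full = NA_real_, J_full_nll = NA_real_, pearson_r = NA_real_,
         rmse = NA_real_, status = termination)
  }

  finish_history(h, r, list(
    kind = "minibatch", algorithm = algorithm, batch_size = batch_size,
    steps_per_epoch = steps_per_epoch, epochs_requested = epochs,
    final_theta = theta, final_metrics = final_metrics,
    termination = termination, total_cost = counter$n_sim,
    epoch_full = if (length(epoch_full)) do.call(rbind, epoch_full) else NULL,
    n_total_records = problem$n_records, seed = seed
  ))
}

#' Full-batch quasi-Newton reference run
#'
#' Bounded L-BFGS-B minimization of the full objective with
#' forward-sensitivity gradients, recorded in the same history schema as the
#' mini-batch runs so that downstream ranking/ensemble tooling treats both
#' uniformly. Non-evaluable points are given a large barrier value (the
#' quasi-Newton line search then backtracks).
#'
#' @inheritParams run_minibatch
#' @param max_iterations L-BFGS-B iteration budget.
#' @return an `mb_history` with `kind = "fullbatch"`.
#' @export
run_fullbatch_reference <- function(problem, theta0, max_iterations = 100,
                                    tol = solver_tol()) {
  space <- problem$space
  n_theta <- problem$model$n_theta
  trace <- new.env()
  trace$theta <- list(); trace$J <- numeric(0); trace$n_sim <- 0

  fn <- function(th) {
    ev <- evaluate_objective(problem, th, tol = tol)
    trace$n_sim <- trace$n_sim + ev$n_sim
    J <- if (ev$status == "ok") ev$J else 1e12
    trace$theta[[length(trace$theta) + 1L]] <- th
    trace$J <- c(trace$J, J)
    J
  }
  gr <- function(th) {
    ev <- evaluate_objective(problem, th, with_gradient = TRUE, tol = tol)
    trace$n_sim <- trace$n_sim + ev$n_sim
    if (ev$status == "ok") ev$gradient else numeric(n_theta)
  }
  opt <- tryCatch(
    stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                 lower = space$lower, upper = space$upper,
                 control = list(maxit = max_iterations)),
    error = function(e) NULL
  )
  n <- length(trace$J)
  h <- new_history(n, n_theta, problem$model$parameter_names)
  for (k in seq_len(n)) h$theta[k, ] <- trace$theta[[k]]
  h$J_batch <- trace$J
  h$n_records <- rep(problem$n_records, n)
  h$eta <- rep(NA_real_, n)
  h$step_scale <- rep(1, n)
  h$epoch <- seq_len(n)            # one full pass per evaluation
  h$cost <- seq_len(n) * problem$n_conditions
  final_theta <- if (!is.null(opt)) opt$par else
    trace$theta[[which.min(trace$J)]]
  termination <- if (is.null(opt)) "optimizer_error" else
    if (opt$convergence == 0) "completed" else sprintf("optim_%d", opt$convergence)
  fm <- full_dataset_metrics(problem, final_theta, tol)
  finish_history(h, n, list(
    kind = "fullbatch", algorithm = "lbfgsb", batch_size = problem$n_conditions,
    steps_per_epoch = 1L, epochs_requested = max_iterations,
    final_theta = final_theta, final_metrics = fm,
    termination = termination, total_cost = trace$n_sim + fm$n_sim,
    epoch_full = data.frame(epoch = seq_len(n), J_full = trace$J,
                            cost = seq_len(n) * problem$n_conditions),
    n_total_records = problem$n_records, seed = NA_integer_
  ))
}

#' Sample multi-start initial points
#'
#' Uniform in the log10 box. With a shared seed, different optimizer settings
#' receive identical start sets, enabling paired comparisons.
#'
#' @param problem a [calib_problem()].
#' @param n_starts number of start points.
#' @param seed integer seed.
#' @return matrix `n_starts x n_theta` (log10 scale).
#' @export
sample_starts <- function(problem, n_starts = 100, seed = 1) {
  space <- problem$space
  n_theta <- length(space$lower)
  withr_seed(derive_seed(seed, 7L), {
    m <- matrix(stats::runif(n_starts * n_theta), n_starts, n_theta)
    m <- sweep(m, 2, space$upper - space$lower, "*")
    m <- sweep(m, 2, space$lower, "+")
    colnames(m) <- problem$model$parameter_names
    m
  })
}

#' Multi-start optimization
#'
#' Runs `n_starts` local optimizations from shared uniformly sampled start
#' points (default 100, the benchmark protocol) and collects histories and
#' final whole-dataset metrics.
#'
#' @inheritParams run_minibatch
#' @param n_starts number of local optimizations.
#' @param runner `"minibatch"` or `"fullbatch"`.
#' @param ... passed to [run_minibatch()] or [run_fullbatch_reference()].
#' @return `multistart_result`: list with `histories`, `finals` (data.frame:
#'   start, J_full, pearson_r, rmse, termination, cost), `starts`.
#' @export
run_multistart <- function(problem, n_starts = 100, seed = 1,
                           runner = c("minibatch", "fullbatch"), ...) {
  runner <- match.arg(runner)
  starts <- sample_starts(problem, n_starts, seed)
  histories <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    histories[[i]] <- if (runner == "minibatch") {
      run_minibatch(problem, starts[i, ], seed = derive_seed(seed, 1000L + i),
                    ...)
    } else {
      run_fullbatch_reference(problem, starts[i, ], ...)
    }
    histories[[i]]$start_id <- i
  }
  finals <- data.frame(
    start = seq_len(n_starts),
    J_full = vapply(histories, function(x) x$final_metrics$J_full, numeric(1)),
    pearson_r = vapply(histories, function(x) x$final_metrics$pearson_r %||% NA_real_,
                       numeric(1)),
    rmse = vapply(histories, function(x) x$final_metrics$rmse %||% NA_real_,
                  numeric(1)),
    termination = vapply(histories, function(x) x$termination, character(1)),
    cost = vapply(histories, function(x) as.numeric(x$total_cost), numeric(1))
  )
  structure(list(histories = histories, finals = finals, starts = starts,
                 runner = runner, seed = seed),
            class = "multistart_result")
}

#' @export
print.multistart_result <- function(x, ...) {
  ok <- is.finite(x$finals$J_full)
  cat(sprintf("<multistart_result> %d starts (%s), best J = %s\n",
              nrow(x$finals), x$runner,
              if (any(ok)) format(min(x$finals$J_full[ok])) else "none finished"))
  invisible(x)
}
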