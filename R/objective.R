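# Negative-log-likelihood objective with per-condition decomposition.
#
# Under additive Gaussian noise with known per-record SD sigma the negative
# log-likelihood is, up to a theta-independent constant,
#   J(theta) = sum_e J_e(theta),
#   J_e = 1/2 sum_i ((ybar_{e,i} - y_{e,i}(theta)) / sigma_{e,i})^2 ,
# which decomposes over experimental conditions e. Mini-batch gradient
# estimates are the *unnormalized* sums of per-condition gradients over the
# batch; summation runs in sorted-condition-id order for bitwise
# reproducibility.

#' Assemble a calibration problem
#'
#' Couples an [ode_model()] with a condition table, a PEtab-flavoured
#' measurement table and a (log10) parameter box.
#'
#' @param model an [ode_model()].
#' @param conditions data.frame with `conditionId`, one column per model
#'   input (named as `model$input_names`), and optionally a logical
#'   `steadyState` column marking equilibrium-readout conditions.
#' @param measurements data.frame with columns `observableId`,
#'   `simulationConditionId`, `time` (`Inf` for steady-state readouts),
#'   `measurement`, `noiseParameters` (the Gaussian noise SD, > 0).
#' @param lower,upper parameter bounds on the log10 scale; the default box
#'   is \[-5, 3\] per parameter, i.e. \[1e-5, 1e3\] on the linear scale.
#' @param scale_observables character vector of observable ids whose model
#'   output is matched to the data only up to a multiplicative scaling
#'   factor; the factor is computed analytically per observable (see
#'   [analytic_scaling_factors()]).
#' @param scaling_during_optimization apply those scalings inside
#'   [evaluate_objective()] as well (default), or only in
#'   [full_dataset_metrics()].
#' @param theta_true optional ground-truth parameter vector (linear scale),
#'   carried along for synthetic problems.
#' @param name label.
#' @return object of class `calib_problem`.
#' @export
calib_problem <- function(model, conditions, measurements,
                          lower = -5, upper = 3,
                          scale_observables = character(),
                          scaling_during_optimization = TRUE,
                          theta_true = NULL, name = "calib_problem") {
  stopifnot(inherits(model, "ode_model"))
  conditions <- as.data.frame(conditions)
  measurements <- as.data.frame(measurements)
  req <- c("observableId", "simulationConditionId", "time", "measurement",
           "noiseParameters")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop_config("measurement table lacks column(s): %s",
                                paste(miss, collapse = ", "))
  if (anyDuplicated(conditions$conditionId)) {
    stop_config("duplicate conditionId in condition table")
  }
  bad_sigma <- which(!is.finite(measurements$noiseParameters) |
                       measurements$noiseParameters <= 0)
  if (length(bad_sigma)) {
    stop_config("non-positive noise SD in measurement row(s): %s",
                paste(utils::head(bad_sigma, 5), collapse = ", "))
  }
  unknown_cond <- setdiff(unique(measurements$simulationConditionId),
                          conditions$conditionId)
  if (length(unknown_cond)) {
    stop_config("measurements reference undefined condition(s): %s",
                paste(utils::head(unknown_cond, 5), collapse = ", "))
  }
  unknown_obs <- setdiff(unique(measurements$observableId),
                         model$observable_names)
  if (length(unknown_obs)) {
    stop_config("measurements reference unknown observable(s): %s",
                paste(unknown_obs, collapse = ", "))
  }
  miss_u <- setdiff(model$input_names, names(conditions))
  if (length(miss_u)) stop_config("condition table lacks input column(s): %s",
                                  paste(miss_u, collapse = ", "))
  if (is.null(conditions$steadyState)) {
    ss_ids <- unique(measurements$simulationConditionId[
      is.infinite(measurements$time)])
    conditions$steadyState <- conditions$conditionId %in% ss_ids
  }

  n <- length(model$parameter_names)
  space <- list(lower = rep_len(lower, n), upper = rep_len(upper, n))
  if (!all(space$lower < space$upper)) stop_config("need lower < upper bounds")

  # Per-condition evaluation index, in sorted-id order (fixed summation order).
  ids <- sort(unique(as.character(measurements$simulationConditionId)))
  cond_rows <- match(ids, conditions$conditionId)
  umat <- as.matrix(conditions[cond_rows, model$input_names, drop = FALSE])
  mode(umat) <- "double"
  index <- lapply(seq_along(ids), function(k) {
    rows <- which(measurements$simulationConditionId == ids[k])
    steady <- conditions$steadyState[cond_rows[k]]
    times <- if (steady) Inf else sort(unique(measurements$time[rows]))
    list(
      id = ids[k],
      rows = rows,
      u = umat[k, ],
      steady = isTRUE(steady),
      times = times,
      time_idx = if (isTRUE(steady)) rep(1L, length(rows)) else
        match(measurements$time[rows], times),
      obs_idx = match(measurements$observableId[rows], model$observable_names)
    )
  })
  names(index) <- ids

  structure(
    list(model = model, conditions = conditions, measurements = measurements,
         space = space, scale_observables = as.character(scale_observables),
         scaling_during_optimization = scaling_during_optimization,
         theta_true = theta_true, name = name,
         condition_ids = ids, index = index,
         n_conditions = length(ids), n_records = nrow(measurements),
         log_const = 0.5 * sum(log(2 * pi * measurements$noiseParameters^2))),
    class = "calib_problem"
  )
}

#' @export
print.calib_problem <- function(x, ...) {
  cat(sprintf(
    "<calib_problem> %s: %d conditions, %d records, %d parameters [%g, %g] (log10)\n",
    x$name, x$n_conditions, x$n_records, x$model$n_theta,
    x$space$lower[1], x$space$upper[1]))
  invisible(x)
}

#' Analytic multiplicative scaling factors
#'
#' For observables modelled as `y = s * yhat`, the J-minimizing scaling for a
#' group of records is the weighted least-squares solution
#' `s* = sum(ybar yhat / sigma^2) / sum(yhat^2 / sigma^2)`. Groups whose
#' simulations are identically zero get `s* = 1` with a warning.
#'
#' @param y_meas,y_sim,sigma measurement, simulation and noise-SD vectors.
#' @param group grouping factor (one scaling per level).
#' @return named numeric vector of scalings, one per group level.
#' @export
analytic_scaling_factors <- function(y_meas, y_sim, sigma,
                                     group = rep("all", length(y_meas))) {
  group <- as.factor(group)
  if (any(tabulate(group, nbins = nlevels(group)) == 0)) {
    stop_config("empty observable group in scaling computation")
  }
  num <- tapply(y_meas * y_sim / sigma^2, group, sum)
  den <- tapply(y_sim^2 / sigma^2, group, sum)
  s <- num / den
  if (any(den == 0)) {
    warning("scaling group(s) with all-zero simulations; using s = 1")
    s[den == 0] <- 1
  }
  out <- as.numeric(s)
  names(out) <- levels(group)
  out
}

# Simulate one indexed condition; returns per-row simulated values (and
# optionally per-row sensitivity matrix on the log10 scale).
simulate_indexed_condition <- function(problem, ci, theta_lin,
                                       with_gradient, tol) {
  model <- problem$model
  if (!with_gradient) {
    if (ci$steady) {
      ss <- simulate_steady_state(model, theta_lin, ci$u, tol)
      if (ss$status != "ok") return(list(status = ss$status))
      y <- matrix(ss$observables, nrow = 1)
    } else {
      tr <- simulate_condition(model, theta_lin, ci$u, ci$times, tol)
      if (tr$status != "ok") return(list(status = tr$status))
      y <- tr$observables
    }
    yhat <- y[cbind(ci$time_idx, ci$obs_idx)]
    return(list(status = "ok", yhat = yhat))
  }
  sres <- compute_output_sensitivities(model, theta_lin, ci$u, ci$times, tol,
                                       steady_state = ci$steady)
  if (sres$status != "ok") return(list(status = sres$status))
  if (ci$steady) {
    # the variational integration reports the end point; re-check equilibrium
    x <- sres$states[nrow(sres$states), ]
    f <- model$rhs(1e8, x, theta_lin, ci$u)
    if (sqrt(mean((f / (1e-16 + 1e-8 * abs(x)))^2)) > 1) {
      return(list(status = "not_converged"))
    }
  }
  n_t <- dim(sres$dy_dtheta)[1]
  yhat <- sres$observables[cbind(ci$time_idx, ci$obs_idx)]
  flat <- matrix(sres$dy_dtheta, n_t * model$n_obs, model$n_theta)
  dy <- flat[(ci$obs_idx - 1L) * n_t + ci$time_idx, , drop = FALSE]
  list(status = "ok", yhat = yhat, dy = dy)
}

#' Evaluate the objective on a condition subset
#'
#' Computes `J` restricted to `subset` (default: all conditions) as the sum
#' of per-condition contributions, and optionally the gradient estimate --
#' the unnormalized sum of per-condition gradients on the log10 parameter
#' scale. Any integration failure or steady-state non-convergence within the
#' subset yields `status = "evaluation_failure"` (J undefined); this is a
#' returned value, never an exception, so optimization-level callers can
#' trigger the rescue interceptor. Unknown subset ids are a configuration
#' error and do raise.
#'
#' @param problem a [calib_problem()].
#' @param theta_log10 point in the log10 parameter box.
#' @param subset condition-id character vector, or `NULL` for all.
#' @param with_gradient also compute the gradient estimate.
#' @param tol solver tolerances.
#' @param return_fits also return the per-record fitted values (`fits`
#'   data.frame with `ybar`, `yfit`, `sigma`); used by
#'   [full_dataset_metrics()] to avoid re-simulating.
#' @return object of class `objective_value`: list with `J`, `J_full_nll`
#'   (`J` plus the Gaussian log-constant of the evaluated records),
#'   `per_condition` (named), `gradient` (or `NULL`), `status`, `n_records`,
#'   `n_sim` (condition simulations spent, the deterministic cost proxy).
#' @export
evaluate_objective <- function(problem, theta_log10, subset = NULL,
                               with_gradient = FALSE, tol = solver_tol(),
                               return_fits = FALSE) {
  stopifnot(inherits(problem, "calib_problem"))
  if (length(theta_log10) != problem$model$n_theta) {
    stop_config("theta has length %d, problem expects %d",
                length(theta_log10), problem$model$n_theta)
  }
  ids <- if (is.null(subset)) problem$condition_ids else {
    bad <- setdiff(subset, problem$condition_ids)
    if (length(bad)) stop_config("unknown condition id(s) in subset: %s",
                                 paste(utils::head(bad, 5), collapse = ", "))
    sort(unique(as.character(subset)))
  }
  if (!length(ids)) stop_config("empty condition subset")
  theta_lin <- 10^theta_log10

  sims <- vector("list", length(ids))
  n_sim <- 0L
  for (k in seq_along(ids)) {
    ci <- problem$index[[ids[k]]]
    n_sim <- n_sim + 1L
    res <- simulate_indexed_condition(problem, ci, theta_lin, with_gradient, tol)
    if (res$status != "ok") {
      return(structure(list(J = NA_real_, J_full_nll = NA_real_,
                            per_condition = NULL, gradient = NULL,
                            status = "evaluation_failure",
                            failed_condition = ids[k],
                            n_records = NA_integer_, n_sim = n_sim),
                       class = "objective_value"))
    }
    sims[[k]] <- res
  }

  rows <- unlist(lapply(ids, function(id) problem$index[[id]]$rows))
  ybar <- problem$measurements$measurement[rows]
  sigma <- problem$measurements$noiseParameters[rows]
  obs_of_row <- problem$measurements$observableId[rows]
  yhat <- unlist(lapply(sims, `[[`, "yhat"))

  # analytic scalings (optional); the gradient below treats s as fixed at its
  # optimum, which is exact by the envelope theorem (dJ/ds = 0 at s*).
  scale_row <- rep(1, length(yhat))
  if (length(problem$scale_observables) &&
      (problem$scaling_during_optimization || is.null(subset))) {
    in_grp <- obs_of_row %in% problem$scale_observables
    if (any(in_grp)) {
      s <- analytic_scaling_factors(ybar[in_grp], yhat[in_grp], sigma[in_grp],
                                    group = obs_of_row[in_grp])
      scale_row[in_grp] <- s[obs_of_row[in_grp]]
    }
  }
  yfit <- scale_row * yhat
  resid <- (ybar - yfit) / sigma

  cond_of_row <- rep(ids, vapply(sims, function(s) length(s$yhat), integer(1)))
  perJ <- 0.5 * vapply(split(resid^2, factor(cond_of_row, levels = ids)),
                       sum, numeric(1))
  J <- sum(perJ)

  gradient <- NULL
  if (with_gradient) {
    dy <- do.call(rbind, lapply(sims, `[[`, "dy")) * scale_row
    gradient <- as.numeric(crossprod(dy, -resid / sigma))
    names(gradient) <- problem$model$parameter_names
  }
  log_const <- 0.5 * sum(log(2 * pi * sigma^2))
  out <- list(J = J, J_full_nll = J + log_const, per_condition = perJ,
              gradient = gradient, status = "ok",
              n_records = length(rows), n_sim = n_sim)
  if (return_fits) {
    out$fits <- data.frame(ybar = ybar, yfit = yfit, sigma = sigma,
                           observableId = obs_of_row, conditionId = cond_of_row)
  }
  structure(out, class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<objective_value> J = %.6g over %d records (%d conditions simulated)\n",
                x$J, x$n_records, x$n_sim))
  } else {
    cat(sprintf("<objective_value> %s (condition %s)\n", x$status,
                x$failed_condition %||% "?"))
  }
  invisible(x)
}

#' Whole-dataset objective, correlation and RMSE
#'
#' Evaluates all conditions, applies analytic scaling factors where
#' configured, and returns the objective together with the Pearson
#' correlation between measurements and simulations and the (unweighted)
#' root-mean-square error. This is the quantity reported after optimization
#' for all methods, full-batch and mini-batch alike, so comparisons are not
#' biased by the batch sampling.
#'
#' @inheritParams evaluate_objective
#' @return list with `J_full`, `J_full_nll`, `pearson_r`, `rmse`, `status`,
#'   `n_records`, `n_sim`.
#' @export
full_dataset_metrics <- function(problem, theta_log10, tol = solver_tol()) {
  ev <- evaluate_objective(problem, theta_log10, subset = NULL,
                           with_gradient = FALSE, tol = tol,
                           return_fits = TRUE)
  if (ev$status != "ok") {
    return(list(J_full = NA_real_, J_full_nll = NA_real_,
                pearson_r = NA_real_, rmse = NA_real_,
                status = ev$status, n_records = problem$n_records,
                n_sim = ev$n_sim))
  }
  ybar <- ev$fits$ybar
  yfit <- ev$fits$yfit
  r <- if (length(ybar) < 2 || stats::sd(ybar) == 0 || stats::sd(yfit) == 0)
    NA_real_ else stats::cor(ybar, yfit)
  list(J_full = ev$J, J_full_nll = ev$J_full_nll,
       pearson_r = r, rmse = sqrt(mean((ybar - yfit)^2)),
       status = "ok", n_records = ev$n_records, n_sim = ev$n_sim)
}
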