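# Parameter ensembles from optimization histories.
#
# Mini-batch runs evaluate the objective on changing subsets, so the
# per-step objective estimates are noisy; before any cutoff is applied the
# trace is smoothed by a centered moving average spanning up to one epoch
# (half an epoch before and after the current step, truncated at the trace
# ends). The ensemble rule then is: cutoff = best smoothed RMSE x (1 +
# tolerance), admit every evaluated parameter vector whose smoothed value is
# below the cutoff, and thin uniformly to at most `cap` members per (start,
# epoch). RMSE here is the weighted residual RMS, recovered from the
# half-sum-of-squares objective as sqrt(2 J / n_records).

#' Smooth an objective trace over one epoch
#'
#' @param values per-step objective values.
#' @param steps_per_epoch window size (one epoch of steps); the centered
#'   window spans `floor(steps_per_epoch / 2)` steps on each side, truncated
#'   at the ends.
#' @return smoothed values, same length.
#' @export
smooth_history <- function(values, steps_per_epoch) {
  n <- length(values)
  half <- floor(steps_per_epoch / 2)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - half):min(n, i + half)
    mean(values[w])
  }, numeric(1))
}

#' Build a parameter ensemble from optimization histories
#'
#' @param histories list of `mb_history` objects.
#' @param tolerance relative tolerance on the best smoothed RMSE (default
#'   0.10: cutoff at best x 1.10).
#' @param cap at most this many members per (start, epoch); `Inf` disables
#'   thinning. Default 50.
#' @param cutoff_mode `"smoothed_best"` (default; cutoff derived from the
#'   smoothed traces) or `"raw_best"` (from the raw per-step RMSE).
#' @return object of class `parameter_ensemble`: `members` (matrix, log10
#'   scale), `provenance` (data.frame start/step/epoch/smoothed RMSE),
#'   `cutoff`, `tolerance`, `cap`.
#' @export
build_ensemble <- function(histories, tolerance = 0.10, cap = 50,
                           cutoff_mode = c("smoothed_best", "raw_best")) {
  cutoff_mode <- match.arg(cutoff_mode)
  traces <- lapply(seq_along(histories), function(i) {
    h <- histories[[i]]
    if (!h$n_steps) return(NULL)
    per_rec <- h$J_batch / h$n_records
    rmse_raw <- sqrt(2 * per_rec)
    rmse_sm <- sqrt(2 * smooth_history(per_rec, h$steps_per_epoch))
    data.frame(start = i, step = seq_len(h$n_steps), epoch = h$epoch,
               rmse = rmse_sm, rmse_raw = rmse_raw)
  })
  tr <- do.call(rbind, traces)
  if (is.null(tr) || !nrow(tr)) stop_config("no history steps to build from")
  best <- if (cutoff_mode == "smoothed_best") min(tr$rmse) else min(tr$rmse_raw)
  cutoff <- best * (1 + tolerance)
  adm <- tr[tr$rmse <= cutoff, , drop = FALSE]
  if (!nrow(adm)) {
    warning("no parameter vectors below the ensemble cutoff")
  }
  # uniform-stride thinning per (start, epoch)
  keep <- unlist(lapply(split(seq_len(nrow(adm)),
                              list(adm$start, adm$epoch), drop = TRUE),
                        function(ix) {
    if (length(ix) <= cap) return(ix)
    ix[unique(round(seq(1, length(ix), length.out = cap)))]
  }), use.names = FALSE)
  keep <- sort(keep)
  adm <- adm[keep, , drop = FALSE]
  members <- do.call(rbind, lapply(seq_len(nrow(adm)), function(k) {
    histories[[adm$start[k]]]$theta[adm$step[k], ]
  }))
  structure(list(members = members, provenance = adm, cutoff = cutoff,
                 tolerance = tolerance, cap = cap,
                 cutoff_mode = cutoff_mode),
            class = "parameter_ensemble")
}

#' @export
print.parameter_ensemble <- function(x, ...) {
  cat(sprintf(
    "<parameter_ensemble> %d members from %d starts (RMSE cutoff %.4g, cap %s/epoch)\n",
    nrow(x$members) %||% 0L, length(unique(x$provenance$start)), x$cutoff,
    format(x$cap)))
  invisible(x)
}

#' Ensemble of the k best final estimates
#'
#' The final-results ensemble variant: the final parameter vectors of the
#' `k` best local optimizations (default 10).
#'
#' @param result a `multistart_result` (or `mb_fit$multistart`).
#' @param k ensemble size.
#' @return a `parameter_ensemble`.
#' @export
top_k_ensemble <- function(result, k = 10) {
  f <- result$finals
  ok <- which(is.finite(f$J_full))
  if (!length(ok)) stop_config("no finished starts")
  sel <- ok[order(f$J_full[ok])][seq_len(min(k, length(ok)))]
  members <- do.call(rbind, lapply(sel, function(i) {
    result$histories[[i]]$final_theta
  }))
  structure(list(members = members,
                 provenance = data.frame(start = sel, step = NA_integer_,
                                         epoch = NA_integer_,
                                         rmse = f$rmse[sel]),
                 cutoff = NA_real_, tolerance = NA_real_, cap = Inf,
                 cutoff_mode = "top_k"),
            class = "parameter_ensemble")
}

#' Ensemble predictions with spread
#'
#' Simulates every ensemble member over the requested conditions and returns
#' the element-wise mean and standard deviation of the model outputs. The SD
#' is computed over the members as listed (duplicated members count).
#' Members whose simulation fails are excluded and counted.
#'
#' @param problem a [calib_problem()].
#' @param ensemble a `parameter_ensemble`.
#' @param conditions condition ids (default: all).
#' @return list: `predictions` data.frame (conditionId, observableId, time,
#'   mean, sd), `n_members_used`, `n_failed`.
#' @export
ensemble_predict <- function(problem, ensemble, conditions = NULL) {
  members <- ensemble$members
  if (is.null(members) || !nrow(members)) stop_config("empty ensemble")
  ids <- conditions %||% problem$condition_ids
  sims <- list(); failed <- 0L
  for (m in seq_len(nrow(members))) {
    theta_lin <- 10^members[m, ]
    vals <- tryCatch({
      unlist(lapply(ids, function(id) {
        res <- simulate_indexed_condition(problem, problem$index[[id]],
                                          theta_lin, FALSE, solver_tol())
        if (res$status != "ok") stop("sim_failed")
        res$yhat
      }))
    }, error = function(e) NULL)
    if (is.null(vals)) failed <- failed + 1L else sims[[length(sims) + 1L]] <- vals
  }
  if (!length(sims)) stop_config("all ensemble member simulations failed")
  mat <- do.call(rbind, sims)
  rows <- unlist(lapply(ids, function(id) problem$index[[id]]$rows))
  out <- data.frame(
    conditionId = problem$measurements$simulationConditionId[rows],
    observableId = problem$measurements$observableId[rows],
    time = problem$measurements$time[rows],
    mean = colMeans(mat),
    sd = if (nrow(mat) > 1) apply(mat, 2, stats::sd) else 0
  )
  list(predictions = out, n_members_used = nrow(mat), n_failed = failed)
}

#' Spectrum of the ensemble covariance matrix
#'
#' Eigen-decomposition of the member covariance (parameters on the log10
#' scale): how many directions in parameter space carry the ensemble's
#' variance. A sharp drop after few directions indicates exploration
#' confined to a low-dimensional subspace.
#'
#' @param ensemble a `parameter_ensemble` with >= 2 members.
#' @return list: `eigenvalues` (descending), `explained` (fractions summing
#'   to 1), `cumulative`.
#' @export
covariance_spectrum <- function(ensemble) {
  members <- ensemble$members
  if (is.null(members) || nrow(members) < 2) {
    stop_config("need at least two ensemble members")
  }
  ev <- eigen(stats::cov(members), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  tot <- sum(ev)
  expl <- if (tot > 0) ev / tot else rep(0, length(ev))
  list(eigenvalues = ev, explained = expl, cumulative = cumsum(expl))
}

#' Singular values of the stacked output-sensitivity matrix
#'
#' Stacks the log10-scale output sensitivities `dy/dtheta` over all
#' conditions, observables and time points for each supplied parameter
#' vector, and returns the singular values together with the count above the
#' numerical-rank threshold `max(dim) * eps * max(sv)`. Directions with zero
#' singular value are combinations of parameters the observed outputs carry
#' no information about.
#'
#' @param problem a [calib_problem()].
#' @param thetas matrix of parameter vectors (rows, log10 scale), e.g. the
#'   members of a [top_k_ensemble()].
#' @param conditions condition ids to include (default: all).
#' @return list: `singular_values`, `numerical_rank`, `n_failed` (parameter
#'   vectors dropped due to simulation failure).
#' @export
output_sensitivity_svd <- function(problem, thetas, conditions = NULL) {
  thetas <- as.matrix(thetas)
  ids <- conditions %||% problem$condition_ids
  blocks <- list(); failed <- 0L
  for (m in seq_len(nrow(thetas))) {
    theta_lin <- 10^thetas[m, ]
    rowsm <- tryCatch({
      do.call(rbind, lapply(ids, function(id) {
        ci <- problem$index[[id]]
        res <- simulate_indexed_condition(problem, ci, theta_lin, TRUE,
                                          solver_tol())
        if (res$status != "ok") stop("sim_failed")
        res$dy
      }))
    }, error = function(e) NULL)
    if (is.null(rowsm)) failed <- failed + 1L else
      blocks[[length(blocks) + 1L]] <- rowsm
  }
  if (!length(blocks)) stop_config("no sensitivities computable")
  S <- do.call(rbind, blocks)
  sv <- svd(S, nu = 0, nv = 0)$d
  thresh <- max(dim(S)) * .Machine$double.eps * max(sv)
  list(singular_values = sv, numerical_rank = sum(sv > thresh),
       n_failed = failed)
}
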