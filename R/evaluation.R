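# Benchmark evaluation: rank-averaged optimizer comparison, convergence
# criteria, waterfall summaries, responder classification, ROC analysis and
# parameter-interval coverage.

#' Rank optimizer settings per start
#'
#' Given a matrix of final objective values (settings x starts, paired: the
#' same start set for every setting), ranks the settings within each start
#' (ascending; lower objective is better, ties averaged; failed/missing
#' finals rank worst, tied) and averages the ranks over starts. The mean rank
#' is the overall performance proxy.
#'
#' @param finals numeric matrix, settings in rows, starts in columns
#'   (dimnames respected); `NA` marks a failed run.
#' @return list of class `ranking_table`: `ranks` (settings x starts),
#'   `mean_rank` (per setting), `finals`.
#' @export
rank_settings <- function(finals) {
  finals <- as.matrix(finals)
  if (is.null(rownames(finals))) {
    rownames(finals) <- paste0("setting_", seq_len(nrow(finals)))
  }
  if (any(!is.finite(finals) & !is.na(finals))) {
    finals[!is.finite(finals)] <- NA
  }
  ranks <- apply(finals, 2, function(col) {
    col[is.na(col)] <- Inf             # failed runs rank worst (tied)
    rank(col, ties.method = "average")
  })
  ranks <- matrix(ranks, nrow = nrow(finals), dimnames = dimnames(finals))
  structure(list(ranks = ranks, mean_rank = rowMeans(ranks), finals = finals),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat("Mean rank per setting (lower is better):\n")
  print(sort(x$mean_rank))
  invisible(x)
}

#' Convergence threshold from reference finals
#'
#' The value-to-reach is the mean plus one sample standard deviation of the
#' ten best (smallest) final objective values of a reference optimizer.
#'
#' @param reference_finals numeric vector of final objective values.
#' @param n_best how many best values enter (default 10).
#' @return the threshold (scalar).
#' @export
value_to_reach <- function(reference_finals, n_best = 10) {
  v <- sort(reference_finals[is.finite(reference_finals)])
  if (length(v) < n_best) {
    warning(sprintf("only %d finite reference finals; using all", length(v)))
  } else {
    v <- v[seq_len(n_best)]
  }
  if (!length(v)) stop_config("no finite reference finals")
  mean(v) + stats::sd(v)
}

#' Convergence metrics for a set of optimization histories
#'
#' A start counts as converged when its full-dataset objective first reaches
#' the threshold; for mini-batch runs this is checked at epoch boundaries on
#' the whole dataset (run with `track_full_epoch = TRUE`). Cost is counted in
#' condition simulations, a hardware-independent proxy.
#'
#' @param histories list of `mb_history` objects carrying `epoch_full`.
#' @param threshold the value-to-reach.
#' @return list: `n_converged`, `cost_to_first_convergence` (Inf if none),
#'   `converged_per_cost` (converged starts per million condition
#'   simulations over the whole experiment), `per_start` data.frame.
#' @export
convergence_metrics <- function(histories, threshold) {
  per <- lapply(seq_along(histories), function(i) {
    h <- histories[[i]]
    ef <- h$epoch_full
    if (is.null(ef) || !nrow(ef)) {
      return(data.frame(start = i, converged = FALSE, cost_at = NA_real_))
    }
    hit <- which(is.finite(ef$J_full) & ef$J_full <= threshold)
    data.frame(start = i, converged = length(hit) > 0,
               cost_at = if (length(hit)) ef$cost[hit[1]] else NA_real_)
  })
  per <- do.call(rbind, per)
  total_cost <- sum(vapply(histories, function(h) as.numeric(h$total_cost),
                           numeric(1)))
  n_conv <- sum(per$converged)
  list(
    n_converged = n_conv,
    cost_to_first_convergence = if (n_conv) min(per$cost_at, na.rm = TRUE) else Inf,
    converged_per_cost = n_conv / (total_cost / 1e6),
    per_start = per
  )
}

#' Waterfall ordering of final objective values
#'
#' @param finals numeric vector of final objective values (NA allowed).
#' @return data.frame `start`, `value`, ascending with ties stable by start
#'   index; NA finals sort last.
#' @export
waterfall <- function(finals) {
  ord <- order(finals, seq_along(finals), na.last = TRUE)
  data.frame(start = ord, value = finals[ord])
}

#' Classify conditions as responsive
#'
#' A condition is responsive iff its readout is reduced by more than 50%
#' relative to the untreated reference of its group (strict inequality:
#' exactly 50% is non-responsive), i.e. `readout < 0.5 * reference`.
#'
#' @param readouts numeric vector of readouts (e.g. viability).
#' @param group group id per readout (e.g. cell line).
#' @param reference named vector of untreated reference readouts, one per
#'   group level.
#' @return logical vector of labels.
#' @export
classify_responsive <- function(readouts, group, reference) {
  group <- as.character(group)
  missing_ref <- setdiff(unique(group), names(reference))
  if (length(missing_ref)) {
    stop_config("no untreated reference for group(s): %s",
                paste(utils::head(missing_ref, 5), collapse = ", "))
  }
  unname(readouts < 0.5 * reference[group])
}

#' ROC curve, AUC and slope-1 threshold
#'
#' Sweeps all unique score values as candidate thresholds (predicting
#' positive for `score >= threshold`), computes TPR/FPR and the trapezoidal
#' AUC, and selects the classification threshold at the point where the ROC
#' is tangential to a slope-1 line, operationalized for the discrete curve
#' as the maximizer of TPR - FPR (Youden's index; ties broken toward smaller
#' FPR). The chosen threshold can then be reused on independent test scores
#' via [roc_classify()].
#'
#' @param scores numeric scores; larger means more likely positive.
#' @param labels logical (or 0/1) true class per score; both classes must be
#'   present.
#' @return list of class `roc_result`: `thresholds`, `tpr`, `fpr`, `auc`,
#'   `chosen_threshold`, `confusion` (at the chosen threshold), `accuracy`.
#' @export
roc_and_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop_config("both classes must be present to compute a ROC")
  }
  P <- sum(labels); N <- sum(!labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / P, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / N, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  youden <- tpr - fpr
  best <- which(youden == max(youden))
  best <- best[which.min(fpr[best])]
  chosen <- thr[best]
  pred <- scores >= chosen
  confusion <- c(tp = sum(pred & labels), fp = sum(pred & !labels),
                 fn = sum(!pred & labels), tn = sum(!pred & !labels))
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 chosen_threshold = chosen, confusion = confusion,
                 accuracy = mean(pred == labels)),
            class = "roc_result")
}

#' Apply a previously chosen ROC threshold
#'
#' @param scores numeric scores.
#' @param threshold threshold from [roc_and_threshold()].
#' @return logical predictions (`scores >= threshold`).
#' @export
roc_classify <- function(scores, threshold) {
  scores >= threshold
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f, threshold = %.4g, accuracy = %.3f\n",
              x$auc, x$chosen_threshold, x$accuracy))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
       ylab = "true positive rate", main = sprintf("ROC (AUC = %.3f)", x$auc),
       ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Parameter-interval coverage across local optimizations
#'
#' For each parameter, the span of the multi-start results divided by the
#' width of the feasible interval, on the log10 scale. A coverage of 1 means
#' the runs hit both bounds; 0 means all runs agree.
#'
#' @param thetas matrix of parameter vectors (runs x n_theta, log10 scale).
#' @param space parameter space (list with `lower`, `upper`).
#' @return numeric vector of per-parameter coverages in \[0, 1\].
#' @export
parameter_interval_coverage <- function(thetas, space) {
  thetas <- as.matrix(thetas)
  if (nrow(thetas) < 2) stop_config("need at least two runs for coverage")
  width <- space$upper - space$lower
  if (any(width <= 0)) stop_config("degenerate parameter bounds")
  (apply(thetas, 2, max) - apply(thetas, 2, min)) / width
}
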