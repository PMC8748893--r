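# Mini-batch optimizer engines. Each engine maps a gradient estimate g (the
# unnormalized sum of per-condition gradients over the current mini-batch) to
# an update proposal delta; the applied step is
#   theta <- clip(theta + step_scale * eta_r * delta, bounds)
# where eta_r comes from the schedule and step_scale in (0, 1] is the rescue
# interceptor's trust-region-style multiplier.

#' Initialize optimizer state
#'
#' @param algorithm one of `"sgd"`, `"momentum"`, `"rmsprop"`, `"adam"`,
#'   `"adam_balanced"`. The two Adam tunings differ only in their decay pair:
#'   standard uses `(rho1, rho2) = (0.9, 0.999)` from the original
#'   publication, balanced sets both to 0.9.
#' @param n_theta parameter-vector length.
#' @param hyper optional overrides: `rho` (momentum/RMSProp decay, default
#'   0.9), `rho1`, `rho2` (Adam decays), `eps` (preconditioner floor,
#'   default 1e-8).
#' @return object of class `optimizer_state` with zeroed accumulators and
#'   `step_scale = 1`.
#' @export
optimizer_state <- function(algorithm = c("sgd", "momentum", "rmsprop",
                                          "adam", "adam_balanced"),
                            n_theta, hyper = list()) {
  algorithm <- match.arg(algorithm)
  h <- list(rho = 0.9, rho1 = 0.9,
            rho2 = if (algorithm == "adam_balanced") 0.9 else 0.999,
            eps = 1e-8)
  h[names(hyper)] <- hyper
  structure(
    list(algorithm = algorithm, hyper = h,
         m = numeric(n_theta),   # momentum / Adam first moment
         v = numeric(n_theta),   # RMS / Adam second moment
         t = 0L,                 # update counter (Adam bias correction)
         step_scale = 1),
    class = "optimizer_state"
  )
}

#' Compute the update proposal for a gradient estimate
#'
#' SGD: `delta = -g`. Momentum: `m <- rho m + g`, `delta = -m`. RMSProp:
#' `v <- rho v + (1 - rho) g^2`, `delta = -g / (sqrt(v) + eps)`. Adam:
#' decaying averages of `g` and `g^2` with bias correction,
#' `delta = -mhat / (sqrt(vhat) + eps)`.
#'
#' @param state an [optimizer_state()].
#' @param g gradient estimate (finite; callers must route non-finite
#'   gradients to the rescue path instead).
#' @return list with `delta` and the updated `state`.
#' @export
step_direction <- function(state, g) {
  if (!is_finite_vec(g)) {
    stop_config("non-finite gradient passed to step_direction; use the rescue path")
  }
  h <- state$hyper
  delta <- switch(state$algorithm,
    sgd = -g,
    momentum = {
      state$m <- h$rho * state$m + g
      -state$m
    },
    rmsprop = {
      state$v <- h$rho * state$v + (1 - h$rho) * g^2
      -g / (sqrt(state$v) + h$eps)
    },
    adam = ,
    adam_balanced = {
      state$t <- state$t + 1L
      state$m <- h$rho1 * state$m + (1 - h$rho1) * g
      state$v <- h$rho2 * state$v + (1 - h$rho2) * g^2
      mhat <- state$m / (1 - h$rho1^state$t)
      vhat <- state$v / (1 - h$rho2^state$t)
      -mhat / (sqrt(vhat) + h$eps)
    }
  )
  list(delta = delta, state = state)
}

#' Apply a scaled update inside the parameter box
#'
#' @param theta current point (log10 scale).
#' @param delta update proposal from [step_direction()].
#' @param eta learning rate for this step.
#' @param space parameter space (list with `lower`, `upper` on log10 scale).
#' @param step_scale rescue-interceptor multiplier in (0, 1].
#' @return the clipped next iterate.
#' @export
apply_update <- function(theta, delta, eta, space, step_scale = 1) {
  stopifnot(is_finite_vec(delta))
  clip_box(theta + step_scale * eta * delta, space$lower, space$upper)
}

#' Partition the conditions of an epoch into mini-batches
#'
#' A random permutation of the condition ids is split into consecutive chunks
#' of `batch_size`; the last batch keeps the remainder, so every condition is
#' used exactly once per epoch.
#'
#' @param ids condition identifiers.
#' @param batch_size conditions per mini-batch (>= 1). Values larger than
#'   `length(ids)` fall back to one full batch with a warning.
#' @return list of character vectors (the batches).
#' @export
make_epoch_batches <- function(ids, batch_size) {
  M <- length(ids)
  stopifnot(batch_size >= 1)
  if (batch_size > M) {
    warning("batch_size exceeds the number of conditions; using one full batch")
    batch_size <- M
  }
  perm <- sample(ids, M)
  split(perm, ceiling(seq_len(M) / batch_size))
}
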