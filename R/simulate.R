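# Numerical simulation of ode_model objects: trajectories, steady states and
# forward sensitivities. All integration uses a variable-order BDF scheme with
# adaptive steps (deSolve), rtol 1e-8 / atol 1e-16 / at most 1e4 steps per
# call. Integration failure is always returned as a status, never thrown:
# the mini-batch rescue interceptor relies on being able to observe failures.

#' Default solver tolerances
#'
#' @return list with `rtol`, `atol`, `maxsteps`.
#' @export
solver_tol <- function(rtol = 1e-8, atol = 1e-16, maxsteps = 1e4) {
  list(rtol = rtol, atol = atol, maxsteps = maxsteps)
}

# Finite-difference Jacobians of the vector field (fallback when the model
# does not supply analytic ones). Central differences on an absolute+relative
# step; these feed the variational ODE, not the gradient directly, so modest
# accuracy suffices.
fd_jac_x <- function(model, t, x, theta, u, h0 = 1e-7) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    h <- h0 * (1 + abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    J[, i] <- (model$rhs(t, xp, theta, u) - model$rhs(t, xm, theta, u)) / (2 * h)
  }
  J
}

fd_jac_theta <- function(model, t, x, theta, u, h0 = 1e-7) {
  n <- length(theta)
  J <- matrix(0, length(x), n)
  for (j in seq_len(n)) {
    h <- h0 * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    J[, j] <- (model$rhs(t, x, tp, u) - model$rhs(t, x, tm, u)) / (2 * h)
  }
  J
}

# dx0/dtheta: analytic when the model provides it, otherwise central
# differences of the (algebraic) init map.
init_sens <- function(model, theta, u, h0 = 1e-7) {
  if (!is.null(model$init_jac)) return(model$init_jac(theta, u))
  S0 <- matrix(0, model$n_x, model$n_theta)
  for (j in seq_len(model$n_theta)) {
    h <- h0 * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    S0[, j] <- (model$init(tp, u) - model$init(tm, u)) / (2 * h)
  }
  S0
}

# Core integrator. Returns list(times, states, sens (n_t x n_x x n_theta) or
# NULL, status). `times` need not start at 0; the initial state is defined at
# t = 0 and a leading 0 is inserted when missing.
integrate_model <- function(model, theta, u, times, tol = solver_tol(),
                            sens = FALSE) {
  n_x <- model$n_x
  n_theta <- model$n_theta
  prepend0 <- times[1] > 0
  tt <- if (prepend0) c(0, times) else times

  x0 <- tryCatch(model$init(theta, u), error = function(e) NULL)
  if (is.null(x0) || !is_finite_vec(x0)) {
    return(list(times = times, states = NULL, sens = NULL,
                status = "integration_failure"))
  }
  y0 <- x0
  if (sens) y0 <- c(x0, as.vector(init_sens(model, theta, u)))

  out <- tryCatch(suppressWarnings({
    if (!is.null(model$compiled)) {
      cf <- model$compiled
      deSolve::ode(
        y = y0, times = tt,
        func = if (sens) cf$sens_func else cf$func,
        parms = cf$pack(theta, u), dllname = cf$dllname,
        initfunc = cf$initfunc, method = "bdf",
        rtol = tol$rtol, atol = tol$atol, maxsteps = tol$maxsteps
      )
    } else {
      func <- if (!sens) {
        function(t, y, p) list(model$rhs(t, y, theta, u))
      } else {
        function(t, y, p) {
          x <- y[seq_len(n_x)]
          S <- matrix(y[-seq_len(n_x)], n_x, n_theta)
          f <- model$rhs(t, x, theta, u)
          Jx <- if (!is.null(model$jac_x)) model$jac_x(t, x, theta, u) else
            fd_jac_x(model, t, x, theta, u)
          Jt <- if (!is.null(model$jac_theta)) model$jac_theta(t, x, theta, u) else
            fd_jac_theta(model, t, x, theta, u)
          list(c(f, as.vector(Jx %*% S + Jt)))
        }
      }
      deSolve::ode(y = y0, times = tt, func = func, parms = NULL,
                   method = "bdf", rtol = tol$rtol, atol = tol$atol,
                   maxsteps = tol$maxsteps)
    }
  }), error = function(e) NULL)

  ok <- !is.null(out) && nrow(out) == length(tt) &&
    all(is.finite(out[, -1, drop = FALSE]))
  if (!ok) {
    return(list(times = times, states = NULL, sens = NULL,
                status = "integration_failure"))
  }
  if (prepend0) out <- out[-1, , drop = FALSE]
  states <- out[, 1 + seq_len(n_x), drop = FALSE]
  colnames(states) <- model$state_names
  sens_arr <- NULL
  if (sens) {
    raw <- out[, -(seq_len(n_x + 1)), drop = FALSE]
    sens_arr <- array(raw, dim = c(nrow(states), n_x, n_theta))
  }
  list(times = times, states = states, sens = sens_arr, status = "ok")
}

obs_matrix <- function(model, states, theta, u) {
  v <- vapply(seq_len(nrow(states)),
              function(k) as.numeric(model$obs(states[k, ], theta, u)),
              numeric(model$n_obs))
  if (model$n_obs == 1) matrix(as.numeric(v), ncol = 1) else t(unname(v))
}

#' Simulate one experimental condition
#'
#' Integrates the model with the BDF scheme and evaluates the observable map
#' at the requested output times. Solver failure (divergence, step-limit) is
#' reported through `status = "integration_failure"` with `states = NULL`;
#' it is never raised as an error, so that optimization-level callers (the
#' rescue interceptor in particular) can react.
#'
#' @param model an [ode_model()].
#' @param theta parameter vector on the linear scale.
#' @param u input-parameter vector of the condition (length `model$n_u`).
#' @param times strictly increasing, non-empty output time grid.
#' @param tol solver tolerances, see [solver_tol()].
#' @return a `trajectory`: list with `times`, `states` (time x n_x),
#'   `observables` (time x n_obs), `status` in `{"ok",
#'   "integration_failure"}`.
#' @export
simulate_condition <- function(model, theta, u, times, tol = solver_tol()) {
  stopifnot(length(times) > 0, !is.unsorted(times, strictly = TRUE))
  if (length(theta) != model$n_theta) {
    stop_config("theta has length %d, model expects %d", length(theta), model$n_theta)
  }
  res <- integrate_model(model, theta, u, times, tol, sens = FALSE)
  obs <- NULL
  if (res$status == "ok") {
    obs <- obs_matrix(model, res$states, theta, u)
    colnames(obs) <- model$observable_names
    if (!all(is.finite(obs))) res$status <- "integration_failure"
  }
  structure(list(times = times, states = res$states, observables = obs,
                 status = res$status),
            class = "trajectory")
}

#' Simulate to steady state
#'
#' Integrates an autonomous model to `t = 1e8` and accepts the end point as a
#' steady state iff the tolerance-weighted root-mean-square norm of the vector
#' field, `sqrt(mean((f_i / (atol + rtol * |x_i|))^2))` with `atol = 1e-16`
#' and `rtol = 1e-8`, is below 1 (the standard solver error-norm convention).
#' The norm must hold at the half horizon as well: a state drifting at a
#' constant rate grows until the relative weight makes the end-point norm
#' approach 1 from above, so the half-horizon check rejects such
#' false equilibria while leaving genuinely equilibrating systems (which
#' settle long before either checkpoint) unaffected.
#'
#' @inheritParams simulate_condition
#' @param t_ss horizon used to reach the equilibrium.
#' @return list with `state`, `observables`, `status` in `{"ok",
#'   "not_converged", "integration_failure"}`, and `fnorm` (the weighted
#'   norm, NA on integration failure).
#' @export
simulate_steady_state <- function(model, theta, u, tol = solver_tol(),
                                  t_ss = 1e8) {
  res <- integrate_model(model, theta, u, c(t_ss / 2, t_ss), tol, sens = FALSE)
  if (res$status != "ok") {
    return(list(state = NULL, observables = NULL,
                status = "integration_failure", fnorm = NA_real_))
  }
  wnorm_at <- function(k) {
    x <- res$states[k, ]
    f <- model$rhs(res$times[k], x, theta, u)
    sqrt(mean((f / (1e-16 + 1e-8 * abs(x)))^2))
  }
  wnorm_half <- wnorm_at(1)
  wnorm <- wnorm_at(2)
  converged <- is.finite(wnorm) && is.finite(wnorm_half) &&
    wnorm < 1 && wnorm_half < 1
  x <- res$states[2, ]
  y <- model$obs(x, theta, u)
  names(y) <- model$observable_names
  list(state = x, observables = y,
       status = if (converged) "ok" else "not_converged", fnorm = wnorm)
}

#' Forward output sensitivities on the log10 parameter scale
#'
#' Solves the forward variational system (state sensitivities `S = dx/dtheta`
#' appended to the state vector) and maps to observable sensitivities
#' `dy/dtheta = H_x S + H_theta`, then applies the chain rule
#' `d theta / d log10(theta) = theta * ln 10`, so the result is the gradient
#' building block on the optimization scale. Observable-map Jacobians come
#' from `model$obs_jac` when provided, otherwise from central finite
#' differences of the (algebraic) observable map.
#'
#' @inheritParams simulate_condition
#' @param steady_state if `TRUE`, sensitivities of the steady-state readout
#'   (variational system integrated to the steady-state horizon).
#' @return list with `dy_dtheta` (time x n_obs x n_theta, log10 scale),
#'   `observables`, `states`, `status`.
#' @export
compute_output_sensitivities <- function(model, theta, u, times,
                                         tol = solver_tol(),
                                         steady_state = FALSE) {
  tt <- if (steady_state) 1e8 else times
  res <- integrate_model(model, theta, u, tt, tol, sens = TRUE)
  if (res$status != "ok") {
    return(list(dy_dtheta = NULL, observables = NULL, states = NULL,
                status = res$status))
  }
  n_t <- nrow(res$states)
  dy <- array(0, dim = c(n_t, model$n_obs, model$n_theta))
  obs <- matrix(0, n_t, model$n_obs)
  for (k in seq_len(n_t)) {
    x <- res$states[k, ]
    S <- matrix(res$sens[k, , ], model$n_x, model$n_theta)
    if (!is.null(model$obs_jac)) {
      oj <- model$obs_jac(x, theta, u)
      Hx <- oj$Jx; Ht <- oj$Jtheta
    } else {
      Hx <- matrix(0, model$n_obs, model$n_x)
      for (i in seq_len(model$n_x)) {
        h <- 1e-7 * (1 + abs(x[i]))
        xp <- x; xp[i] <- x[i] + h
        xm <- x; xm[i] <- x[i] - h
        Hx[, i] <- (model$obs(xp, theta, u) - model$obs(xm, theta, u)) / (2 * h)
      }
      Ht <- matrix(0, model$n_obs, model$n_theta)
      for (j in seq_len(model$n_theta)) {
        h <- 1e-7 * (1 + abs(theta[j]))
        tp <- theta; tp[j] <- theta[j] + h
        tm <- theta; tm[j] <- theta[j] - h
        Ht[, j] <- (model$obs(x, tp, u) - model$obs(x, tm, u)) / (2 * h)
      }
    }
    obs[k, ] <- model$obs(x, theta, u)
    dy[k, , ] <- Hx %*% S + Ht
  }
  # chain rule to log10 scale
  scale <- theta * LN10
  dy <- sweep(dy, 3, scale, "*")
  if (!all(is.finite(dy))) {
    return(list(dy_dtheta = NULL, observables = NULL, states = NULL,
                status = "integration_failure"))
  }
  list(dy_dtheta = dy, observables = obs, states = res$states, status = "ok")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points, status: %s\n",
              length(x$times), x$status))
  invisible(x)
}
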