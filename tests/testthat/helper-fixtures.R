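# Shared fixtures, all built in code.

# one-state linear decay: xdot = -k x, x(0) = 1, y = x
model_decay <- function() {
  ode_model(
    rhs = function(t, x, theta, u) -theta[1] * x,
    init = function(theta, u) 1,
    obs = function(x, theta, u) x,
    jac_x = function(t, x, theta, u) matrix(-theta[1], 1, 1),
    jac_theta = function(t, x, theta, u) matrix(-x, 1, 1),
    state_names = "x", parameter_names = "k_decay",
    input_names = character(), observable_names = "y",
    name = "decay"
  )
}

# divergent fixture: xdot = k x with huge k overflows over a long horizon
model_blowup <- function() {
  ode_model(
    rhs = function(t, x, theta, u) theta[1] * x,
    init = function(theta, u) 1,
    obs = function(x, theta, u) x,
    state_names = "x", parameter_names = "k_grow",
    input_names = character(), observable_names = "y",
    name = "blowup"
  )
}

# relaxation to an input level: xdot = -x + u
model_relax <- function() {
  ode_model(
    rhs = function(t, x, theta, u) -x + u[1],
    init = function(theta, u) 0,
    obs = function(x, theta, u) x,
    state_names = "x", parameter_names = "unused_rate",
    input_names = "level", observable_names = "y",
    name = "relax"
  )
}

# small cascade calibration problem (compiled path), M conditions, L layers
small_cascade_problem <- function(M = 5, L = 3, seed = 42, noise = TRUE,
                                  observed = L) {
  preset <- generator_preset("fujita_like", n_conditions = M)
  preset$n_layers <- as.integer(L)
  preset$observed <- as.integer(observed)
  generate_dataset(preset, seed = seed, noise = noise,
                   theta_true = cascade_true_theta(L))
}

# a decay-model problem whose evaluations fail on a script: the init map
# returns NaN for the n-th, ... simulation (one simulation per evaluation as
# there is a single condition), which the solver reports as failure.
scripted_failure_problem <- function(fail_evals) {
  env <- new.env()
  env$n <- 0L
  model <- ode_model(
    rhs = function(t, x, theta, u) -theta[1] * x,
    init = function(theta, u) {
      env$n <- env$n + 1L
      if (env$n %in% fail_evals) NaN else 1
    },
    obs = function(x, theta, u) x,
    jac_x = function(t, x, theta, u) matrix(-theta[1], 1, 1),
    jac_theta = function(t, x, theta, u) matrix(-x, 1, 1),
    init_jac = function(theta, u) matrix(0, 1, 1),
    state_names = "x", parameter_names = "k_decay",
    input_names = character(), observable_names = "y",
    name = "scripted"
  )
  conditions <- data.frame(conditionId = "c1")
  meas <- data.frame(observableId = "y", simulationConditionId = "c1",
                     time = 1, measurement = exp(-1), noiseParameters = 0.1)
  prob <- calib_problem(model, conditions, meas, name = "scripted")
  list(problem = prob, env = env)
}

# central finite-difference gradient of the objective on the log10 scale
fd_gradient <- function(problem, theta_log10, h = 1e-5) {
  vapply(seq_along(theta_log10), function(j) {
    tp <- theta_log10; tp[j] <- tp[j] + h
    tm <- theta_log10; tm[j] <- tm[j] - h
    (evaluate_objective(problem, tp)$J - evaluate_objective(problem, tm)$J) /
      (2 * h)
  }, numeric(1))
}

# independently hand-coded optimizer recursions (the oracle for the engine)
oracle_trajectory <- function(algorithm, gradients, eta, theta0,
                              rho = 0.9, rho1 = 0.9, rho2 = 0.999,
                              eps = 1e-8) {
  theta <- theta0
  m <- v <- numeric(length(theta0))
  out <- matrix(NA_real_, length(gradients), length(theta0))
  for (r in seq_along(gradients)) {
    g <- gradients[[r]]
    if (algorithm == "sgd") {
      d <- -g
    } else if (algorithm == "momentum") {
      m <- rho * m + g
      d <- -m
    } else if (algorithm == "rmsprop") {
      v <- rho * v + (1 - rho) * g^2
      d <- -g / (sqrt(v) + eps)
    } else { # adam / adam_balanced
      if (algorithm == "adam_balanced") rho2 <- 0.9
      m <- rho1 * m + (1 - rho1) * g
      v <- rho2 * v + (1 - rho2) * g^2
      mh <- m / (1 - rho1^r)
      vh <- v / (1 - rho2^r)
      d <- -mh / (sqrt(vh) + eps)
    }
    theta <- theta + eta * d
    out[r, ] <- theta
  }
  out
}
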