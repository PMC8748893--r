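#' Construct a condition-parameterized ODE model
#'
#' An `ode_model` couples a vector field `dx/dt = f(t, x, theta, u)` with an
#' initial-state map `x(0) = x0(theta, u)` and an observable map
#' `y = h(x, theta, u)`. The input vector `u` encodes an experimental
#' condition: each condition is a distinct initial value problem for the same
#' model, e.g. one stimulus dose together with cell-line specific expression
#' scalings. Estimated parameters `theta` are always passed on the linear
#' scale; optimization-facing code works on log10(theta) and converts.
#'
#' Optional analytic Jacobians (`jac_x`, `jac_theta`) accelerate
#' forward-sensitivity computation; when absent they are approximated by
#' central finite differences of `rhs`. A model may additionally carry a
#' `compiled` descriptor pointing at native right-hand sides registered in the
#' package DLL (used by the built-in cascade family), which the simulator
#' prefers for speed; the R closures remain the reference semantics.
#'
#' @param rhs function `(t, x, theta, u) -> dx/dt` (length `n_x`).
#' @param init function `(theta, u) -> x(0)` (length `n_x`).
#' @param obs function `(x, theta, u) -> y` (length `n_obs`); `x` is a single
#'   state vector.
#' @param state_names,parameter_names,input_names,observable_names identifier
#'   character vectors; `parameter_names` must be duplicate-free.
#' @param jac_x optional function `(t, x, theta, u)` returning the
#'   `n_x x n_x` state Jacobian of `rhs`.
#' @param jac_theta optional function `(t, x, theta, u)` returning the
#'   `n_x x n_theta` parameter Jacobian of `rhs`.
#' @param obs_jac optional function `(x, theta, u)` returning
#'   `list(Jx = n_obs x n_x, Jtheta = n_obs x n_theta)` Jacobians of the
#'   observable map.
#' @param init_jac optional function `(theta, u)` returning the
#'   `n_x x n_theta` Jacobian of the initial-state map (otherwise
#'   approximated by central finite differences).
#' @param compiled optional list with entries `func`, `sens_func`, `initfunc`,
#'   `dllname`, `pack` (function `(theta, u) -> double vector` of native
#'   parameters) enabling compiled integration.
#' @param name model label used in printing.
#' @return an object of class `ode_model`.
#' @examples
#' m <- ode_model(
#'   rhs = function(t, x, theta, u) -theta[1] * x,
#'   init = function(theta, u) 1,
#'   obs = function(x, theta, u) x,
#'   state_names = "x", parameter_names = "k_decay",
#'   input_names = character(), observable_names = "y"
#' )
#' tr <- simulate_condition(m, theta = 1, u = numeric(), times = c(0.5, 1))
#' tr$observables
#' @export
ode_model <- function(rhs, init, obs, state_names, parameter_names,
                      input_names = character(), observable_names,
                      jac_x = NULL, jac_theta = NULL, obs_jac = NULL,
                      init_jac = NULL, compiled = NULL, name = "ode_model") {
  stopifnot(is.function(rhs), is.function(init), is.function(obs))
  parameter_names <- as.character(parameter_names)
  if (anyDuplicated(parameter_names)) {
    stop_config("duplicate parameter names in model definition")
  }
  structure(
    list(
      n_x = length(state_names),
      n_theta = length(parameter_names),
      n_u = length(input_names),
      n_obs = length(observable_names),
      rhs = rhs, init = init, obs = obs,
      jac_x = jac_x, jac_theta = jac_theta, obs_jac = obs_jac,
      init_jac = init_jac, compiled = compiled,
      state_names = as.character(state_names),
      parameter_names = parameter_names,
      input_names = as.character(input_names),
      observable_names = as.character(observable_names),
      name = name
    ),
    class = "ode_model"
  )
}

#' @export
print.ode_model <- function(x, ...) {
  cat(sprintf(
    "<ode_model> %s: %d states, %d parameters, %d inputs, %d observables%s\n",
    x$name, x$n_x, x$n_theta, x$n_u, x$n_obs,
    if (!is.null(x$compiled)) " (compiled rhs)" else ""
  ))
  invisible(x)
}

#' Build an ODE model from a declarative YAML description
#'
#' The schema mirrors how small signalling models are written down by hand:
#' named states with initial-value expressions, estimated parameters, input
#' parameters, one rate expression per state, and named observable
#' expressions. Expressions are ordinary arithmetic in terms of state,
#' parameter and input identifiers plus `t`.
#'
#' ```yaml
#' name: decay
#' states:      {x: "1"}
#' parameters:  [k]
#' inputs:      [dose]
#' odes:        {x: "-k * x + dose"}
#' observables: {y: "x"}
#' ```
#'
#' @param path path to a YAML file, or a yaml string.
#' @return an [ode_model()].
#' @export
model_from_yaml <- function(path) {
  spec <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  states <- names(spec$states)
  params <- as.character(spec$parameters)
  inputs <- as.character(spec$inputs %||% character())
  obs_names <- names(spec$observables)
  if (is.null(states) || is.null(spec$odes)) {
    stop_config("model YAML needs 'states' and 'odes' blocks")
  }
  missing_ode <- setdiff(states, names(spec$odes))
  if (length(missing_ode)) {
    stop_config("no rate expression for state(s): %s", paste(missing_ode, collapse = ", "))
  }
  ode_exprs <- lapply(spec$odes[states], function(s) parse(text = s)[[1]])
  init_exprs <- lapply(spec$states[states], function(s) parse(text = s)[[1]])
  obs_exprs <- lapply(spec$observables, function(s) parse(text = s)[[1]])

  make_env <- function(theta, u, x = NULL, t = NULL) {
    e <- new.env(parent = baseenv())
    for (i in seq_along(params)) assign(params[i], theta[i], envir = e)
    for (i in seq_along(inputs)) assign(inputs[i], u[i], envir = e)
    if (!is.null(x)) for (i in seq_along(states)) assign(states[i], x[i], envir = e)
    if (!is.null(t)) assign("t", t, envir = e)
    e
  }

  ode_model(
    rhs = function(t, x, theta, u) {
      e <- make_env(theta, u, x, t)
      vapply(ode_exprs, eval, numeric(1), envir = e)
    },
    init = function(theta, u) {
      e <- make_env(theta, u)
      vapply(init_exprs, eval, numeric(1), envir = e)
    },
    obs = function(x, theta, u) {
      e <- make_env(theta, u, x)
      vapply(obs_exprs, eval, numeric(1), envir = e)
    },
    state_names = states, parameter_names = params,
    input_names = inputs, observable_names = obs_names,
    name = spec$name %||% "yaml_model"
  )
}
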