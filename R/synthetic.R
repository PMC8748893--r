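# Synthetic benchmark problems with known ground truth.
#
# The time-course family is a phosphorylation cascade of L coupled
# activation/deactivation cycles observed across many experimental
# conditions. Conditions differ only through their inputs: a stimulus dose
# and per-layer total-protein (expression) scalings, emulating benchmark
# setups in which hundreds of conditions share one model but correspond to
# distinct initial value problems. Preset sizes follow the benchmark
# protocol: 600 conditions x 6,000 records, 1,200 x 12,000, and
# 1,500 x 60,000.

#' Specification of a cascade model
#'
#' @param n_layers number of phosphorylation cycles (>= 1).
#' @param observed which layers are read out; defaults to the terminal layer.
#' @param readout `"per_layer"` (one observable per observed layer, its
#'   active fraction) or `"composite"` (a single observable: the mean active
#'   fraction over the observed layers, like a total phospho-signal). The
#'   composite readout makes each layer's relaxation time visible in the
#'   output, which keeps the per-layer rate scales identifiable from a
#'   single-observable time course.
#' @return list of class `cascade_spec`.
#' @export
cascade_spec <- function(n_layers, observed = n_layers,
                         readout = c("per_layer", "composite")) {
  readout <- match.arg(readout)
  n_layers <- as.integer(n_layers)
  if (is.na(n_layers) || n_layers < 1 || n_layers > 20) {
    stop_config("n_layers must be an integer in 1..20")
  }
  observed <- as.integer(observed)
  if (!length(observed) || any(observed < 1 | observed > n_layers)) {
    stop_config("observed layers must lie in 1..n_layers")
  }
  structure(list(n_layers = n_layers, observed = sort(unique(observed)),
                 readout = readout),
            class = "cascade_spec")
}

#' Build the cascade ODE model
#'
#' Each layer i carries an inactive/active pair `(b_i, a_i)` with
#' `da_i/dt = (kb_i + ka_i s_i) b_i - kd_i a_i` and `db_i/dt` its negative;
#' the stimulus is `s_1 = dose` for layer 1 and the upstream active species
#' for deeper layers. Estimated parameters are the rate constants
#' `(ka_1..L, kd_1..L, kb_1..L)`; condition inputs are the post-switch
#' stimulus `dose`, the pre-switch stimulus `pre_dose`, and the per-layer
#' totals `T_i`. The initial state is the equilibrium under `pre_dose`,
#' computed in closed form layer by layer, so a simulation is the response
#' to a stimulus switched from `pre_dose` to `dose` at t = 0: stimulus-onset
#' experiments have `pre_dose = 0`, washout experiments have `dose = 0` and
#' a positive `pre_dose`. Observables are active fractions
#' `a_i / (a_i + b_i)` of the observed layers (or their mean, see `readout`
#' in [cascade_spec()]). The model carries analytic Jacobians and compiled
#' right-hand sides.
#'
#' @param spec a [cascade_spec()].
#' @return an [ode_model()].
#' @export
build_cascade_model <- function(spec) {
  stopifnot(inherits(spec, "cascade_spec"))
  L <- spec$n_layers
  obs_layers <- spec$observed
  a_ix <- 2 * seq_len(L)       # active state indices
  b_ix <- a_ix - 1             # inactive state indices

  split_theta <- function(theta) {
    list(ka = theta[seq_len(L)], kd = theta[L + seq_len(L)],
         kb = theta[2 * L + seq_len(L)])
  }

  rhs <- function(t, x, theta, u) {
    p <- split_theta(theta)
    s <- c(u[1], x[a_ix])[seq_len(L)]      # dose, a_1, ..., a_{L-1}
    rate <- (p$kb + p$ka * s) * x[b_ix] - p$kd * x[a_ix]
    dx <- numeric(2 * L)
    dx[b_ix] <- -rate
    dx[a_ix] <- rate
    dx
  }

  init <- function(theta, u) {
    p <- split_theta(theta)
    x0 <- numeric(2 * L)
    s <- u[2]                               # equilibrium under pre_dose
    for (i in seq_len(L)) {
      Ti <- u[2 + i]
      kon <- p$kb[i] + p$ka[i] * s
      a <- kon * Ti / (kon + p$kd[i])
      x0[2 * i - 1] <- Ti - a
      x0[2 * i] <- a
      s <- a
    }
    x0
  }

  jac_x <- function(t, x, theta, u) {
    p <- split_theta(theta)
    s <- c(u[1], x[a_ix])[seq_len(L)]
    J <- matrix(0, 2 * L, 2 * L)
    for (i in seq_len(L)) {
      kon <- p$kb[i] + p$ka[i] * s[i]
      J[2 * i, 2 * i - 1] <- kon
      J[2 * i, 2 * i] <- -p$kd[i]
      if (i > 1) J[2 * i, 2 * i - 2] <- p$ka[i] * x[2 * i - 1]
      J[2 * i - 1, ] <- -J[2 * i, ]
    }
    J
  }

  jac_theta <- function(t, x, theta, u) {
    s <- c(u[1], x[a_ix])[seq_len(L)]
    J <- matrix(0, 2 * L, 3 * L)
    for (i in seq_len(L)) {
      b <- x[2 * i - 1]; a <- x[2 * i]
      J[2 * i, i] <- s[i] * b          # ka_i
      J[2 * i, L + i] <- -a            # kd_i
      J[2 * i, 2 * L + i] <- b         # kb_i
      J[2 * i - 1, ] <- -J[2 * i, ]
    }
    J
  }

  composite <- identical(spec$readout, "composite")
  n_obs_model <- if (composite) 1L else length(obs_layers)

  obs_fun <- function(x, theta, u) {
    frac <- x[2 * obs_layers] / (x[2 * obs_layers] + x[2 * obs_layers - 1])
    if (composite) mean(frac) else frac
  }

  obs_jac <- function(x, theta, u) {
    Jx <- matrix(0, length(obs_layers), 2 * L)
    for (k in seq_along(obs_layers)) {
      i <- obs_layers[k]
      b <- x[2 * i - 1]; a <- x[2 * i]
      tot2 <- (a + b)^2
      Jx[k, 2 * i] <- b / tot2
      Jx[k, 2 * i - 1] <- -a / tot2
    }
    if (composite) Jx <- matrix(colMeans(Jx), 1)
    list(Jx = Jx, Jtheta = matrix(0, n_obs_model, 3 * L))
  }

  pack <- function(theta, u) {
    p <- numeric(2 + 3 * 20)
    p[1] <- L
    p[2] <- u[1]
    p[2 + seq_len(3 * L)] <- theta
    p
  }

  ode_model(
    rhs = rhs, init = init,
    obs = obs_fun,
    jac_x = jac_x, jac_theta = jac_theta, obs_jac = obs_jac,
    compiled = list(func = "mbode_cascade_derivs",
                    sens_func = "mbode_cascade_sens_derivs",
                    initfunc = "mbode_cascade_init",
                    dllname = "mbode", pack = pack),
    state_names = as.vector(rbind(paste0("inactive_", seq_len(L)),
                                  paste0("active_", seq_len(L)))),
    parameter_names = c(paste0("k_act_", seq_len(L)),
                        paste0("k_deact_", seq_len(L)),
                        paste0("k_basal_", seq_len(L))),
    input_names = c("dose", "pre_dose", paste0("total_", seq_len(L))),
    observable_names = if (composite) "obs_phospho_total" else
      paste0("obs_active_", obs_layers),
    name = sprintf("cascade_%dL%s", L, if (composite) "c" else "")
  )
}

#' Ground-truth rates for a cascade
#'
#' A fixed, well-posed choice with layer relaxation times of a few model time
#' units, so that every layer's timescale (not only its steady-state gain)
#' leaves a signature inside the sampled time window -- the property that
#' makes the rate scale of each cycle identifiable from time-course data.
#' Rates are varied per layer so that no two layers are exchangeable.
#'
#' @param n_layers cascade depth.
#' @return named parameter vector on the linear scale.
#' @export
cascade_true_theta <- function(n_layers) {
  ka <- rep(c(0.40, 0.25, 0.35, 0.20), length.out = n_layers)
  kd <- rep(c(0.20, 0.12, 0.25, 0.15), length.out = n_layers)
  kb <- rep(c(0.03, 0.05, 0.02, 0.04), length.out = n_layers)
  stats::setNames(c(ka, kd, kb),
                  c(paste0("k_act_", seq_len(n_layers)),
                    paste0("k_deact_", seq_len(n_layers)),
                    paste0("k_basal_", seq_len(n_layers))))
}

#' Generator presets
#'
#' `fujita_like`: 2-layer cascade, 600 conditions, 1 composite observable x
#' 10 time points = 6,000 records. `bachmann_like`: 3 layers, 1,200
#' conditions, 12,000 records. `lucarelli_like`: 4 layers, 4 per-layer
#' observables, 1,500 conditions, 60,000 records. `viability_like`:
#' steady-state dose-response problem (see
#' [generate_viability_dataset()]). The smallest preset is dimensioned so
#' that all of its rate constants are practically identifiable from the
#' generated data (see the methods vignette); the deeper cascades carry
#' weakly determined directions on purpose, as larger benchmarks do.
#'
#' @param name preset name.
#' @param n_conditions optional override of the condition count (reduced-
#'   scale versions of the same problem).
#' @return list describing the preset.
#' @export
generator_preset <- function(name = c("fujita_like", "bachmann_like",
                                      "lucarelli_like", "viability_like"),
                             n_conditions = NULL) {
  name <- match.arg(name)
  p <- switch(name,
    fujita_like = list(name = name, n_layers = 2L, observed = 1:2,
                       readout = "composite", n_conditions = 600L,
                       times = seq(1, 19, by = 2)),
    bachmann_like = list(name = name, n_layers = 3L, observed = 1:3,
                         readout = "composite", n_conditions = 1200L,
                         times = seq(1, 19, by = 2)),
    lucarelli_like = list(name = name, n_layers = 4L, observed = 1:4,
                          readout = "per_layer", n_conditions = 1500L,
                          times = seq(1, 19, by = 2)),
    viability_like = list(name = name, n_cell_lines = 12L, n_drugs = 7L,
                          n_doses = 8L)
  )
  if (!is.null(n_conditions)) p$n_conditions <- as.integer(n_conditions)
  # noise SD = 5% of each observable's dynamic range: large enough to make
  # calibration non-trivial, small enough that the reduced-scale benchmark
  # stays identifiable (layer rate scales are weakly determined directions;
  # see the methods vignette)
  p$noise_frac <- 0.05
  p
}

#' Sample experimental conditions for a cascade preset
#'
#' Each condition combines a stimulus dose from a log-spaced grid with
#' per-layer expression scalings drawn log-uniformly from \[0.2, 5\].
#' Conditions alternate between stimulus-onset experiments (`pre_dose = 0`,
#' readout of the activation transient) and washout experiments (system
#' pre-equilibrated at the dose, stimulus removed at t = 0, readout of the
#' relaxation); the washout arm pins the deactivation timescales that onset
#' data alone determine only weakly.
#'
#' @param preset a cascade preset from [generator_preset()].
#' @param seed integer seed (conditions are deterministic given the seed).
#' @return data.frame with `conditionId`, `dose`, `pre_dose`, `total_1..L`.
#' @export
sample_conditions <- function(preset, seed = 1) {
  M <- preset$n_conditions
  L <- preset$n_layers
  withr_seed(derive_seed(seed, 11L), {
    dose_grid <- 10^seq(-1.5, 0.5, length.out = 12)
    level <- sample(dose_grid, M, replace = TRUE)
    washout <- rep_len(c(FALSE, TRUE), M)
    scal <- matrix(exp(stats::runif(M * L, log(0.2), log(5))), M, L)
    cond <- data.frame(conditionId = sprintf("c%04d", seq_len(M)),
                       dose = ifelse(washout, 0, level),
                       pre_dose = ifelse(washout, level, 0))
    for (i in seq_len(L)) cond[[paste0("total_", i)]] <- scal[, i]
    cond
  })
}

# run code under a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic calibration problem
#'
#' Simulates every condition of the preset at the ground-truth parameters on
#' the preset time grid and adds independent Gaussian noise with SD equal to
#' `noise_frac` (default 5%) of each observable's dynamic range, emitting a
#' ready-to-fit [calib_problem()] with PEtab-flavoured tables and the truth
#' attached.
#'
#' @param preset preset name or object from [generator_preset()].
#' @param seed integer seed; conditions and noise derive from it through
#'   separate streams.
#' @param theta_true ground-truth parameters (linear scale); default
#'   [cascade_true_theta()].
#' @param noise add measurement noise (disable for self-consistency checks:
#'   without noise `J(theta_true) = 0`).
#' @param n_conditions optional reduced condition count.
#' @return a [calib_problem()] with `theta_true` set.
#' @export
generate_dataset <- function(preset = "fujita_like", seed = 1,
                             theta_true = NULL, noise = TRUE,
                             n_conditions = NULL) {
  if (is.character(preset)) preset <- generator_preset(preset, n_conditions)
  if (identical(preset$name, "viability_like")) {
    return(generate_viability_dataset(
      n_cell_lines = preset$n_cell_lines, n_drugs = preset$n_drugs,
      n_doses = preset$n_doses, seed = seed, noise = noise))
  }
  model <- build_cascade_model(cascade_spec(preset$n_layers, preset$observed,
                                            preset$readout %||% "per_layer"))
  if (is.null(theta_true)) theta_true <- cascade_true_theta(preset$n_layers)
  if (any(theta_true < 1e-5 | theta_true > 1e3)) {
    stop_config("theta_true outside the feasible box [1e-5, 1e3]")
  }
  conditions <- sample_conditions(preset, seed)
  times <- preset$times
  n_obs <- model$n_obs

  sims <- matrix(NA_real_, nrow(conditions) * length(times), n_obs)
  for (k in seq_len(nrow(conditions))) {
    u <- as.numeric(conditions[k, model$input_names])
    tr <- simulate_condition(model, theta_true, u, times)
    if (tr$status != "ok") {
      stop_config("simulation failed at ground truth for condition %s",
                  conditions$conditionId[k])
    }
    sims[(k - 1) * length(times) + seq_along(times), ] <- tr$observables
  }

  rng <- apply(sims, 2, function(col) diff(range(col)))
  sigma_obs <- pmax(preset$noise_frac * rng, 1e-4)

  meas <- data.frame(
    observableId = rep(rep(model$observable_names, each = length(times)),
                       nrow(conditions)),
    simulationConditionId = rep(conditions$conditionId,
                                each = length(times) * n_obs),
    time = rep(times, nrow(conditions) * n_obs),
    measurement = as.vector(vapply(seq_len(nrow(conditions)), function(k) {
      as.vector(sims[(k - 1) * length(times) + seq_along(times), ])
    }, numeric(length(times) * n_obs))),
    noiseParameters = rep(rep(sigma_obs, each = length(times)),
                          nrow(conditions))
  )
  if (noise) {
    meas$measurement <- withr_seed(derive_seed(seed, 13L), {
      meas$measurement + stats::rnorm(nrow(meas), 0, meas$noiseParameters)
    })
  }
  problem <- calib_problem(model, conditions, meas, theta_true = theta_true,
                           name = preset$name)
  problem$descriptor <- list(type = "cascade", n_layers = preset$n_layers,
                             observed = preset$observed,
                             readout = preset$readout %||% "per_layer")
  problem
}

#' Generate the steady-state viability dose-response problem
#'
#' Emulates cell-line drug-response calibration: one viability readout per
#' experimental condition, taken at steady state. Viability follows
#' `dv/dt = k_grow (1 - v) - k_kill E v` with drug effect
#' `E = s_c * sum_d emax_d dose_d / (ec50_d + dose_d)`, where `s_c` is a
#' cell-line sensitivity input. Conditions are all cell line x drug x dose
#' combinations plus one untreated condition per cell line. A condition is
#' labelled responsive iff its noiseless ground-truth readout falls below 50%
#' of the untreated readout of the same cell line (strict); the labels are
#' emitted for ROC testing as `attr(problem, "labels")`.
#'
#' @param n_cell_lines,n_drugs,n_doses design size (all >= 1).
#' @param seed integer seed.
#' @param noise add Gaussian measurement noise (10% of the readout range).
#' @return a [calib_problem()] with attributes `labels` (data.frame) and
#'   `theta_true`.
#' @export
generate_viability_dataset <- function(n_cell_lines = 12, n_drugs = 7,
                                       n_doses = 8, seed = 1, noise = TRUE) {
  stopifnot(n_cell_lines >= 1, n_drugs >= 1, n_doses >= 1)
  D <- n_drugs
  par_names <- c("k_grow", "k_kill", paste0("ec50_", seq_len(D)),
                 paste0("emax_", seq_len(D)))
  input_names <- c("sens", paste0("dose_", seq_len(D)))

  effect <- function(theta, u) {
    ec50 <- theta[2 + seq_len(D)]
    emax <- theta[2 + D + seq_len(D)]
    dose <- u[1 + seq_len(D)]
    u[1] * sum(emax * dose / (ec50 + dose))
  }
  model <- ode_model(
    rhs = function(t, x, theta, u) {
      theta[1] * (1 - x) - theta[2] * effect(theta, u) * x
    },
    init = function(theta, u) 1,
    obs = function(x, theta, u) x[1],
    jac_x = function(t, x, theta, u) {
      matrix(-theta[1] - theta[2] * effect(theta, u), 1, 1)
    },
    jac_theta = function(t, x, theta, u) {
      ec50 <- theta[2 + seq_len(D)]
      emax <- theta[2 + D + seq_len(D)]
      dose <- u[1 + seq_len(D)]
      E <- effect(theta, u)
      J <- numeric(2 + 2 * D)
      J[1] <- 1 - x
      J[2] <- -E * x
      J[2 + seq_len(D)] <- theta[2] * x * u[1] * emax * dose / (ec50 + dose)^2
      J[2 + D + seq_len(D)] <- -theta[2] * x * u[1] * dose / (ec50 + dose)
      matrix(J, 1)
    },
    obs_jac = function(x, theta, u) {
      list(Jx = matrix(1, 1, 1), Jtheta = matrix(0, 1, 2 + 2 * D))
    },
    state_names = "viability", parameter_names = par_names,
    input_names = input_names, observable_names = "viability",
    name = "viability"
  )

  theta_true <- withr_seed(derive_seed(seed, 21L), {
    stats::setNames(
      c(0.1, 1,
        10^stats::runif(D, -1.2, 0.5),     # ec50 within the dose range
        stats::runif(D, 0.3, 1.5)),        # per-drug efficacy
      par_names)
  })

  dose_grid <- 10^seq(-2, 1, length.out = n_doses)
  cells <- sprintf("cell%02d", seq_len(n_cell_lines))
  sens <- withr_seed(derive_seed(seed, 22L),
                     exp(stats::runif(n_cell_lines, log(0.2), log(5))))

  rowsu <- list(); labels <- list()
  k <- 0
  for (c_i in seq_len(n_cell_lines)) {
    add <- function(drug, dose) {
      k <<- k + 1
      u <- c(sens[c_i], numeric(D))
      if (drug > 0) u[1 + drug] <- dose
      id <- if (drug == 0) sprintf("%s_untreated", cells[c_i]) else
        sprintf("%s_d%d_l%d", cells[c_i], drug, dose_i)
      rowsu[[k]] <<- c(list(conditionId = id), as.list(u))
      labels[[k]] <<- data.frame(conditionId = id, cell_line = cells[c_i],
                                 drug = drug, dose = dose)
    }
    dose_i <- 0; add(0, 0)
    for (d in seq_len(D)) for (dose_i in seq_len(n_doses)) {
      add(d, dose_grid[dose_i])
    }
  }
  conditions <- do.call(rbind, lapply(rowsu, function(r) {
    as.data.frame(stats::setNames(r, c("conditionId", input_names)))
  }))
  conditions$steadyState <- TRUE
  labels <- do.call(rbind, labels)

  readout <- vapply(seq_len(nrow(conditions)), function(i) {
    u <- as.numeric(conditions[i, input_names])
    ss <- simulate_steady_state(model, theta_true, u)
    if (ss$status != "ok") {
      stop_config("steady state did not converge at ground truth (%s)",
                  conditions$conditionId[i])
    }
    as.numeric(ss$observables)
  }, numeric(1))
  labels$readout_true <- readout
  untreated <- readout[match(sprintf("%s_untreated", labels$cell_line),
                             conditions$conditionId)]
  labels$responsive <- readout < 0.5 * untreated

  sigma <- max(0.1 * diff(range(readout)), 1e-4)
  meas <- data.frame(
    observableId = "viability",
    simulationConditionId = conditions$conditionId,
    time = Inf,
    measurement = if (noise) {
      withr_seed(derive_seed(seed, 23L),
                 readout + stats::rnorm(length(readout), 0, sigma))
    } else readout,
    noiseParameters = sigma
  )
  problem <- calib_problem(model, conditions, meas, theta_true = theta_true,
                           name = "viability_like")
  problem$descriptor <- list(type = "viability", n_drugs = D)
  attr(problem, "labels") <- labels
  problem
}
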