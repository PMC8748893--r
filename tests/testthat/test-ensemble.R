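# History smoothing, ensemble construction, predictions, spectra.

scripted_history <- function(J, theta = NULL, steps_per_epoch = 2,
                             n_records = 10) {
  n <- length(J)
  if (is.null(theta)) theta <- matrix(seq_len(n), n, 1)
  structure(list(theta = theta, J_batch = J,
                 n_records = rep(n_records, n),
                 epoch = ceiling(seq_len(n) / steps_per_epoch),
                 steps_per_epoch = steps_per_epoch, n_steps = n),
            class = "mb_history")
}

test_that("history smoothing is a truncated centered mean over one epoch", {
  expect_equal(smooth_history(rep(4, 7), 4), rep(4, 7))
  expect_equal(smooth_history(5, 4), 5)
  x <- c(10, 8, 6, 4, 2, 4, 6, 8, 10, 12)
  # window 4 -> half-width 2, truncated at the ends (hand-computed)
  hand <- vapply(seq_along(x), function(i) {
    mean(x[max(1, i - 2):min(10, i + 2)])
  }, numeric(1))
  expect_equal(smooth_history(x, 4), hand)
  expect_equal(hand[1], mean(c(10, 8, 6)))
  expect_equal(hand[5], mean(c(6, 4, 2, 4, 6)))
})

test_that("ensemble admission and thinning match hand enumeration", {
  # two starts; objective per record J/n gives rmse sqrt(2 J / n)
  h1 <- scripted_history(c(50, 10, 5, 5, 5, 5), steps_per_epoch = 2)
  h2 <- scripted_history(c(50, 40, 30, 20, 20, 20), steps_per_epoch = 2)
  ens <- build_ensemble(list(h1, h2), tolerance = 0.10, cap = Inf)
  # hand enumeration: smoothed per-record traces (window 2 -> half-width 1)
  sm1 <- sapply(1:6, function(i) mean(c(50, 10, 5, 5, 5, 5)[max(1, i - 1):min(6, i + 1)])) / 10
  sm2 <- sapply(1:6, function(i) mean(c(50, 40, 30, 20, 20, 20)[max(1, i - 1):min(6, i + 1)])) / 10
  rmse <- sqrt(2 * c(sm1, sm2))
  cutoff <- min(rmse) * 1.10
  expect_equal(ens$cutoff, cutoff)
  expect_identical(nrow(ens$members), sum(rmse <= cutoff))
  # admissibility invariant
  expect_true(all(ens$provenance$rmse <= ens$cutoff))

  # thinning to 1 per (start, epoch) keeps at most one member per cell
  ens1 <- build_ensemble(list(h1, h2), tolerance = 0.10, cap = 1)
  tab <- table(ens1$provenance$start, ens1$provenance$epoch)
  expect_true(all(tab <= 1))
  # cap = Inf is the identity relative to admission
  expect_gte(nrow(ens$members), nrow(ens1$members))

  # nothing admissible -> empty ensemble with a warning
  h3 <- scripted_history(c(5, 5, 100, 100))
  expect_warning(e0 <- build_ensemble(list(h3), tolerance = -0.99),
                 "no parameter vectors")
  expect_identical(nrow(e0$members), NULL)
})

test_that("top-k final ensembles pick the k best starts", {
  finals <- data.frame(start = 1:4, J_full = c(4, 1, NA, 2),
                       pearson_r = NA, rmse = c(2, 1, NA, 1.5),
                       termination = "completed", cost = 1)
  hists <- lapply(1:4, function(i) {
    structure(list(final_theta = c(i, i)), class = "mb_history")
  })
  res <- structure(list(histories = hists, finals = finals),
                   class = "multistart_result")
  ens <- top_k_ensemble(res, k = 2)
  expect_equal(ens$provenance$start, c(2, 4))
  expect_equal(unname(ens$members), rbind(c(2, 2), c(4, 4)))
})

test_that("ensemble predictions average member simulations", {
  prob <- small_cascade_problem(M = 3, L = 2, seed = 61, noise = FALSE)
  th <- log10(prob$theta_true)
  single <- structure(list(members = matrix(th, 1)), class = "parameter_ensemble")
  p1 <- ensemble_predict(prob, single)
  expect_true(all(p1$predictions$sd == 0))
  expect_equal(p1$predictions$mean, prob$measurements$measurement,
               tolerance = 1e-6)

  two <- structure(list(members = rbind(th, th + 0.1)),
                   class = "parameter_ensemble")
  p2 <- ensemble_predict(prob, two)
  a <- p1$predictions$mean
  b <- ensemble_predict(prob, structure(list(members = matrix(th + 0.1, 1)),
                                        class = "parameter_ensemble"))$predictions$mean
  expect_equal(p2$predictions$mean, (a + b) / 2, tolerance = 1e-9)
  # duplicating members: SD computed over members as listed
  four <- structure(list(members = rbind(th, th, th + 0.1, th + 0.1)),
                    class = "parameter_ensemble")
  p4 <- ensemble_predict(prob, four)
  expect_equal(p4$predictions$mean, p2$predictions$mean, tolerance = 1e-9)
  expect_equal(p4$predictions$sd, abs(b - a) / 2 * sqrt(4 / 3) / sqrt(2) *
                 sqrt(2), tolerance = 1e-6)
})

test_that("covariance spectra expose the explored subspace", {
  # members on a line: a single nonzero eigenvalue
  base <- c(1, 2, 3)
  members <- t(sapply(seq(-1, 1, length.out = 9), function(a) a * base))
  sp <- covariance_spectrum(structure(list(members = members),
                                      class = "parameter_ensemble"))
  expect_gt(sp$eigenvalues[1], 0)
  expect_equal(sp$eigenvalues[-1], rep(0, 2), tolerance = 1e-12)
  expect_equal(sum(sp$explained), 1, tolerance = 1e-10)

  # trace identity and near-isotropy of an isotropic sample
  set.seed(62)
  iso <- matrix(rnorm(1000 * 5), 1000, 5)
  spi <- covariance_spectrum(structure(list(members = iso),
                                       class = "parameter_ensemble"))
  expect_equal(sum(spi$eigenvalues), sum(diag(stats::cov(iso))),
               tolerance = 1e-10)
  expect_lt(max(spi$eigenvalues) / min(spi$eigenvalues), 1.5)
})

test_that("output-sensitivity SVD finds non-informative directions", {
  # layer 2 unobserved: its three rates cannot influence the observed output
  prob <- small_cascade_problem(M = 2, L = 2, seed = 63, observed = 1)
  th <- log10(prob$theta_true)
  sv <- output_sensitivity_svd(prob, rbind(th))
  expect_lte(length(sv$singular_values), 6)
  expect_lt(sv$numerical_rank, prob$model$n_theta)
  expect_lte(sv$numerical_rank, 3)

  # algebraic model with a hand Jacobian: singular values match closed form
  lin <- ode_model(
    rhs = function(t, x, theta, u) c(0, 0),
    init = function(theta, u) c(theta[1] + theta[2], theta[1] - theta[2]),
    obs = function(x, theta, u) x,
    init_jac = function(theta, u) matrix(c(1, 1, 1, -1), 2, 2),
    state_names = c("s1", "s2"), parameter_names = c("p1", "p2"),
    observable_names = c("y1", "y2")
  )
  conds <- data.frame(conditionId = "c1")
  meas <- data.frame(observableId = c("y1", "y2"),
                     simulationConditionId = "c1", time = 1,
                     measurement = c(3, 1), noiseParameters = 1)
  probl <- calib_problem(lin, conds, meas)
  th0 <- log10(c(2, 1))
  svl <- output_sensitivity_svd(probl, rbind(th0))
  # dy/dlog10 theta = [[1,1],[1,-1]] %*% diag(theta ln 10)
  handJ <- matrix(c(1, 1, 1, -1), 2, 2, byrow = TRUE) %*% diag(c(2, 1) * log(10))
  expect_equal(svl$singular_values, svd(handJ)$d, tolerance = 1e-6)
})
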