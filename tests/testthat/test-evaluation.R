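# Ranking, convergence thresholds, responder classification, ROC, coverage.

test_that("settings are ranked per start with averaged ties, failures worst", {
  # two settings, A always better
  finals <- rbind(A = c(1, 2, 3), B = c(2, 3, 4))
  rt <- rank_settings(finals)
  expect_equal(unname(rt$mean_rank), c(1, 2))
  # equal finals share the averaged rank
  rt2 <- rank_settings(rbind(A = c(1, 1), B = c(1, 1)))
  expect_equal(unname(rt2$mean_rank), c(1.5, 1.5))
  # failed runs rank worst (tied among themselves)
  rt3 <- rank_settings(rbind(A = c(NA, 1), B = c(5, NA), C = c(1, 2)))
  expect_equal(unname(rt3$ranks[, 1]), c(3, 2, 1))
  expect_equal(unname(rt3$ranks[, 2]), c(1, 3, 2))
  # per-start rank sums are S(S+1)/2
  expect_true(all(colSums(rt3$ranks) == 6))
})

test_that("random ranking tables match a brute-force oracle", {
  set.seed(41)
  for (i in 1:5) {
    finals <- matrix(sample(1:6, 12, replace = TRUE), 3, 4,
                     dimnames = list(paste0("s", 1:3), NULL))
    rt <- rank_settings(finals)
    oracle <- sapply(1:4, function(j) rank(finals[, j], ties.method = "average"))
    expect_equal(unname(rt$ranks), unname(oracle))
    expect_equal(rt$mean_rank, rowMeans(oracle))
  }
  # invariance: a per-start constant shift leaves ranks unchanged
  finals <- matrix(rnorm(12), 3, 4)
  shifted <- sweep(finals, 2, c(10, -5, 0, 100), "+")
  expect_equal(rank_settings(finals)$ranks, rank_settings(shifted)$ranks)
})

test_that("value-to-reach is mean + 1 SD of the ten best reference finals", {
  expect_equal(value_to_reach(rep(3, 10)), 3)
  v <- c(rep(0, 9), 10)
  expect_equal(value_to_reach(v), 1 + sqrt(10))
  # values worse than the 10th do not move the threshold
  expect_equal(value_to_reach(c(v, 50, 99)), 1 + sqrt(10))
  expect_warning(t5 <- value_to_reach(1:5), "using all")
  expect_equal(t5, 3 + sd(1:5))
})

test_that("convergence metrics match hand computation on scripted histories", {
  mk <- function(epoch_J, cost_per_epoch, total) {
    structure(list(epoch_full = data.frame(epoch = seq_along(epoch_J),
                                           J_full = epoch_J,
                                           cost = cost_per_epoch * seq_along(epoch_J)),
                   total_cost = total, n_steps = length(epoch_J)),
              class = "mb_history")
  }
  hs <- list(mk(c(10, 5, 2), 100, 400),   # crosses 3 at epoch 3 (cost 300)
             mk(c(10, 9, 8), 100, 400),   # never converges
             mk(c(2.5, 2, 1), 100, 400))  # crosses at epoch 1 (cost 100)
  cm <- convergence_metrics(hs, threshold = 3)
  expect_identical(cm$n_converged, 2L)
  expect_equal(cm$cost_to_first_convergence, 100)
  expect_equal(cm$converged_per_cost, 2 / (1200 / 1e6))
  # loosening the threshold never decreases the converged count
  for (thr in c(1, 2, 5, 20)) {
    expect_gte(convergence_metrics(hs, thr + 1)$n_converged,
               convergence_metrics(hs, thr)$n_converged)
  }
  # nothing below the threshold: Inf sentinel
  cm0 <- convergence_metrics(hs, threshold = 0.1)
  expect_identical(cm0$n_converged, 0L)
  expect_identical(cm0$cost_to_first_convergence, Inf)
})

test_that("waterfall sorts ascending with stable ties", {
  f <- c(3, 1, 2, 1, NA)
  wf <- waterfall(f)
  expect_equal(wf$start, c(2, 4, 3, 1, 5))
  expect_equal(wf$value, c(1, 1, 2, 3, NA))
  sorted <- sort(f[1:4])
  expect_equal(waterfall(sorted)$value, sorted)
  expect_equal(waterfall(rev(sorted))$value, sorted)
})

test_that("responder classification uses the strict >50% reduction rule", {
  ref <- c(g1 = 1, g2 = 2)
  expect_identical(
    classify_responsive(c(1, 0.49, 0.5, 0.999), c("g1", "g1", "g1", "g2"), ref),
    c(FALSE, TRUE, FALSE, TRUE))
  expect_error(classify_responsive(1, "g3", ref), "reference")
})

test_that("ROC endpoints, AUC and threshold behave on canonical cases", {
  # perfectly separated
  roc <- roc_and_threshold(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(roc$auc, 1)
  expect_equal(roc$accuracy, 1)
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
  expect_true(!is.unsorted(roc$tpr) && !is.unsorted(roc$fpr))
  # scores carrying no information
  roc2 <- roc_and_threshold(rep(1, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(roc2$auc, 0.5)
  expect_error(roc_and_threshold(1:4, rep(TRUE, 4)), "both classes")
  # thresholds transfer to new scores
  expect_identical(roc_classify(c(0.2, 10.5), roc$chosen_threshold),
                   c(FALSE, TRUE))
})

test_that("AUC equals the normalized Mann-Whitney statistic", {
  mw_auc <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    comp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(comp)
  }
  set.seed(53)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(rnorm(n, mean = labels), 1)  # ties likely
    expect_equal(roc_and_threshold(scores, labels)$auc,
                 mw_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("our ROC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
  scores <- rnorm(40, mean = labels)
  ours <- roc_and_threshold(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("parameter-interval coverage is the span over the bound width", {
  space <- list(lower = c(-5, -5), upper = c(3, 3))
  th <- rbind(c(-5, 0), c(-1, 0))
  expect_equal(parameter_interval_coverage(th, space), c(0.5, 0))
  th2 <- rbind(c(-5, -5), c(3, 3))
  expect_equal(parameter_interval_coverage(th2, space), c(1, 1))
  expect_error(parameter_interval_coverage(th[1, , drop = FALSE], space),
               "two runs")
  expect_error(parameter_interval_coverage(th, list(lower = c(0, 0),
                                                    upper = c(0, 1))),
               "degenerate")
})
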