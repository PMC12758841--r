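test_that("AUC matches the worked example and handles degenerate ties", {
  expect_equal(binary_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(binary_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(binary_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(binary_auc(c(0.1, 0.2), c(1, 1)), "single class")
})

test_that("average precision matches hand enumeration and tie formula", {
  expect_equal(average_precision(c(0.9, 0.8, 0.7), c(1, 0, 1)),
               (1 * 1 + (2 / 3) * 1) / 2, tolerance = 1e-12)
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # constant scores: AP equals prevalence
  set.seed(31)
  y <- stats::rbinom(200, 1, 0.3)
  expect_equal(average_precision(rep(0.5, 200), y), mean(y),
               tolerance = 1e-12)
  expect_error(average_precision(c(0.2, 0.3), c(0, 0)), "no positives")
})

test_that("ranking metrics equal brute-force oracles on 200 random
           instances", {
  set.seed(32)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    # coarse grid forces frequent ties
    s <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_identical(binary_auc(s, y), brute_auc(s, y))
    expect_equal(average_precision(s, y), brute_ap(s, y),
                 tolerance = 1e-12)
  }
})

test_that("ranking metrics are invariant under monotone transforms", {
  set.seed(33)
  s <- stats::runif(60)
  y <- stats::rbinom(60, 1, 0.4)
  y[1:2] <- c(0, 1)
  for (f in list(function(x) 3 * x + 1, function(x) x^3,
                 function(x) stats::qlogis(pmin(pmax(x, 1e-6),
                                                1 - 1e-6)))) {
    expect_equal(binary_auc(f(s), y), binary_auc(s, y), tolerance = 1e-12)
    expect_equal(average_precision(f(s), y), average_precision(s, y),
                 tolerance = 1e-12)
  }
})

test_that("thresholded metrics come from the confusion table with
           fallbacks", {
  m <- threshold_metrics(c(1, 0, 0, 1), c(1, 0, 1, 0), threshold = 0.5)
  expect_equal(unname(m), rep(0.5, 5))

  mp <- threshold_metrics(c(0.9, 0.1, 0.8, 0.2), c(1, 0, 1, 0))
  expect_true(all(mp == 1))

  # all-negative predictions on mixed labels
  mn <- threshold_metrics(c(0.1, 0.2, 0.3), c(1, 0, 1))
  expect_equal(unname(mn[c("recall", "precision", "f1")]), c(0, 0, 0))
  expect_equal(unname(mn["specificity"]), 1)

  # specificity on flipped labels equals recall on the originals
  set.seed(34)
  s <- stats::runif(50)
  y <- stats::rbinom(50, 1, 0.5)
  a <- threshold_metrics(s, y)
  b <- threshold_metrics(1 - s, 1 - y, threshold = 0.5 + 1e-12)
  expect_equal(unname(a[["recall"]]), unname(b[["specificity"]]),
               tolerance = 1e-12)
})

test_that("macro report averages with population SD and flags undefined
           labels", {
  set.seed(35)
  probs <- matrix(stats::runif(40 * 3), 40, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  labs <- cbind(a = stats::rbinom(40, 1, 0.5),
                b = stats::rbinom(40, 1, 0.3),
                c = rep(0L, 40))
  expect_warning(rep1 <- macro_report(probs, labs), "single-class")
  expect_false(rep1$per_label$defined[3])
  expect_identical(rep1$macro$n_labels[rep1$macro$metric == "auc"], 2)

  # hand-checkable macro mean and SD: {0.8, 0.9}
  expect_equal(mean(c(0.8, 0.9)), 0.85)
  pop_sd <- sqrt(mean((c(0.8, 0.9) - 0.85)^2))
  expect_equal(pop_sd, 0.05)
  # identical per-label values: SD 0 via the same code path
  probs2 <- cbind(a = c(0.9, 0.9, 0.1, 0.1), b = c(0.9, 0.9, 0.1, 0.1))
  labs2 <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))
  rep2 <- macro_report(probs2, labs2)
  expect_equal(rep2$macro$sd[rep2$macro$metric == "auc"], 0)
})

test_that("Platt scaling recovers the identity on calibrated data", {
  set.seed(36)
  n <- 10000
  z <- stats::rnorm(n, 0, 2)
  y <- stats::rbinom(n, 1, stats::plogis(z))
  cal <- fit_platt(matrix(z, ncol = 1), matrix(y, ncol = 1))
  expect_lt(abs(cal$a[1] - 1), 0.1)
  expect_lt(abs(cal$b[1]), 0.1)

  # a constant logit shift is absorbed by the intercept
  delta <- 1.7
  cal2 <- fit_platt(matrix(z + delta, ncol = 1), matrix(y, ncol = 1))
  expect_equal(cal2$a[1], cal$a[1], tolerance = 0.05)
  expect_equal(cal2$b[1], cal$b[1] - cal2$a[1] * delta, tolerance = 0.1)

  # monotone recalibration leaves AUC unchanged
  p_raw <- stats::plogis(z)
  p_cal <- drop(apply_platt(matrix(z, ncol = 1), cal))
  expect_equal(binary_auc(p_cal, y), binary_auc(p_raw, y),
               tolerance = 1e-12)

  expect_warning(fit_platt(matrix(z[1:10], ncol = 1),
                           matrix(rep(1, 10), ncol = 1)), "single-class")
})

test_that("calibration curve bins conserve counts and positives", {
  set.seed(37)
  p <- stats::runif(5000)
  y <- stats::rbinom(5000, 1, p)
  cc <- calibration_curve(p, y, n_bins = 10)
  expect_identical(sum(cc$count), 5000L)
  occupied <- cc$count > 0
  expect_true(all(abs(cc$mean_pred[occupied] - cc$obs_freq[occupied])
                  < 0.05))
  expect_equal(sum(cc$count * cc$obs_freq, na.rm = TRUE), sum(y))

  # single occupied bin
  cc2 <- calibration_curve(rep(0.5, 100), rep(c(0, 1), 50))
  expect_identical(sum(cc2$count > 0), 1L)
  expect_equal(cc2$obs_freq[cc2$count > 0], 0.5)
})

test_that("subgroup reports partition records by sex and age quartile", {
  set.seed(38)
  n <- 100
  probs <- matrix(stats::runif(n * 2), n, 2)
  labs <- matrix(stats::rbinom(n * 2, 1, 0.5), n, 2)
  demo <- list(ages = as.numeric(1:100), sexes = rep(c("M", "F"), 50))

  sg <- subgroup_report(probs, labs, demo, scheme = "age_quartile")
  expect_equal(sg$breaks, c(25.75, 50.5, 75.25))
  sizes <- vapply(sg$groups, function(g) g$n, integer(1))
  expect_equal(unname(sizes), c(25, 25, 25, 25))
  all_idx <- sort(unname(unlist(lapply(sg$groups, `[[`, "ids"))))
  expect_identical(all_idx, 1:100)

  sgp <- subgroup_report(probs, labs, demo, scheme = "age_quartile",
                         age_breaks = "preset")
  expect_equal(sgp$breaks, c(54, 66, 78))

  # single-sex cohort: one populated group, one empty
  demo2 <- list(ages = demo$ages, sexes = rep("F", 100))
  sg2 <- subgroup_report(probs, labs, demo2, scheme = "sex")
  expect_identical(sg2$groups$male$n, 0L)
  expect_null(sg2$groups$male$report)
  expect_identical(sg2$groups$female$n, 100L)
})
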