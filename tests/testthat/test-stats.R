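test_that("response transforms match their definitions", {
  expect_equal(transform_response(0.25, "sqrt"), 0.5)
  expect_equal(transform_response(c(0, 1), "sqrt"), c(0, 1))
  expect_equal(transform_response(0, "log", offset = 1), 0)
  expect_equal(transform_response(exp(2) - 1, "log"), 2)
  expect_error(transform_response(-0.1, "sqrt"), "negative")
  expect_error(transform_response(1.5, "sqrt"), "proportions")
})

test_that("exactly linear responses give the exact slope with zero se", {
  trials <- 1:10
  metrics <- do.call(rbind, lapply(1:5, function(i)
    data.frame(animal_id = paste0("a", i), trial_index = trials,
               prop_on_spot = (0.2 + 0.03 * trials)^2)))
  est <- estimate_learning_slope(metrics, "prop_on_spot", "sqrt", n_boot = 0)
  expect_equal(est$slope, 0.03, tolerance = 1e-12)
  expect_equal(est$se, 0, tolerance = 1e-12)
  # constant responses give slope zero
  metrics$prop_on_spot <- 0.25
  est0 <- estimate_learning_slope(metrics, "prop_on_spot", "sqrt", n_boot = 0)
  expect_equal(est0$slope, 0, tolerance = 1e-12)
})

test_that("animals with too few trials are dropped, all dropped errors", {
  metrics <- data.frame(animal_id = c("a1", "a1", "a1", "a2"),
                        trial_index = c(1, 2, 3, 1),
                        prop_on_spot = c(0.1, 0.2, 0.3, 0.5))
  expect_warning(est <- estimate_learning_slope(metrics, n_boot = 0),
                 "dropped")
  expect_equal(est$n_animals, 1)
  lone <- metrics[4, ]
  expect_error(suppressWarnings(estimate_learning_slope(lone, n_boot = 0)),
               "no animal")
})

test_that("slope estimator is calibrated on its generative model", {
  covered <- 0; bias <- c(); ses <- c()
  for (r in 1:30) {
    m <- gen_metrics_session(seed = 7 + r, n_animals = 15, n_trials = 10)
    est <- estimate_learning_slope(m, "prop_on_spot", "sqrt", n_boot = 0)
    covered <- covered + (est$ci95[1] <= 0.026 && 0.026 <= est$ci95[2])
    bias <- c(bias, est$slope - 0.026); ses <- c(ses, est$se)
  }
  expect_gte(covered, 26)                       # ~95% nominal over 30 runs
  expect_lt(abs(mean(bias)), mean(ses) / 2)
})

test_that("Mann-Whitney exact p matches the permutation oracle", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-9)
  set.seed(61)
  for (rep in 1:20) {
    x <- stats::rnorm(sample(3:6, 1)); y <- stats::rnorm(sample(3:6, 1))
    got <- mann_whitney_u(x, y)
    want <- mw_perm_oracle(x, y)
    expect_equal(unname(got$statistic), want$u)
    expect_equal(got$p_value, want$p, tolerance = 1e-9)
  }
})

test_that("identical samples give the central U and approximation is close", {
  x <- c(1, 2, 3, 7)
  r <- mann_whitney_u(x, x)
  expect_equal(unname(r$statistic), length(x)^2 / 2)
  set.seed(71)
  deltas <- replicate(50, {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    exact <- mw_perm_oracle(x, y)$p
    approx <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))$p.value
    abs(exact - approx)
  })
  expect_lt(max(deltas), 0.02)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 5), 1.0)
  expect_equal(bonferroni(0.0158, m = 5), 0.079)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni(c(0.01, 0.02)),
               stats::p.adjust(c(0.01, 0.02), "bonferroni"))
  expect_error(bonferroni(1.2), "0, 1")
})

test_that("2x2 chi-square matches the closed form and stats::chisq.test", {
  tab <- rbind(c(13, 2), c(5, 10))
  r <- chi_square_2x2(tab)
  expect_equal(r$statistic, 8.888889, tolerance = 1e-6)
  expect_equal(r$p_value, 0.002869, tolerance = 1e-4)
  ref <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  # identical proportions give zero; transposition leaves it unchanged
  expect_equal(chi_square_2x2(rbind(c(10, 5), c(10, 5)))$statistic, 0)
  expect_equal(chi_square_2x2(t(tab))$statistic, r$statistic)
  # Yates correction matches the reference implementation
  refc <- stats::chisq.test(tab, correct = TRUE)
  expect_equal(chi_square_2x2(tab, TRUE)$statistic, unname(refc$statistic),
               tolerance = 1e-12)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "margins")
  expect_error(chi_square_2x2(rbind(c(1.5, 2), c(3, 4))), "integers")
})
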