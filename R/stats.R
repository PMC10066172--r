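#' Variance-stabilizing response transforms
#'
#' The two transforms applied before slope estimation: square root for the
#' on-spot time proportion and natural log for the latency. Latencies of
#' zero are handled by the additive `offset` (default +1 s), which is also
#' applied to censored trial-length latencies as-is.
#'
#' @param values numeric vector; proportions in [0, 1] for `"sqrt"`,
#'   non-negative latencies for `"log"`.
#' @param kind `"sqrt"` or `"log"`.
#' @param offset additive offset for the log transform, seconds.
#' @return transformed vector.
#' @export
transform_response <- function(values, kind = c("sqrt", "log"), offset = 1) {
  kind <- match.arg(kind)
  if (any(values < 0, na.rm = TRUE)) stop("negative values cannot be transformed")
  if (kind == "sqrt") {
    if (any(values > 1 + 1e-9, na.rm = TRUE))
      stop("sqrt transform expects proportions in [0, 1]")
    sqrt(values)
  } else {
    if (any(values + offset <= 0, na.rm = TRUE))
      stop("log transform needs values + offset > 0")
    log(values + offset)
  }
}

#' Learning slope of a transformed response across trials
#'
#' Two-stage estimator of the mean per-trial change: (1) an ordinary
#' least-squares line of the transformed response on trial number is fitted
#' per animal; (2) the arena-level slope is the mean of the per-animal
#' slopes, with `se = sd / sqrt(n)` and a t-based 95% CI. A nonparametric
#' bootstrap over animals provides an alternative percentile CI. Animals
#' with fewer than `min_trials` usable trials are dropped with a warning.
#'
#' @param metrics tidy metrics table with columns `animal_id`,
#'   `trial_index` and the response column.
#' @param response column name, e.g. `"prop_on_spot"` or `"latency_s"`.
#' @param transform `"sqrt"`, `"log"` or `"none"`.
#' @param offset log-transform offset, seconds.
#' @param min_trials minimum usable trials per animal (default 3).
#' @param n_boot bootstrap resamples over animals (0 disables).
#' @param seed seed for the bootstrap.
#' @return object of class `learning_slope`: `slope`, `se`, `ci95`,
#'   `ci95_boot`, `n_animals`, `per_animal` (named slope vector),
#'   `response`, `transform`.
#' @export
estimate_learning_slope <- function(metrics, response = "prop_on_spot",
                                    transform = c("sqrt", "log", "none"),
                                    offset = 1, min_trials = 3,
                                    n_boot = 2000, seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(response %in% names(metrics), "trial_index" %in% names(metrics))
  y <- metrics[[response]]
  y <- switch(transform,
              sqrt = transform_response(y, "sqrt"),
              log = transform_response(y, "log", offset = offset),
              none = y)
  dat <- data.frame(animal = as.character(metrics$animal_id),
                    trial = as.numeric(metrics$trial_index), y = y)
  dat <- dat[is.finite(dat$y), , drop = FALSE]
  slopes <- c()
  dropped <- character(0)
  for (a in unique(dat$animal)) {
    d <- dat[dat$animal == a, ]
    if (nrow(d) < min_trials || length(unique(d$trial)) < 2) {
      dropped <- c(dropped, a)
      next
    }
    slopes[a] <- unname(stats::coef(stats::lm(y ~ trial, data = d))["trial"])
  }
  if (length(dropped))
    warning("dropped animals with < ", min_trials, " usable trials: ",
            paste(dropped, collapse = ", "))
  n <- length(slopes)
  if (n == 0) stop("no animal has enough usable trials")
  slope <- mean(slopes)
  se <- if (n >= 2) stats::sd(slopes) / sqrt(n) else NA_real_
  ci95 <- if (n >= 2)
    slope + c(-1, 1) * stats::qt(0.975, n - 1) * se else c(NA_real_, NA_real_)
  ci_boot <- c(NA_real_, NA_real_)
  if (n_boot > 0 && n >= 2) {
    set.seed(seed)
    boots <- replicate(n_boot, mean(sample(slopes, n, replace = TRUE)))
    ci_boot <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  structure(list(slope = slope, se = se, ci95 = ci95, ci95_boot = ci_boot,
                 n_animals = n, per_animal = slopes, response = response,
                 transform = transform),
            class = "learning_slope")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with midrank ties: the p value is exact (by
#' enumeration) when `n1 + n2 <= 12` and there are no ties, otherwise the
#' normal approximation with tie and continuity corrections is used. The
#' reported statistic is U for the first sample.
#'
#' @param x,y non-empty numeric samples.
#' @return object of class `test_result`: `statistic`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  structure(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "mann-whitney exact"
                          else "mann-whitney normal approximation"),
            class = "test_result")
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` element-wise; `m` defaults to the family size, i.e. the
#' number of p values supplied.
#'
#' @param p_values p values in [0, 1].
#' @param m family size.
#' @return adjusted p values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p values must lie in [0, 1]")
  pmin(1, m * p_values)
}

#' 2x2 chi-square test
#'
#' Pearson chi-square on a 2x2 count table via the closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, one degree of freedom, upper
#' tail; optional Yates continuity correction.
#'
#' @param tab 2x2 matrix of non-negative integer counts, all margins > 0.
#' @param continuity_correction apply Yates' correction (default `FALSE`).
#' @return object of class `test_result`: `statistic`, `p_value`, `method`.
#' @export
chi_square_2x2 <- function(tab, continuity_correction = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  num <- abs(a * d - b * c_)
  if (continuity_correction) num <- max(0, num - n / 2)
  stat <- n * num^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  structure(list(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = if (continuity_correction)
                   "chi-square 2x2 (Yates)" else "chi-square 2x2"),
            class = "test_result")
}
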