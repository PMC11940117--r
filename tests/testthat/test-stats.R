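test_that("age grouping follows the printed decade bins", {
  expect_equal(as.character(assign_age_group(19.38)), "18-20")
  expect_equal(as.character(assign_age_group(20.99)), "18-20")
  expect_equal(as.character(assign_age_group(21.0)), "21-30")
  expect_equal(as.character(assign_age_group(88.92)), "81-88")
  expect_equal(as.character(assign_age_group(60.5)), "51-60")
  expect_error(assign_age_group(17.9), "age")
  expect_error(assign_age_group(89), "age")
})

test_that("group summaries give the closed-form mean, SE and CI", {
  d <- tibble::tibble(v = c(1, 2, 3), g = "a")
  gs <- group_summary(d, v, g)
  expect_equal(gs$mean, 2)
  expect_equal(gs$se, 1 / sqrt(3))
  expect_equal(gs$ci_lo, 2 - 1.96 / sqrt(3))
  expect_equal(gs$ci_hi, 2 + 1.96 / sqrt(3))
  # zero variance: degenerate point interval
  d2 <- tibble::tibble(v = rep(5, 4L), g = "a")
  gs2 <- group_summary(d2, v, g)
  expect_equal(gs2$se, 0)
  expect_equal(gs2$ci_lo, 5)
  expect_equal(gs2$ci_hi, 5)
  # n = 1 group: SE missing with a warning
  d3 <- tibble::tibble(v = c(1, 2, 3), g = c("a", "a", "b"))
  expect_warning(gs3 <- group_summary(d3, v, g), "n < 2")
  expect_true(is.na(gs3$se[gs3$group == "b"]))
})

test_that("normal-approximation CI attains nominal coverage", {
  set.seed(914)
  n <- 40L
  hits <- vapply(seq_len(1000L), function(i) {
    x <- stats::rnorm(n, mean = 1.7, sd = 2)
    gs <- group_summary(tibble::tibble(v = x, g = "a"), v, g)
    gs$ci_lo <= 1.7 && 1.7 <= gs$ci_hi
  }, logical(1L))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("independent t-test matches the pooled closed form and conventions", {
  # A = {1,2,3}, B = {2,3,4}: pooled s = 1, t = -1 / sqrt(2/3), df = 4
  tt <- ttest_independent(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * stats::pt(-abs(tt$t), df = 4), tolerance = 1e-12)
  # identical groups
  tt0 <- ttest_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  # degenerate zero-variance conventions
  expect_equal(ttest_independent(c(2, 2), c(2, 2))$p, 1)
  expect_equal(ttest_independent(c(2, 2), c(3, 3))$p, 0)
  # Welch flag reaches the unequal-variance test
  tw <- ttest_independent(c(1, 2, 3, 4), c(10, 30), welch = TRUE)
  ref <- stats::t.test(c(1, 2, 3, 4), c(10, 30))
  expect_equal(tw$t, unname(ref$statistic))
  expect_equal(tw$df, unname(ref$parameter))
  expect_error(ttest_independent(1, c(1, 2)), "n >= 2")
})

test_that("stepwise backward elimination recovers a noiseless signal and drops duplicates", {
  set.seed(5)
  n <- 60L
  d <- tibble::tibble(
    x1 = stats::rnorm(n), x2 = stats::rnorm(n), x3 = stats::rnorm(n),
    x4 = stats::rnorm(n), x5 = stats::rnorm(n), x6 = stats::rnorm(n)
  )
  d$y <- d$x1
  fit <- stepwise_backward(d, "y", paste0("x", 1:6))
  expect_identical(fit$terms$term, "x1")
  expect_equal(fit$terms$estimate, 1, tolerance = 1e-10)

  # duplicated column: exactly one of the pair enters, the other is recorded
  d$x1_dup <- d$x1
  fit2 <- stepwise_backward(d, "y", c(paste0("x", 1:6), "x1_dup"))
  expect_length(
    intersect(c("x1", "x1_dup"), fit2$dropped_collinear), 1L
  )
  expect_length(intersect(c("x1", "x1_dup"), fit2$terms$term), 1L)

  # n too small
  expect_error(
    stepwise_backward(d[1:5, ], "y", paste0("x", 1:6)),
    "n > number of predictors"
  )
})

test_that("stepwise elimination is deterministic with a monotone R^2 trace", {
  set.seed(8)
  n <- 80L
  X <- matrix(stats::rnorm(n * 8L), n, 8L)
  colnames(X) <- paste0("p", 1:8)
  y <- X[, 1L] * 0.6 + X[, 2L] * 0.4 + stats::rnorm(n)
  d <- tibble::as_tibble(as.data.frame(X))
  d$y <- y
  f1 <- stepwise_backward(d, "y", paste0("p", 1:8))
  f2 <- stepwise_backward(d, "y", paste0("p", 1:8))
  expect_identical(f1$terms, f2$terms)
  expect_identical(f1$trace, f2$trace)
  # removing the least significant predictor can only lower R^2
  expect_true(all(diff(f1$trace$r_squared) <= 1e-12))
  expect_lte(f1$r_squared, f1$trace$r_squared[1L] + 1e-12)
  # every retained predictor is significant
  expect_true(all(f1$terms$p.value < 0.05))
})

test_that("standardization makes the fit invariant to predictor scaling", {
  set.seed(13)
  n <- 70L
  d <- tibble::tibble(
    a = stats::rnorm(n), b = stats::rnorm(n), c = stats::rnorm(n)
  )
  d$y <- 0.8 * d$a - 0.5 * d$b + stats::rnorm(n, sd = 0.7)
  f_raw <- stepwise_backward(d, "y", c("a", "b", "c"))
  d2 <- d
  d2$a <- d2$a * 1000
  d2$b <- d2$b * 1e-4
  f_scaled <- stepwise_backward(d2, "y", c("a", "b", "c"))
  expect_identical(f_raw$terms$term, f_scaled$terms$term)
  expect_equal(f_raw$terms$estimate, f_scaled$terms$estimate, tolerance = 1e-10)
})

test_that("tidy and glance views expose the elimination outcome", {
  set.seed(21)
  n <- 50L
  d <- tibble::tibble(u = stats::rnorm(n), v = stats::rnorm(n))
  d$w <- d$u
  d$y <- d$u + stats::rnorm(n, sd = 0.3)
  fit <- stepwise_backward(d, "y", c("u", "v", "w"))
  td <- tidy(fit)
  expect_setequal(td$term, c("u", "v", "w"))
  expect_setequal(unique(td$status), c("retained", "eliminated", "collinear"))
  gl <- glance(fit)
  expect_equal(gl$n, n)
  expect_equal(gl$n.retained + gl$n.eliminated + gl$n.collinear, 3L)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("trend-shape classification distinguishes U, monotone and other patterns", {
  u <- detect_trend_shape(c(5, 4, 3, 2, 3))
  expect_equal(u$shape, "U_SHAPED")
  expect_equal(u$argmin, 4L)
  expect_equal(detect_trend_shape(c(5, 4, 3, 2, 1))$shape, "MONOTONE_DECREASING")
  expect_equal(detect_trend_shape(c(1, 2, 3, 4))$shape, "MONOTONE_INCREASING")
  expect_equal(detect_trend_shape(c(1, 2, 1, 2))$shape, "OTHER") # min at the edge
  expect_equal(detect_trend_shape(c(2, 1, 1, 2))$shape, "U_SHAPED") # flat bottom
  expect_equal(detect_trend_shape(c(3, 2, 1, 1))$shape, "OTHER") # no rebound
  expect_error(detect_trend_shape(c(1, 2, 3)), "at least 4")
})
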