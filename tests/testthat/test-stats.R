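test_that("robust regression equals OLS on an exact line and resists outliers", {
  x <- 1:12
  y <- 2.5 * x - 1
  r <- robust_regression(x, y)
  expect_equal(r$slope, 2.5, tolerance = 1e-8)
  expect_equal(r$intercept, -1, tolerance = 1e-8)
  # one gross outlier barely moves the slope
  y2 <- y
  y2[4] <- y2[4] + 200
  r2 <- robust_regression(x, y2)
  expect_equal(r2$slope, 2.5, tolerance = 0.01)
  expect_lt(min(r2$weights), 0.01)  # the outlier is downweighted
  expect_error(robust_regression(rep(1, 10), rnorm(10)), "constant")
})

test_that("robust regression matches OLS on clean noisy data", {
  set.seed(91)
  x <- rnorm(40)
  y <- 1.2 * x + rnorm(40, 0, 0.3)
  r <- robust_regression(x, y)
  ols <- unname(coef(lm(y ~ x))[2])
  expect_equal(r$slope, ols, tolerance = 0.05)
  expect_lt(r$p, 1e-6)
})

test_that("the within-subject slope test behaves at its analytic extremes", {
  # identical nonzero slopes: degenerate, maximal evidence
  d <- do.call(rbind, lapply(1:20, function(s)
    data.frame(subject = s, x = 1:4, y = 3 * (1:4) + s)))
  r <- within_subject_slope_test(d)
  expect_true(is.infinite(r$t) && r$t > 0)
  expect_lt(r$p, 1e-6)
  # slopes exactly symmetric around zero: mean zero
  d2 <- do.call(rbind, lapply(1:10, function(s) {
    sl <- if (s %% 2 == 0) 1 else -1
    data.frame(subject = s, x = 1:4, y = sl * (1:4))
  }))
  r2 <- within_subject_slope_test(d2)
  expect_equal(abs(r2$t), 0, tolerance = 1e-10)
  expect_equal(r2$p, 1, tolerance = 1e-10)
  # a single subject cannot support the test
  expect_error(within_subject_slope_test(
    data.frame(subject = 1, x = 1:4, y = 1:4)), "2 subjects")
  # subjects with one condition are dropped with a warning
  d3 <- rbind(d2, data.frame(subject = 99, x = 1, y = 1))
  expect_warning(within_subject_slope_test(d3), "dropped")
})

test_that("paired area tests handle identical, offset and modulated inputs", {
  tt <- seq(-300, 0, by = 4)
  mk <- function(amp) make_lrp(tt, amp * exp(-(tt + 100)^2 / 80^2))
  subs <- paste0("s", 1:8)
  a <- setNames(lapply(1:8, function(i) mk(3)), subs)
  r_id <- paired_area_test(a, a, c(-150, -50))
  expect_equal(r_id$t, 0)
  expect_equal(r_id$p, 1)
  expect_true(r_id$zero_variance)
  # constant offset in every subject: zero variance, maximal t
  b <- setNames(lapply(1:8, function(i) mk(2)), subs)
  r_off <- paired_area_test(a, b, c(-150, -50))
  expect_true(is.infinite(r_off$t) && r_off$t > 0)
  expect_true(r_off$zero_variance)
  # subject-varying amplitude difference in a fixed direction
  set.seed(92)
  c1 <- setNames(lapply(1:8, function(i) mk(3 + rnorm(1, 0, 0.1))), subs)
  c2 <- setNames(lapply(1:8, function(i) mk(2 + rnorm(1, 0, 0.1))), subs)
  r_mod <- paired_area_test(c1, c2, c(-150, -50))
  expect_gt(r_mod$t, 4)
  expect_lt(r_mod$p, 0.01)
  names(b)[1] <- "zz"
  expect_error(paired_area_test(a, b, c(-150, -50)), "match")
})
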