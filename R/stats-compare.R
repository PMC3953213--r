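#' Robust regression (iteratively reweighted least squares, bisquare)
#'
#' Linear regression of `y` on `x` with Tukey bisquare weights (tuning
#' constant 4.685) via [MASS::rlm()]. On data with an exact linear
#' relationship the result equals ordinary least squares. The p-value uses
#' a t reference distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return A list: `slope`, `intercept`, `t`, `p`, `df`, `weights`,
#'   `method` (`"rlm"`, or `"ols"` when the fit is exact and the robust
#'   scale degenerates).
#' @export
robust_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0) stop("x is constant; regression is degenerate")
  n <- length(x)
  ols <- lm(y ~ x)
  res <- list(slope = unname(coef(ols)[2]), intercept = unname(coef(ols)[1]))
  if (max(abs(ols$residuals)) < 1e-10 * max(1, sd(y))) {
    # exact line: the robust scale is zero, return the OLS solution
    se <- suppressWarnings(summary(ols))$coefficients[2, 2]
    tv <- if (se > 0) res$slope / se else sign(res$slope) * Inf
    return(c(res, list(t = tv, p = 2 * pt(-abs(tv), n - 2), df = n - 2,
                       weights = rep(1, n), method = "ols")))
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  sm <- summary(fit)$coefficients
  tv <- sm[2, 3]
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       t = tv, p = 2 * pt(-abs(tv), n - 2), df = n - 2,
       weights = fit$w, method = "rlm")
}

#' t-test on per-subject regression slopes
#'
#' Fits an OLS slope of `y` on `x` within each subject and tests the
#' slopes against zero with a one-sample t-test. This is the
#' repeated-measures test used for within-subject relations between an LRP
#' measure and a DDM parameter (e.g. peak height on starting point), with
#' the condition value as a continuous within-subject factor.
#'
#' @param data Data frame with columns `subject`, `x`, `y` (>= 2 rows with
#'   distinct `x` per subject; subjects failing this are dropped with a
#'   warning).
#' @return A list: `t`, `df`, `p`, `slopes` (named per subject).
#' @export
within_subject_slope_test <- function(data) {
  stopifnot(all(c("subject", "x", "y") %in% names(data)))
  subjects <- unique(data$subject)
  slopes <- c()
  dropped <- character(0)
  for (s in subjects) {
    d <- data[data$subject == s, , drop = FALSE]
    if (nrow(d) < 2L || sd(d$x) == 0) { dropped <- c(dropped, s); next }
    slopes[as.character(s)] <- unname(coef(lm(y ~ x, data = d))[2])
  }
  if (length(dropped))
    warning("dropped subject(s) with < 2 usable conditions: ",
            paste(dropped, collapse = ", "))
  if (length(slopes) < 2L)
    stop("need at least 2 subjects with slopes for the t-test")
  if (sd(slopes) == 0) {
    # all slopes identical: the t statistic degenerates
    m <- mean(slopes)
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                df = length(slopes) - 1, p = if (m == 0) 1 else 0,
                slopes = slopes, zero_variance = TRUE))
  }
  tt <- t.test(slopes, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, slopes = slopes, zero_variance = FALSE)
}

#' Paired t-test on per-subject areas between two LRP curves
#'
#' For each subject, integrates the difference between the two waveforms
#' over the window ([lrp_area_between()]); the areas are then tested
#' against zero with a one-sample t-test (equivalently, a paired t-test on
#' the two curves). If all subjects show the identical nonzero area the t
#' statistic degenerates; this is reported as `t = +/-Inf` with
#' `zero_variance = TRUE`.
#'
#' @param lrps_a,lrps_b Named lists of `lrp_waveform`s, matched by subject.
#' @param window_ms Integration window (ms).
#' @return A list: `t`, `df`, `p`, `areas` (per subject),
#'   `zero_variance`.
#' @export
paired_area_test <- function(lrps_a, lrps_b, window_ms) {
  if (is.null(names(lrps_a)) || is.null(names(lrps_b)) ||
      !setequal(names(lrps_a), names(lrps_b)))
    stop("subject names of the two waveform lists must match")
  subs <- names(lrps_a)
  areas <- vapply(subs, function(s)
    lrp_area_between(lrps_a[[s]], lrps_b[[s]], window_ms), numeric(1))
  n <- length(areas)
  if (n < 2L) stop("need at least 2 subjects")
  if (sd(areas) == 0) {
    m <- mean(areas)
    if (m == 0)
      return(list(t = 0, df = n - 1, p = 1, areas = areas,
                  zero_variance = TRUE))
    return(list(t = sign(m) * Inf, df = n - 1, p = 0, areas = areas,
                zero_variance = TRUE))
  }
  tt <- t.test(areas, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       areas = areas, zero_variance = FALSE)
}
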