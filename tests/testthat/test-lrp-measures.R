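test_that("onset regression is exact on a noiseless flat-then-ramp waveform", {
  tt <- seq(0, 800, by = 4)
  y <- pmax(0, tt - 300) * 0.01
  expect_equal(lrp_onset(make_lrp(tt, y)), 300)
  # all-flat input: no rise to detect
  expect_error(lrp_onset(make_lrp(tt, rep(0.5, length(tt)))), "no rise")
})

test_that("onset is median-unbiased within one sample at SNR 10", {
  tt <- seq(0, 800, by = 4)
  signal <- pmax(0, pmin(tt - 300, 200)) * 0.02  # ramp 300..500 then flat
  amp <- max(signal)
  est <- vapply(1:100, function(s) {
    set.seed(s)
    y <- signal + rnorm(length(tt), 0, amp / 10)
    lrp_onset(make_lrp(tt, y), window_ms = c(0, 800))
  }, numeric(1))
  expect_lte(abs(median(est) - 300), 4)  # one sample at 250 Hz
})

test_that("response-locked peaks follow the last-peak-before-trough rule", {
  tt <- seq(-600, 200, by = 4)
  bump <- function(center, width, amp) amp * exp(-(tt - center)^2 / width^2)
  # single bump peaking 90 ms pre-response
  l <- make_lrp(tt, bump(-90, 60, 3), locking = "response")
  pk <- lrp_peak(l, "response")
  expect_equal(pk$peak_latency_ms, -88, tolerance = 5)
  expect_equal(pk$peak_height_uv, 3 - min(l$amplitude[tt < pk$peak_latency_ms]),
               tolerance = 0.05)
  # two bumps, both pre-response: the last is selected even if the first is
  # taller in between lies the trough that sets the height
  y2 <- bump(-300, 50, 2) + bump(-100, 50, 2.5)
  l2 <- make_lrp(tt, y2, locking = "response")
  pk2 <- lrp_peak(l2, "response")
  expect_lt(abs(pk2$peak_latency_ms - -100), 10)
  # height is invariant to constant offsets
  l3 <- make_lrp(tt, y2 + 10, locking = "response")
  expect_equal(lrp_peak(l3, "response")$peak_height_uv, pk2$peak_height_uv)
})

test_that("stimulus-locked peak takes the first maximum before the reference RT", {
  tt <- seq(-200, 1200, by = 4)
  y <- 3 * exp(-(tt - 400)^2 / 120^2) + 4 * exp(-(tt - 900)^2 / 80^2)
  l <- make_lrp(tt, y, locking = "stimulus")
  pk <- lrp_peak(l, "stimulus", rt_ref_ms = 700, onset_ms = 150)
  expect_lt(abs(pk$peak_latency_ms - 400), 10)
})

test_that("areas between curves integrate the signed difference", {
  tt <- seq(-400, 0, by = 4)
  a <- make_lrp(tt, rep(2, length(tt)))
  b <- make_lrp(tt, rep(0.5, length(tt)))
  expect_equal(lrp_area_between(a, b, c(-250, -150)), 1.5 * 100)
  expect_equal(lrp_area_between(a, a, c(-250, -150)), 0)
  expect_error(lrp_area_between(a, b, c(-600, -150)), "window")
  short <- make_lrp(seq(-100, 0, by = 4), rep(1, 26))
  expect_error(lrp_area_between(a, short, c(-50, 0)), "common time axis")
})

test_that("neural non-decision time adds onset and motor interval", {
  # onset at 200 ms, response-locked peak at -90 ms -> 290 ms
  tt_s <- seq(0, 800, by = 4)
  stim <- make_lrp(tt_s, pmax(0, pmin(tt_s - 200, 300)) * 0.01)
  tt_r <- seq(-600, 100, by = 4)
  resp <- make_lrp(tt_r, 3 * exp(-(tt_r + 90)^2 / 100^2), locking = "response")
  nt <- lrp_neural_t0(stim, resp, median_rt_ms = 600)
  expect_equal(nt$onset_ms, 200, tolerance = 4)
  expect_equal(nt$neural_t0_ms, 200 + abs(nt$peak_latency_ms),
               tolerance = 1e-10)
  expect_lt(abs(nt$neural_t0_ms - 290), 10)
})
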