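test_that("behavioral generation is seeded and respects bias proportions", {
  p <- ref_bias_params(z = 0.0889)
  a <- simulate_behavior(list(b90 = p), n = 1500, seed = 81,
                         bias_prob = c(b90 = 0.9))
  b <- simulate_behavior(list(b90 = p), n = 1500, seed = 81,
                         bias_prob = c(b90 = 0.9))
  expect_identical(a, b)
  prop <- mean(a$direction == "preferred")
  se <- sqrt(0.9 * 0.1 / 1500)
  expect_lt(abs(prop - 0.9), 3 * se)
  expect_equal(nrow(simulate_behavior(list(x = p), n = 0, seed = 1)), 0L)
})

test_that("EEG generation is bit-identical under a fixed seed", {
  fx1 <- make_synth_eeg(seed = 82, n = 8)
  fx2 <- make_synth_eeg(seed = 82, n = 8)
  expect_identical(fx1$epochs$data, fx2$epochs$data)
  expect_identical(fx1$truth, fx2$truth)
})

test_that("without noise the computed LRP equals the embedded template", {
  tt <- ddm_simulate(eeg_ddm_params(), n = 40, seed = 83)
  ge <- simulate_eeg(tt, extra_channels = character(0), amplitude_uv = 5,
                     noise = list(white = 0, pink = 0, common = 0),
                     seed = 84)
  l <- compute_lrp(ge$epochs, "stimulus")
  # expected average template over the correct trials
  keep <- tt$correct
  u <- sapply(which(keep), function(i)
    lrpddm:::template_shape(l$time_ms, 180, tt$rt[i] * 1000 - 100, 300))
  expect_equal(l$amplitude, 5 * rowMeans(u), tolerance = 1e-10)
})

test_that("templates from different drifts produce a positive pre-peak area", {
  lo <- ddm_params(v = 0.10, a = 0.12, t0 = 0.35)
  hi <- ddm_params(v = 0.45, a = 0.12, t0 = 0.35)
  tt <- ddm_simulate(list(low = lo, high = hi), n = 250, seed = 85)
  ge <- simulate_eeg(tt, extra_channels = character(0), amplitude_uv = 8,
                     seed = 86)
  ep <- lowpass_epochs(ge$epochs, 40)
  l_lo <- compute_lrp(ep, "response", condition = "low")
  l_hi <- compute_lrp(ep, "response", condition = "high")
  expect_gt(lrp_area_between(l_lo, l_hi, c(-250, -150)), 0)
})

test_that("the generator rejects templates that cannot fit the epoch", {
  tt <- ddm_simulate(eeg_ddm_params(), n = 10, seed = 87)
  expect_error(simulate_eeg(tt, epoch_ms = c(-400, 600), seed = 88),
               "epoch")
  tt$rt <- rep(0.2, nrow(tt))  # too fast for d1 + d2
  expect_error(simulate_eeg(tt, seed = 89), "onset")
})
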