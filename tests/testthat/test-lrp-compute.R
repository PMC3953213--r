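test_that("identical C3 and C4 signals give a flat zero LRP", {
  fx <- make_synth_eeg(seed = 71, n = 10)
  ep <- fx$epochs
  ep$data[, match("C4", ep$ch_names), ] <- ep$data[, match("C3", ep$ch_names), ]
  l <- compute_lrp(ep, "stimulus")
  expect_equal(max(abs(l$amplitude)), 0)
})

test_that("a lateralized template on left-hand trials is recovered exactly", {
  # known waveform, noiseless, mirrored on C3/C4
  sfreq <- 250
  tt_ms <- seq(-200, 1000, by = 1000 / sfreq)
  wave <- ifelse(tt_ms > 100 & tt_ms < 500,
                 sin(pi * (tt_ms - 100) / 400), 0) * 5
  ep <- make_manual_epochs(wave, n_trials = 6, rt_ms = 600)
  l <- compute_lrp(ep, "stimulus", window_ms = c(-200, 900))
  sel <- match(round(l$time_ms), round(tt_ms[tt_ms <= 900]))
  expect_equal(l$amplitude, wave[tt_ms <= 900][sel], tolerance = 1e-10)
})

test_that("swapping all hand labels flips the LRP sign exactly", {
  fx <- make_synth_eeg(seed = 72, n = 30)
  l1 <- compute_lrp(fx$epochs, "response")
  ep2 <- fx$epochs
  ep2$hand <- ifelse(ep2$hand == "left", "right", "left")
  l2 <- compute_lrp(ep2, "response")
  expect_identical(l1$amplitude, -l2$amplitude)
})

test_that("baseline windows average exactly to zero after correction", {
  fx <- make_synth_eeg(seed = 73, n = 40)
  ls <- compute_lrp(fx$epochs, "stimulus")
  bs <- ls$time_ms >= -200 & ls$time_ms <= 0
  expect_equal(mean(ls$amplitude[bs]), 0, tolerance = 1e-10)
  lr <- compute_lrp(fx$epochs, "response")
  br <- lr$time_ms >= -600 & lr$time_ms <= -400
  expect_equal(mean(lr$amplitude[br]), 0, tolerance = 1e-10)
})

test_that("missing labels and empty selections fail loudly", {
  fx <- make_synth_eeg(seed = 74, n = 10)
  ep <- fx$epochs
  ep$hand[3] <- NA
  expect_error(compute_lrp(ep, "stimulus"), "hand")
  ep2 <- fx$epochs
  ep2$correct[] <- FALSE
  expect_error(compute_lrp(ep2, "stimulus"), "no trials")
})

test_that("the grand average is the unweighted mean across subjects", {
  l1 <- make_lrp(0:10, rep(1, 11))
  l2 <- make_lrp(0:10, rep(3, 11))
  g <- grand_average_lrp(list(l1, l2))
  expect_equal(g$amplitude, rep(2, 11))
  expect_equal(g$n, 2L)
  l3 <- make_lrp(0:9, rep(1, 10))
  expect_error(grand_average_lrp(list(l1, l3)), "common time axis")
})

test_that("epochs survive the JSON+CSV round trip", {
  fx <- make_synth_eeg(seed = 75, n = 3)
  base <- tempfile()
  write_eeg_epochs(fx$epochs, base)
  ep2 <- read_eeg_epochs(base)
  expect_equal(ep2$data, fx$epochs$data, tolerance = 1e-10)
  expect_identical(ep2$hand, fx$epochs$hand)
  expect_equal(ep2$resp_ms, fx$epochs$resp_ms, tolerance = 1e-10)
})
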