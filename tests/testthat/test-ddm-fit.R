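test_that("fit designs validate their fields", {
  expect_error(fit_design(character(0)), "non-empty")
  expect_error(fit_design(c("a", "a")), "unique")
  expect_error(fit_design("a", drift = "fixed"), "free")
  d <- fit_design(c("x", "y"), drift = "free", threshold = "shared",
                  start_point = "shared", ndt = "free")
  expect_s3_class(d, "ddm_fit_design")
  expect_equal(lrpddm:::design_layout(d)$n_par, 6L)
})

test_that("shared parameters are identical across conditions after fitting", {
  p <- ddm_params(v = 0.15, a = 0.13, t0 = 0.3)
  tt <- ddm_simulate(list(c1 = p, c2 = p), n = 1500, seed = 21)
  d <- fit_design(c("c1", "c2"), drift = "shared", threshold = "shared",
                  start_point = "shared", ndt = "shared")
  f <- ddm_fit(tt, d, seed = 22, n_starts = 4)
  expect_identical(f$params$c1$v, f$params$c2$v)
  expect_identical(f$params$c1$a, f$params$c2$a)
  expect_identical(f$params$c1$z, f$params$c2$z)
  expect_identical(f$params$c1$t0, f$params$c2$t0)
  expect_equal(f$BIC, f$k * log(f$n) - 2 * f$logLik)
})

test_that("the quantile-multinomial fit recovers generating parameters", {
  tt <- ddm_simulate(list(low = ref_low_coh(), high = ref_high_coh()),
                     n = 6000, seed = 31)
  d <- fit_design(c("low", "high"), drift = "free", threshold = "shared",
                  start_point = "shared", ndt = "free")
  f <- ddm_fit(tt, d, seed = 32, n_starts = 6)
  # moderate-n smoke recovery; the full-scale recovery runs in the
  # acceptance suite
  expect_equal(f$params$low$v, 0.060, tolerance = 0.15)
  expect_equal(f$params$high$v, 0.172, tolerance = 0.10)
  expect_equal(f$params$low$a, 0.151, tolerance = 0.10)
  expect_equal(f$params$low$t0, 0.435, tolerance = 0.05)
})

test_that("BIC prefers the drift-free design when drifts truly differ", {
  tt <- ddm_simulate(list(low = ref_low_coh(), high = ref_high_coh()),
                     n = 4000, seed = 41)
  d_free <- fit_design(c("low", "high"), drift = "free",
                       threshold = "shared", start_point = "shared",
                       ndt = "free")
  d_all_shared <- fit_design(c("low", "high"), drift = "shared",
                             threshold = "shared", start_point = "shared",
                             ndt = "shared")
  f_free <- ddm_fit(tt, d_free, seed = 42, n_starts = 5)
  f_shared <- ddm_fit(tt, d_all_shared, seed = 43, n_starts = 5)
  expect_lt(f_free$BIC, f_shared$BIC)
})

test_that("fitting fails cleanly on missing conditions", {
  tt <- ddm_simulate(ddm_params(v = 0.2, a = 0.12, t0 = 0.3),
                     n = 300, seed = 51)
  d <- fit_design(c("condition1", "ghost"))
  expect_error(ddm_fit(tt, d, seed = 52), "ghost")
})
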