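test_that("path simulation is reproducible and validates its inputs", {
  p <- ddm_params(v = 0.2, a = 0.12, t0 = 0.3)
  a <- ddm_simulate(p, n = 200, seed = 5)
  b <- ddm_simulate(p, n = 200, seed = 5)
  expect_identical(a, b)
  expect_error(ddm_simulate(p, n = 10, seed = 1, dt = 0.01), "dt")
  expect_error(ddm_simulate(p, n = 10), "seed")
  expect_equal(nrow(ddm_simulate(p, n = 0, seed = 1)), 0L)
})

test_that("a strong drift with tiny noise gives deterministic crossings", {
  p <- ddm_params(v = 2, a = 0.1, z = 0.05, t0 = 0.2, s = 1e-4)
  tt <- ddm_simulate(p, n = 50, seed = 9)
  expect_true(all(tt$choice == "upper"))
  # RT -> (a - z)/v + t0 in the noise-free limit
  expect_equal(mean(tt$rt), (0.1 - 0.05) / 2 + 0.2, tolerance = 1e-3)
})

test_that("simulated accuracy and mean RT match the closed forms", {
  set.seed(314)
  sets <- c(list(ref_low_coh(), ref_high_coh()),
            replicate(4, {
              a <- runif(1, 0.08, 0.25)
              ddm_params(v = runif(1, -0.25, 0.25), a = a,
                         z = runif(1, 0.25, 0.75) * a,
                         t0 = runif(1, 0.1, 0.4))
            }, simplify = FALSE))
  n <- 10000
  for (k in seq_along(sets)) {
    p <- sets[[k]]
    tt <- ddm_simulate(p, n = n, seed = 1000 + k)
    p_up <- ddm_choice_probability(p)
    se_acc <- sqrt(p_up * (1 - p_up) / n)
    expect_lt(abs(mean(tt$choice == "upper") - p_up), 3 * se_acc + 1e-4)
    m_rt <- ddm_mean_decision_time(p) + p$t0
    se_rt <- sd(tt$rt) / sqrt(n)
    # 2 ms absolute slack for the Euler discretization bias at dt = 0.1 ms
    expect_lt(abs(mean(tt$rt) - m_rt), 3 * se_rt + 2e-3)
  }
})

test_that("trials hitting the time guard are flagged and dropped", {
  p <- ddm_params(v = 0.001, a = 0.4, t0 = 0.2)  # very slow process
  expect_warning(tt <- ddm_simulate(p, n = 50, seed = 2, max_t = 0.5),
                 "guard")
  expect_true(all(tt$rt <= 0.5 + p$t0))
})

test_that("trial tables survive a CSV round trip", {
  p <- ddm_params(v = 0.2, a = 0.12, t0 = 0.3)
  tt <- ddm_simulate(p, n = 25, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_trial_table(tt, f)
  tt2 <- read_trial_table(f)
  expect_equal(tt2$rt, tt$rt, tolerance = 1e-12)
  expect_identical(tt2$choice, tt$choice)
  expect_identical(tt2$correct, tt$correct)
})
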