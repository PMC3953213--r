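test_that("defective first-passage densities are normalized", {
  sets <- list(ref_low_coh(), ref_high_coh(),
               ddm_params(v = -0.08, a = 0.12, z = 0.04, t0 = 0),
               ddm_params(v = 0.3, a = 0.2, z = 0.15, t0 = 0))
  for (p in sets) {
    fu <- integrate(function(t) ddm_fpt_density(t, p, "upper"), 0, Inf,
                    rel.tol = 1e-8)$value
    fl <- integrate(function(t) ddm_fpt_density(t, p, "lower"), 0, Inf,
                    rel.tol = 1e-8)$value
    expect_equal(fu + fl, 1, tolerance = 1e-4)
    # each boundary's mass equals its choice probability
    expect_equal(fu, ddm_choice_probability(p), tolerance = 1e-4)
  }
})

test_that("the defective CDF agrees with the integrated density", {
  p <- ddm_params(v = 0.1, a = 0.15, z = 0.06, t0 = 0)
  for (tmax in c(0.2, 0.5, 1.5)) {
    num <- integrate(function(t) ddm_fpt_density(t, p, "upper"), 0, tmax,
                     rel.tol = 1e-9)$value
    expect_equal(ddm_fpt_cdf(tmax, p, "upper"), num, tolerance = 1e-6)
  }
  # saturates at the boundary probability
  expect_equal(ddm_fpt_cdf(60, p, "lower"), 1 - ddm_choice_probability(p),
               tolerance = 1e-8)
  expect_equal(ddm_fpt_cdf(0, p, "upper"), 0)
})

test_that("the adaptive expansion matches brute-force series everywhere", {
  # long fixed sums of both expansions as the oracle, across normalized
  # times spanning the small-/large-time switch
  brute <- function(tau, w) {
    k <- 1:5000
    lt <- pi * sum(k * exp(-k^2 * pi^2 * tau / 2) * sin(k * pi * w))
    j <- -500:500
    st <- sum((w + 2 * j) * exp(-(w + 2 * j)^2 / (2 * tau))) /
      sqrt(2 * pi * tau^3)
    c(lt = lt, st = st)
  }
  for (w in c(0.2, 0.5, 0.8)) {
    for (tau in c(0.005, 0.02, 0.08, 0.3, 1, 3)) {
      o <- brute(tau, w)
      expect_equal(o[["lt"]], o[["st"]], tolerance = 1e-8)
      expect_equal(lrpddm:::wfpt_f0(tau, w), o[["lt"]],
                   tolerance = 1e-8, label = sprintf("tau=%g w=%g", tau, w))
    }
  }
})

test_that("empirical RT distribution matches the density's CDF at deciles", {
  p <- ref_low_coh()
  n <- 20000
  tt <- ddm_simulate(p, n = n, seed = 77)
  up <- tt$rt[tt$choice == "upper"] - p$t0
  qs <- quantile(up, probs = seq(0.1, 0.9, by = 0.1))
  p_up <- ddm_choice_probability(p)
  # model CDF of decision times conditional on the upper boundary
  F_model <- ddm_fpt_cdf(qs, p, "upper") / p_up
  F_emp <- seq(0.1, 0.9, by = 0.1)
  # sup-norm over the deciles within Monte-Carlo error (~3/sqrt(n_upper))
  expect_lt(max(abs(F_model - F_emp)), 3 / sqrt(length(up)))
})
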