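test_that("switch units are quiescent, bistable, then saturated as input grows", {
  np <- network_params()
  crit <- switch_critical_inputs(np)
  # far below the bistable region: a single low stable state
  eq_lo <- switch_equilibria(np, crit[["lower"]] - 0.2)
  expect_equal(nrow(eq_lo), 1L)
  expect_equal(eq_lo$stability, "stable")
  expect_lt(eq_lo$activation, 0.2)
  # inside: stable-unstable-stable
  eq_mid <- switch_equilibria(np, mean(crit))
  expect_equal(eq_mid$stability, c("stable", "unstable", "stable"))
  # far above: a single high state
  eq_hi <- switch_equilibria(np, crit[["upper"]] + 0.2)
  expect_equal(nrow(eq_hi), 1L)
  expect_gt(eq_hi$activation, 0.8)
})

test_that("without self-excitation the unit is a linear leaky integrator", {
  np <- network_params(selfexc_thr = 1e-12, leak_thr = 1.3)
  eq <- switch_equilibria(np, 0.5)
  expect_equal(nrow(eq), 1L)
  expect_equal(eq$activation, 0.5 / 1.3, tolerance = 1e-6)
})

test_that("sweeping input up and down shows hysteresis", {
  np <- network_params()
  inputs_up <- seq(0, 0.5, by = 0.01)
  y_up <- sweep_switch_unit(np, inputs_up)
  y_down <- rev(sweep_switch_unit(np, rev(inputs_up),
                                  y0 = y_up[length(y_up)]))
  # the up- and down-sweep switch at different inputs: positive loop area
  loop_area <- sum((y_down - y_up) * c(diff(inputs_up), 0))
  expect_gt(loop_area, 0.05)
  sw_up <- inputs_up[which(y_up > 0.5)[1]]
  sw_down <- inputs_up[rev(which(y_down < 0.5))[1] + 1L]
  expect_gt(sw_up, sw_down)
})

test_that("the resting network stays quiet without input or noise", {
  np <- network_params(noise_acc = 0, noise_thr = 0, drive_base = 0,
                      t_max = 1)
  sim <- suppressWarnings(simulate_network(np, drive = 0, n = 2, seed = 1))
  expect_true(all(!sim$responded))
  expect_lt(max(abs(sim$thr)), 0.05)
  expect_lt(max(abs(sim$acc)), 0.05)
})

test_that("bias raises the pre-stimulus threshold baseline without a response", {
  np0 <- network_params(drive_base = 0, t_max = 1.5)
  npb <- network_params(bias = 0.2, drive_base = 0, t_max = 1.5)
  s0 <- suppressWarnings(simulate_network(np0, drive = 0, n = 5, seed = 3))
  sb <- suppressWarnings(simulate_network(npb, drive = 0, n = 5, seed = 3))
  expect_true(all(!sb$responded))
  expect_gt(mean(sb$thr[, , 1]), mean(s0$thr[, , 1]) + 0.1)
})

test_that("with balanced leak and inhibition the accumulator difference drifts linearly", {
  np <- network_params()
  drive <- 0.3
  sim <- suppressWarnings(simulate_network(np, drive = drive, n = 300, seed = 7))
  # mean difference over trials in the early post-stimulus epoch
  sel <- sim$time >= 0.05 & sim$time <= 0.25
  md <- colMeans(sim$acc[, sel, 1] - sim$acc[, sel, 2])
  fit <- lm(md ~ sim$time[sel])
  expect_equal(unname(coef(fit)[2]), 2 * drive, tolerance = 0.15)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("network choice probabilities match a fitted pure DDM's closed form", {
  np <- network_params(noise_acc = 0.35)
  sim <- suppressWarnings(simulate_network(np, drive = 0.12, n = 2500,
                                           seed = 11, record = FALSE))
  ok <- sim$responded
  trials <- data.frame(
    trial = seq_len(sum(ok)), condition = "net",
    choice = ifelse(sim$choice[ok] == 1L, "upper", "lower"),
    hand = ifelse(sim$choice[ok] == 1L, "right", "left"),
    rt = sim$rt[ok], correct = sim$choice[ok] == 1L)
  f <- ddm_fit(trials, fit_design("net", drift = "free", threshold = "free",
                                  start_point = "free", ndt = "free"),
               seed = 12, n_starts = 5)
  p_hat <- ddm_choice_probability(f$params$net)
  p_emp <- mean(trials$choice == "upper")
  se <- sqrt(p_emp * (1 - p_emp) / nrow(trials))
  expect_lt(abs(p_emp - p_hat), 3 * se + 0.01)
})

test_that("the reset returns threshold activations to baseline before the next trial", {
  np <- network_params()
  sim <- simulate_network(np, drive = 0.45, n = 60, seed = 13)
  base <- mean(sim$thr[, sim$time < 0, 1])
  peak <- max(colMeans(sim$thr[, , 1]))
  ok <- which(sim$responded & sim$rt + 1.0 <= np$t_max)
  expect_gt(length(ok), 20)
  # ensemble mean one inter-trial interval after the response (individual
  # trials carry the threshold units' stationary noise)
  y_iti <- vapply(ok, function(i) {
    it <- which.min(abs(sim$time - (sim$rt[i] + 1.0)))
    mean(sim$thr[i, it + (-25:0), 1])
  }, numeric(1))
  expect_lt(abs(mean(y_iti) - base), 0.05 * (peak - base))
})

test_that("simulated LRPs require a recorded, non-empty ensemble", {
  np <- network_params()
  sim <- simulate_network(np, drive = 0.4, n = 20, seed = 15, record = FALSE)
  expect_error(simulated_lrp(sim, "response"), "record")
})

test_that("layer RMSD comparison identifies the generating layer (both directions)", {
  np <- network_params()
  src <- suppressWarnings(simulate_network(np, drive = 0.35, n = 150,
                                           seed = 17))
  grid <- data.frame(drive = c(0.25, 0.35, 0.5))
  for (layer in c("threshold", "accumulator")) {
    l <- suppressWarnings(simulated_lrp(src, "response", layer = layer))
    l$amplitude <- l$amplitude * 3   # arbitrary microvolt scaling
    res <- suppressWarnings(
      compare_layer_rmsd(l, grid, base_params = np, n_per_point = 80,
                         rt_window = c(0.2, 2.5), seed = 18))
    expect_gt(res$n_plausible, 0)
    if (layer == "threshold") expect_gt(res$fraction_threshold, 0.5)
    else expect_lt(res$fraction_threshold, 0.5)
    # the reported fraction matches the tie rule applied to the table
    pl <- res$table[res$table$plausible, ]
    expect_equal(res$fraction_threshold,
                 (sum(pl$winner == "threshold") +
                    0.5 * sum(pl$winner == "tie")) / nrow(pl))
  }
})
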