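#' Parameters of the three-layer decision network
#'
#' The network has two units per layer (one per response side). The
#' accumulation layer consists of leaky competing accumulators driven by the
#' stimulus; with leak balanced by lateral inhibition their difference
#' approximates a drift-diffusion process. The threshold layer consists of
#' bistable switch units: leaky integrators with strong sigmoidal
#' self-excitation that stay near a low stable state over a broad range of
#' inputs and snap to a high state once the input passes a critical value.
#' The response layer contains the same kind of switch units; when one
#' activates, the model emits a response and broadcasts a reset current that
#' drives the accumulator and threshold layers back down.
#'
#' Dynamics per unit (Euler-Maruyama, step `dt`):
#' \deqn{\tau \dot u = -\lambda u + \alpha\,\sigma(\beta(u - \theta)) + I(t)}
#' with \eqn{\sigma} the logistic function; accumulators have
#' \eqn{\alpha = 0} and mutual inhibition instead.
#'
#' @param tau_acc,leak_acc,inhib_acc Accumulator time constant (s), leak and
#'   lateral inhibition. Leak == inhibition gives the drift-diffusion regime.
#' @param drive_base Common stimulus drive to both accumulators; the
#'   coherence drive is added to the correct side and subtracted from the
#'   other at simulation time.
#' @param noise_acc Accumulator noise (per sqrt-second).
#' @param w_acc_thr Feedforward weight from accumulator to threshold unit.
#' @param tau_thr,leak_thr,selfexc_thr,slope_thr,offset_thr Threshold-layer
#'   time constant, leak \eqn{\lambda}, self-excitation gain \eqn{\alpha},
#'   sigmoid slope \eqn{\beta} and offset \eqn{\theta}.
#' @param noise_thr Threshold-unit noise (per sqrt-second).
#' @param bias Continuous biasing input to the threshold units; scalar
#'   (applied to side 1, the correct/preferred side) or length 2.
#' @param tau_resp,leak_resp,selfexc_resp,slope_resp,offset_resp,w_thr_resp
#'   Response-layer constants and input weight from the threshold unit.
#' @param resp_criterion Activation above which a response unit counts as
#'   "on" (midpoint of its two stable states).
#' @param reset_strength Gain of the feedback inhibition from the response
#'   layer to the threshold and accumulation layers (proportional to
#'   response-unit activation, so it ramps up just before the overt response
#'   and stays on while a response unit is in its up state).
#' @param reset_duration Seconds after the response before the response
#'   units themselves are switched off.
#' @param resp_shutoff Seconds of self-inhibition that switches the response
#'   units back off after the reset.
#' @param dt Integration step (s), <= 1 ms.
#' @param t_baseline Pre-stimulus simulation time (s).
#' @param t_max Post-stimulus guard time (s); trials without a response by
#'   then are flagged.
#' @return An object of class `network_params`.
#' @export
network_params <- function(tau_acc = 1, leak_acc = 2, inhib_acc = 2,
                           drive_base = 1, noise_acc = 0.2, w_acc_thr = 1,
                           tau_thr = 0.05, leak_thr = 1, selfexc_thr = 1,
                           slope_thr = 8, offset_thr = 0.7, noise_thr = 0.01,
                           bias = 0,
                           tau_resp = 0.05, leak_resp = 1, selfexc_resp = 1,
                           slope_resp = 8, offset_resp = 0.55,
                           w_thr_resp = 0.25, resp_criterion = 0.5,
                           reset_strength = 2, reset_duration = 0.15,
                           resp_shutoff = 0.2,
                           dt = 1e-3, t_baseline = 0.7, t_max = 3) {
  stopifnot(tau_acc > 0, tau_thr > 0, tau_resp > 0, leak_thr > 0,
            selfexc_thr > 0, slope_thr > 0, dt <= 1e-3, dt > 0)
  if (length(bias) == 1L) bias <- c(bias, 0)
  p <- as.list(environment())
  structure(p, class = "network_params")
}

logistic <- function(x) plogis(x)

#' Equilibria of a bistable switch unit at fixed input
#'
#' Solves the noise-free fixed-point equation of a threshold unit,
#' \eqn{0 = -\lambda y + \alpha\,\sigma(\beta(y - \theta)) + I}, on a fine
#' grid with root refinement. Stability follows from the sign of the local
#' derivative; roots where the derivative is (numerically) zero are tangent
#' cases and reported as `"marginal"`.
#'
#' @param params A [network_params()] object.
#' @param input Constant input level `I`.
#' @param grid_n Grid resolution for the sign scan.
#' @return A data frame with columns `activation` and `stability`
#'   (`"stable"`, `"unstable"` or `"marginal"`), one row per equilibrium
#'   (1 or 3 for a bistable configuration).
#' @export
switch_equilibria <- function(params, input, grid_n = 4001L) {
  stopifnot(inherits(params, "network_params"))
  lam <- params$leak_thr; al <- params$selfexc_thr
  be <- params$slope_thr; th <- params$offset_thr
  f <- function(y) -lam * y + al * logistic(be * (y - th)) + input
  fp <- function(y) {
    s <- logistic(be * (y - th))
    -lam + al * be * s * (1 - s)
  }
  lo <- min(input / lam, 0) - 1
  hi <- max((al + max(input, 0)) / lam, th) + 1
  ys <- seq(lo, hi, length.out = grid_n)
  fv <- f(ys)
  roots <- numeric(0)
  for (i in seq_len(grid_n - 1L)) {
    if (fv[i] == 0) roots <- c(roots, ys[i])
    else if (fv[i] * fv[i + 1L] < 0)
      roots <- c(roots, uniroot(f, c(ys[i], ys[i + 1L]), tol = 1e-12)$root)
  }
  roots <- sort(unique(roots))
  if (!length(roots)) stop("no equilibrium found; widen the scan range")
  d <- fp(roots)
  stab <- ifelse(abs(d) < 1e-8, "marginal", ifelse(d < 0, "stable", "unstable"))
  data.frame(activation = roots, stability = stab, stringsAsFactors = FALSE)
}

#' Critical inputs of the bistable region
#'
#' Scans input levels for the boundaries of bistability of the threshold
#' unit (where the count of equilibria changes between 1 and 3).
#'
#' @param params A [network_params()] object.
#' @param inputs Input levels to scan.
#' @return Named vector with the lower and upper critical inputs.
#' @export
switch_critical_inputs <- function(params, inputs = seq(-0.5, 1, by = 1e-3)) {
  k <- vapply(inputs, function(I) nrow(switch_equilibria(params, I, 801L)),
              numeric(1))
  if (!any(k == 3)) stop("unit is not bistable over the scanned inputs")
  c(lower = min(inputs[k == 3]), upper = max(inputs[k == 3]))
}

#' Quasi-static input sweep of a switch unit
#'
#' Integrates the noise-free unit while stepping the input through `inputs`,
#' relaxing at each level; the state carries over between levels, so sweeping
#' up and then down exposes hysteresis.
#'
#' @param params A [network_params()] object.
#' @param inputs Sequence of input levels.
#' @param y0 Initial activation.
#' @param relax_t Relaxation time per level (s).
#' @return Vector of relaxed activations, one per input level.
#' @export
sweep_switch_unit <- function(params, inputs, y0 = 0, relax_t = 1) {
  lam <- params$leak_thr; al <- params$selfexc_thr
  be <- params$slope_thr; th <- params$offset_thr
  dt <- params$dt; nstep <- ceiling(relax_t / dt)
  y <- y0
  out <- numeric(length(inputs))
  for (i in seq_along(inputs)) {
    I <- inputs[i]
    for (s in seq_len(nstep))
      y <- y + dt / params$tau_thr *
        (-lam * y + al * logistic(be * (y - th)) + I)
    out[i] <- y
  }
  out
}

#' Simulate an ensemble of network trials
#'
#' Integrates all three layers for `n` trials. The stimulus turns on after
#' `t_baseline` seconds with drive `drive_base + drive` to the correct-side
#' accumulator and `drive_base - drive` to the other, and turns off at the
#' trial's response. A response is emitted when either response unit exceeds
#' `resp_criterion`. Feedback inhibition proportional to response-layer
#' activation drives the threshold and accumulation layers back down;
#' `reset_duration` seconds after the response the response units are
#' switched off for `resp_shutoff` seconds, completing the reset.
#'
#' @param params A [network_params()] object.
#' @param drive Coherence drive (>= 0) added to the correct side.
#' @param n Number of trials.
#' @param seed Integer RNG seed (required).
#' @param record Keep full activation traces (needed for LRP extraction).
#' @return An object of class `network_sim` with elements `time` (s, 0 =
#'   stimulus onset), `rt`, `choice` (1 = correct side), `responded`, and,
#'   if recorded, trace arrays `acc`, `thr`, `resp` of dimension
#'   trials x time x 2.
#' @export
simulate_network <- function(params, drive, n = 100L, seed, record = TRUE) {
  stopifnot(inherits(params, "network_params"), drive >= 0)
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  set.seed(as.integer(seed))
  P <- unclass(params)
  dt <- P$dt
  tgrid <- seq(0, P$t_baseline + P$t_max, by = dt)
  nt <- length(tgrid)
  sq <- sqrt(dt)

  x1 <- x2 <- y1 <- y2 <- r1 <- r2 <- numeric(n)
  # start threshold units at their low equilibrium given the bias input
  y1[] <- low_state(params, P$bias[1])
  y2[] <- low_state(params, P$bias[2])
  r1[] <- low_state_resp(params, P$w_thr_resp * y1[1])
  r2[] <- low_state_resp(params, P$w_thr_resp * y2[1])

  rt <- rep(NA_real_, n)
  resp_time <- rep(Inf, n)   # absolute time of response
  choice <- rep(NA_integer_, n)
  if (record) {
    # time-major matrices (nt x n) for cheap row writes; reshaped at the end
    accT1 <- matrix(NA_real_, nt, n); accT2 <- matrix(NA_real_, nt, n)
    thrT1 <- matrix(NA_real_, nt, n); thrT2 <- matrix(NA_real_, nt, n)
    rspT1 <- matrix(NA_real_, nt, n); rspT2 <- matrix(NA_real_, nt, n)
  }

  for (it in seq_len(nt)) {
    t <- tgrid[it]
    if (record) {
      accT1[it, ] <- x1; accT2[it, ] <- x2
      thrT1[it, ] <- y1; thrT2[it, ] <- y2
      rspT1[it, ] <- r1; rspT2[it, ] <- r2
    }
    stim_on <- (t >= P$t_baseline) & (t < resp_time)
    shut_on <- (t >= resp_time + P$reset_duration) &
               (t < resp_time + P$reset_duration + P$resp_shutoff)
    S1 <- ifelse(stim_on, P$drive_base + drive, 0)
    S2 <- ifelse(stim_on, P$drive_base - drive, 0)
    # feedback inhibition follows the response units' sigmoidal output
    # (near zero in the down state), so it ramps up in the last tens of ms
    # before the overt response and stays on while a response unit is up
    rst <- P$reset_strength *
      (logistic(P$slope_resp * (r1 - P$offset_resp)) +
       logistic(P$slope_resp * (r2 - P$offset_resp)))

    nx1 <- x1 + dt / P$tau_acc *
      (S1 - P$leak_acc * x1 - P$inhib_acc * x2 - rst) +
      P$noise_acc / P$tau_acc * sq * rnorm(n)
    nx2 <- x2 + dt / P$tau_acc *
      (S2 - P$leak_acc * x2 - P$inhib_acc * x1 - rst) +
      P$noise_acc / P$tau_acc * sq * rnorm(n)
    ny1 <- y1 + dt / P$tau_thr *
      (-P$leak_thr * y1 +
         P$selfexc_thr * logistic(P$slope_thr * (y1 - P$offset_thr)) +
         P$w_acc_thr * x1 + P$bias[1] - rst) +
      P$noise_thr / P$tau_thr * sq * rnorm(n)
    ny2 <- y2 + dt / P$tau_thr *
      (-P$leak_thr * y2 +
         P$selfexc_thr * logistic(P$slope_thr * (y2 - P$offset_thr)) +
         P$w_acc_thr * x2 + P$bias[2] - rst) +
      P$noise_thr / P$tau_thr * sq * rnorm(n)
    shut <- P$reset_strength * shut_on
    nr1 <- r1 + dt / P$tau_resp *
      (-P$leak_resp * r1 +
         P$selfexc_resp * logistic(P$slope_resp * (r1 - P$offset_resp)) +
         P$w_thr_resp * y1 - shut)
    nr2 <- r2 + dt / P$tau_resp *
      (-P$leak_resp * r2 +
         P$selfexc_resp * logistic(P$slope_resp * (r2 - P$offset_resp)) +
         P$w_thr_resp * y2 - shut)

    x1 <- pmax(nx1, 0); x2 <- pmax(nx2, 0)
    y1 <- pmax(ny1, 0); y2 <- pmax(ny2, 0)
    r1 <- pmax(nr1, 0); r2 <- pmax(nr2, 0)

    just <- is.na(choice) &
      (r1 > P$resp_criterion | r2 > P$resp_criterion) & t >= P$t_baseline
    if (any(just)) {
      choice[just] <- ifelse(r1[just] >= r2[just], 1L, 2L)
      rt[just] <- t - P$t_baseline
      resp_time[just] <- t
    }
  }
  if (record) {
    acc <- array(NA_real_, c(n, nt, 2))
    thr <- array(NA_real_, c(n, nt, 2))
    rsp <- array(NA_real_, c(n, nt, 2))
    acc[, , 1] <- t(accT1); acc[, , 2] <- t(accT2)
    thr[, , 1] <- t(thrT1); thr[, , 2] <- t(thrT2)
    rsp[, , 1] <- t(rspT1); rsp[, , 2] <- t(rspT2)
  }

  out <- list(params = params, drive = drive,
              time = tgrid - params$t_baseline,
              rt = rt, choice = choice, responded = !is.na(rt))
  if (any(!out$responded))
    warning(sprintf("%d of %d trials did not respond within t_max",
                    sum(!out$responded), n))
  if (record) out <- c(out, list(acc = acc, thr = thr, resp = rsp))
  structure(out, class = "network_sim")
}

# low stable state of a threshold unit at constant input (smallest root)
low_state <- function(params, input) {
  eq <- switch_equilibria(params, input, 801L)
  eq$activation[1]
}

low_state_resp <- function(params, input) {
  p2 <- params
  p2$leak_thr <- params$leak_resp
  p2$selfexc_thr <- params$selfexc_resp
  p2$slope_thr <- params$slope_resp
  p2$offset_thr <- params$offset_resp
  eq <- switch_equilibria(p2, input, 801L)
  eq$activation[1]
}

#' Simulated LRP from a network ensemble
#'
#' Averages the threshold-layer (or accumulation-layer) difference,
#' correct-side minus incorrect-side unit, across trials, aligned to the
#' stimulus or to the model response. This difference is the model's
#' prediction for the LRP.
#'
#' @param sim A recorded [simulate_network()] object.
#' @param locking `"stimulus"` or `"response"`.
#' @param layer `"threshold"` or `"accumulator"`.
#' @param window Time window in seconds relative to the locking event.
#' @param correct_only Use correct (side-1) responses only.
#' @return An object of class `sim_lrp`: `time_ms`, `amplitude` (model
#'   activation units), `n`, `locking`, `layer`.
#' @export
simulated_lrp <- function(sim, locking = c("stimulus", "response"),
                          layer = c("threshold", "accumulator"),
                          window = NULL, correct_only = TRUE) {
  locking <- match.arg(locking)
  layer <- match.arg(layer)
  stopifnot(inherits(sim, "network_sim"))
  if (is.null(sim$thr)) stop("simulate_network() must be run with record = TRUE")
  keep <- sim$responded
  if (correct_only) keep <- keep & sim$choice == 1L
  if (!any(keep)) stop("no usable trials in the ensemble")
  arr <- if (layer == "threshold") sim$thr else sim$acc
  diffs <- arr[keep, , 1, drop = FALSE] - arr[keep, , 2, drop = FALSE]
  dim(diffs) <- dim(diffs)[1:2]
  dt <- sim$params$dt
  if (locking == "stimulus") {
    if (is.null(window)) window <- c(-sim$params$t_baseline, sim$params$t_max)
    idx <- which(sim$time >= window[1] & sim$time <= window[2])
    amp <- colMeans(diffs[, idx, drop = FALSE])
    tt <- sim$time[idx]
  } else {
    if (is.null(window)) window <- c(-0.6, 0.2)
    rel <- seq(round(window[1] / dt), round(window[2] / dt))
    tt <- rel * dt
    rts <- sim$rt[keep]
    i0 <- vapply(rts, function(r) which.min(abs(sim$time - r)), numeric(1))
    cover <- i0 + min(rel) >= 1 & i0 + max(rel) <= length(sim$time)
    if (!any(cover)) stop("response-locked window exceeds all trial epochs")
    if (!all(cover))
      warning(sprintf("%d trial(s) cannot cover the response-locked window and were dropped",
                      sum(!cover)))
    mat <- matrix(NA_real_, sum(cover), length(rel))
    ci <- which(cover)
    for (i in seq_along(ci)) mat[i, ] <- diffs[ci[i], i0[ci[i]] + rel]
    amp <- colMeans(mat)
    n_used <- sum(cover)
  }
  n_used <- if (locking == "response") n_used else sum(keep)
  structure(list(time_ms = tt * 1000, amplitude = amp, n = n_used,
                 locking = locking, layer = layer), class = "sim_lrp")
}

#' Compare threshold- vs accumulation-layer fits to an LRP waveform
#'
#' For every parameter set in `grid` (a data frame whose columns override
#' [network_params()] fields; a `drive` column sets the coherence drive),
#' simulates an ensemble, keeps sets whose median model RT falls inside the
#' plausibility window, peak-scales the response-locked threshold-layer and
#' accumulation-layer mean difference traces to the height of the observed
#' LRP, and computes the root-mean-square deviation of each from the LRP
#' over `window_ms`. Reports the fraction of the plausible grid where the
#' threshold layer fits better (ties count 0.5 to each layer).
#'
#' @param lrp An LRP waveform (list with `time_ms`, `amplitude`), typically
#'   from [compute_lrp()] or [simulated_lrp()].
#' @param grid Data frame of parameter sets.
#' @param base_params Baseline [network_params()].
#' @param n_per_point Trials simulated per grid point.
#' @param rt_window Plausibility window for the median model RT (s).
#' @param window_ms Comparison window relative to the response (ms).
#' @param seed Integer RNG seed.
#' @return A list with `table` (per-grid-point RMSDs, plausibility, winner),
#'   `fraction_threshold`, and `n_plausible`.
#' @export
compare_layer_rmsd <- function(lrp, grid, base_params = network_params(),
                               n_per_point = 100L,
                               rt_window = c(0.2, 1.5),
                               window_ms = c(-400, 50), seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  res <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    pp <- base_params
    drive <- 0.3
    for (cn in names(grid)) {
      if (cn == "drive") drive <- grid$drive[g]
      else pp[[cn]] <- grid[[cn]][g]
    }
    class(pp) <- "network_params"
    sim <- simulate_network(pp, drive = drive, n = n_per_point,
                            seed = as.integer(seed) + g, record = TRUE)
    med_rt <- median(sim$rt, na.rm = TRUE)
    plausible <- is.finite(med_rt) && med_rt >= rt_window[1] &&
      med_rt <= rt_window[2] && mean(sim$responded) > 0.5
    if (!plausible) {
      res[[g]] <- data.frame(point = g, median_rt = med_rt, plausible = FALSE,
                             rmsd_threshold = NA_real_,
                             rmsd_accumulator = NA_real_,
                             winner = NA_character_)
      next
    }
    rmsd <- vapply(c("threshold", "accumulator"), function(ly) {
      tr <- simulated_lrp(sim, locking = "response", layer = ly,
                          window = range(window_ms) / 1000)
      scale_rmsd(lrp, tr, window_ms)
    }, numeric(1))
    winner <- if (abs(rmsd[1] - rmsd[2]) < 1e-12) "tie"
              else if (rmsd[1] < rmsd[2]) "threshold" else "accumulator"
    res[[g]] <- data.frame(point = g, median_rt = med_rt, plausible = TRUE,
                           rmsd_threshold = rmsd[1],
                           rmsd_accumulator = rmsd[2], winner = winner)
  }
  tab <- do.call(rbind, res)
  pl <- tab[tab$plausible, , drop = FALSE]
  if (!nrow(pl)) stop("no grid point fell inside the RT plausibility window")
  frac <- (sum(pl$winner == "threshold") + 0.5 * sum(pl$winner == "tie")) /
    nrow(pl)
  list(table = tab, fraction_threshold = frac, n_plausible = nrow(pl))
}

#' Baseline-to-peak height of a simulated LRP
#'
#' The baseline is the mean pre-stimulus threshold-layer difference
#' (stimulus-locked, `baseline_ms` before stimulus onset); the peak is the
#' maximum of the response-locked mean difference. Used to test the
#' model's response-bias prediction: a stronger bias raises the baseline
#' toward the switch tipping point and so shrinks the baseline-to-peak
#' height.
#'
#' @param sim A recorded [simulate_network()] ensemble.
#' @param baseline_ms Pre-stimulus baseline window (ms, negative = before
#'   stimulus onset).
#' @param resp_window Response-locked search window (s).
#' @return List with `height`, `baseline`, `peak` and `peak_latency_ms`.
#' @export
network_lrp_height <- function(sim, baseline_ms = c(-200, 0),
                               resp_window = c(-0.6, 0.2)) {
  st <- simulated_lrp(sim, "stimulus")
  sel <- st$time_ms >= baseline_ms[1] & st$time_ms < baseline_ms[2]
  base <- mean(st$amplitude[sel])
  re <- simulated_lrp(sim, "response", window = resp_window)
  ipk <- which.max(re$amplitude)
  list(height = re$amplitude[ipk] - base, baseline = base,
       peak = re$amplitude[ipk], peak_latency_ms = re$time_ms[ipk])
}

# peak-scale a model trace to the LRP height, interpolate onto the LRP's
# time axis and return the RMSD over the window
scale_rmsd <- function(lrp, trace, window_ms) {
  sel <- lrp$time_ms >= window_ms[1] & lrp$time_ms <= window_ms[2]
  tt <- lrp$time_ms[sel]
  obs <- lrp$amplitude[sel]
  pred <- approx(trace$time_ms, trace$amplitude, xout = tt, rule = 2)$y
  pk <- max(abs(pred))
  if (pk > 0) pred <- pred * max(abs(obs)) / pk
  sqrt(mean((obs - pred)^2))
}
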