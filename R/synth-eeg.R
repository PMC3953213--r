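#' 1/f ("pink") noise
#'
#' Gaussian noise with a 1/f amplitude spectrum (spectral exponent 1),
#' generated by spectrally shaping white noise, normalized to unit standard
#' deviation. Uses the current RNG state.
#'
#' @param n Number of samples.
#' @return Numeric vector of length `n` with sd 1.
#' @export
pink_noise <- function(n) {
  white <- rnorm(n)
  sp <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # mirror for the negative frequencies
  sp <- sp / sqrt(f)
  sp[1] <- 0                        # drop DC
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate synthetic epoched EEG with an embedded lateralized template
#'
#' Builds EEG epochs around the trials of a behavioral table. Each trial
#' carries a lateralized template at C3/C4 whose sign follows the response
#' hand (consistent with [compute_lrp()]'s difference convention): the
#' template rises linearly from stimulus onset plus the perceptual delay
#' `d1_ms` to its peak at the response minus the motor delay `d2_ms`, then
#' falls back to baseline over `fall_ms`. On top of the signal each channel
#' receives independent white and 1/f noise plus a shared common-mode 1/f
#' term (which the C3/C4 difference cancels). Artifacts can be injected per
#' trial, each designed to trip exactly one rejection rule of
#' [reject_artifacts()].
#'
#' @param trials A trial table (RT in seconds; only these trials are built).
#' @param sfreq Sampling rate (Hz).
#' @param extra_channels EEG channels besides C3, C4 and the eye channel.
#' @param epoch_ms Epoch window around stimulus onset (ms).
#' @param amplitude_uv Lateralization amplitude of the template
#'   (microvolts): scalar or named per condition.
#' @param d1_ms Perceptual delay: template onset after stimulus (ms).
#' @param d2_ms Motor delay: template peak before the response (ms).
#' @param fall_ms Fall time from peak back to baseline (ms).
#' @param noise List with sds `white`, `pink` (per channel) and `common`
#'   (shared 1/f), in microvolts.
#' @param artifacts Optional data frame with columns `trial` and `type`
#'   (one of `"blink"`, `"amplitude"`, `"variance_high"`, `"variance_low"`,
#'   `"kurtosis"`).
#' @param seed Integer seed.
#' @return A list: `epochs` (an [eeg_epochs()] object) and `truth` (ground
#'   truth: template onset, peak offset, per-condition amplitude, delays,
#'   expected artifact log, `neural_t0_ms = d1_ms + d2_ms`).
#' @export
simulate_eeg <- function(trials, sfreq = 250, extra_channels = "Cz",
                         epoch_ms = c(-400, 2600), amplitude_uv = 4,
                         d1_ms = 180, d2_ms = 100, fall_ms = 300,
                         noise = list(white = 4, pink = 4, common = 3),
                         artifacts = NULL, seed) {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  validate_trial_table(trials)
  n <- nrow(trials)
  if (!n) stop("empty trial table")
  ch_names <- c("C3", "C4", extra_channels, "EOG")
  nc <- length(ch_names)
  time_ms <- seq(epoch_ms[1], epoch_ms[2], by = 1000 / sfreq)
  ns <- length(time_ms)

  conds <- unique(trials$condition)
  amp <- if (length(amplitude_uv) == 1L && is.null(names(amplitude_uv)))
    setNames(rep(amplitude_uv, length(conds)), conds)
  else amplitude_uv[conds]
  if (anyNA(amp)) stop("amplitude_uv must cover every condition")

  rt_ms <- trials$rt * 1000
  if (any(rt_ms + 200 > epoch_ms[2]))
    stop("template longer than epoch: increase epoch_ms or shorten RTs")
  peak_ms <- rt_ms - d2_ms
  if (any(peak_ms <= d1_ms + 20))
    stop("template peak would precede its onset; RTs too short for d1/d2")

  set.seed(as.integer(seed))
  data <- array(0, c(n, nc, ns))
  eeg_idx <- which(ch_names != "EOG")
  i_c3 <- match("C3", ch_names)
  i_c4 <- match("C4", ch_names)

  for (i in seq_len(n)) {
    u <- template_shape(time_ms, d1_ms, peak_ms[i], fall_ms)
    A <- amp[[trials$condition[i]]]
    sgn <- if (trials$hand[i] == "left") 1 else -1
    common <- noise$common * pink_noise(ns)
    for (j in seq_len(nc)) {
      x <- noise$white * rnorm(ns) + noise$pink * pink_noise(ns) + common
      data[i, j, ] <- x
    }
    data[i, i_c4, ] <- data[i, i_c4, ] + sgn * A / 2 * u
    data[i, i_c3, ] <- data[i, i_c3, ] - sgn * A / 2 * u
  }

  log <- data.frame(trial = integer(0), rule = character(0),
                    stringsAsFactors = FALSE)
  if (!is.null(artifacts) && nrow(artifacts)) {
    stopifnot(all(c("trial", "type") %in% names(artifacts)),
              all(artifacts$trial %in% seq_len(n)))
    for (r in seq_len(nrow(artifacts))) {
      i <- artifacts$trial[r]
      type <- artifacts$type[r]
      data[i, , ] <- inject_artifact(data[i, , , drop = TRUE], type,
                                     time_ms, ch_names)
      log <- rbind(log, data.frame(trial = i, rule = type,
                                   stringsAsFactors = FALSE))
    }
  }

  epochs <- eeg_epochs(
    data, sfreq = sfreq, ch_names = ch_names, time_ms = time_ms,
    stim_ms = rep(0, n), resp_ms = rt_ms, hand = trials$hand,
    condition = trials$condition, correct = trials$correct, eog = "EOG")
  truth <- list(onset_ms = d1_ms, peak_offset_ms = -d2_ms,
                d1_ms = d1_ms, d2_ms = d2_ms,
                neural_t0_ms = d1_ms + d2_ms,
                amplitude_uv = amp, artifact_log = log, seed = seed)
  list(epochs = epochs, truth = truth)
}

# piecewise-linear template: flat 0, rise from onset to 1 at peak, fall to 0
template_shape <- function(time_ms, onset_ms, peak_ms, fall_ms) {
  u <- numeric(length(time_ms))
  rise <- time_ms >= onset_ms & time_ms <= peak_ms
  u[rise] <- (time_ms[rise] - onset_ms) / (peak_ms - onset_ms)
  fall <- time_ms > peak_ms & time_ms <= peak_ms + fall_ms
  u[fall] <- 1 - (time_ms[fall] - peak_ms) / fall_ms
  u
}

# each artifact trips exactly one rule of reject_artifacts() (given its
# precedence order); amplitudes are sized against the default thresholds
# and the default noise level
inject_artifact <- function(trial_mat, type, time_ms, ch_names) {
  ns <- length(time_ms)
  i_eog <- match("EOG", ch_names)
  i_c3 <- match("C3", ch_names)
  eeg_idx <- which(ch_names != "EOG")
  switch(type,
    blink = {
      # 120 uV half-sine, 300 ms, on the eye channel only
      k <- max(round(300 / diff(time_ms[1:2])), 3L)
      i0 <- round(ns * 0.4)
      idx <- i0:min(i0 + k - 1L, ns)
      trial_mat[i_eog, idx] <- trial_mat[i_eog, idx] +
        120 * sin(pi * seq_along(idx) / length(idx))
      trial_mat
    },
    amplitude = {
      # 100 uV slow half-sine across the whole epoch on C3
      trial_mat[i_c3, ] <- trial_mat[i_c3, ] +
        100 * sin(pi * seq_len(ns) / ns)
      trial_mat
    },
    variance_high = {
      # clipped extra noise: variance >> 80 but amplitudes below 70 uV
      trial_mat[i_c3, ] <- trial_mat[i_c3, ] +
        pmin(pmax(rnorm(ns, 0, 11), -35), 35)
      trial_mat
    },
    variance_low = {
      # near-flat EEG channels
      for (j in eeg_idx) trial_mat[j, ] <- rnorm(ns, 0, 0.01)
      trial_mat
    },
    kurtosis = {
      # sparse large spikes: heavy tails at modest variance and amplitude
      pos <- round(seq(0.2, 0.8, length.out = 4) * ns)
      trial_mat[i_c3, pos] <- trial_mat[i_c3, pos] + c(48, -48, 48, -48)
      trial_mat
    },
    stop(sprintf("unknown artifact type '%s'", type)))
}
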