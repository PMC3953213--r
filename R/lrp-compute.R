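#' Compute the lateralized readiness potential
#'
#' Forms the per-trial signed motor-cortex difference — C4 minus C3 for
#' left-hand responses and C3 minus C4 for right-hand responses — re-epochs
#' it to the stimulus or the response, baseline-corrects each trial
#' (stimulus-locked: mean of the 200 ms immediately preceding stimulus
#' onset; response-locked: mean of 400-600 ms pre-response) and averages
#' across trials. Only correct trials enter the average by default.
#' Artifact rejection is assumed to have been applied beforehand.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param locking `"stimulus"` or `"response"`.
#' @param window_ms Output window relative to the locking event; defaults
#'   to -200..1500 ms (stimulus) or -600..200 ms (response).
#' @param baseline_ms Baseline window relative to the locking event;
#'   defaults to -200..0 ms (stimulus) or -600..-400 ms (response).
#' @param correct_only Restrict to correct trials.
#' @param condition Optional condition label to restrict to.
#' @param flip Multiply the waveform by -1 (orientation flag; all measures
#'   operate on the waveform as returned, so set this if the pre-response
#'   deflection comes out negative in your recording convention).
#' @return An object of class `lrp_waveform`: `time_ms` (0 = locking
#'   event), `amplitude` (microvolts), `n` trials averaged, `locking`,
#'   `condition`.
#' @export
compute_lrp <- function(epochs, locking = c("stimulus", "response"),
                        window_ms = NULL, baseline_ms = NULL,
                        correct_only = TRUE, condition = NULL,
                        flip = FALSE) {
  locking <- match.arg(locking)
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(window_ms))
    window_ms <- if (locking == "stimulus") c(-200, 1500) else c(-600, 200)
  if (is.null(baseline_ms))
    baseline_ms <- if (locking == "stimulus") c(-200, 0) else c(-600, -400)

  keep <- rep(TRUE, n_trials(epochs))
  if (correct_only) keep <- keep & epochs$correct
  if (!is.null(condition)) keep <- keep & epochs$condition == condition
  if (!any(keep)) stop("no trials to average (after correctness/condition filter)")

  c3 <- match("C3", epochs$ch_names)
  c4 <- match("C4", epochs$ch_names)
  if (anyNA(epochs$hand[keep])) stop("missing hand labels")

  sf <- epochs$sfreq
  rel <- seq(ms_to_samples(window_ms[1], sf), ms_to_samples(window_ms[2], sf))
  rel_base <- seq(ms_to_samples(baseline_ms[1], sf),
                  ms_to_samples(baseline_ms[2], sf))
  # index of each trial's locking event on the epoch grid
  ev_ms <- if (locking == "stimulus") epochs$stim_ms else epochs$resp_ms
  if (anyNA(ev_ms[keep])) stop("missing event latencies for the chosen locking")
  i0 <- vapply(ev_ms, function(m)
    which.min(abs(epochs$time_ms - m)), numeric(1))

  ns <- dim(epochs$data)[3]
  idx <- which(keep)
  cover <- i0[idx] + min(c(rel, rel_base)) >= 1 &
           i0[idx] + max(c(rel, rel_base)) <= ns
  if (!any(cover)) stop("re-epoching window exceeds all trial epochs")
  if (!all(cover))
    warning(sprintf("%d trial(s) cannot cover the %s-locked window and were dropped",
                    sum(!cover), locking))
  idx <- idx[cover]

  mat <- matrix(NA_real_, length(idx), length(rel))
  for (r in seq_along(idx)) {
    i <- idx[r]
    d <- if (epochs$hand[i] == "left")
      epochs$data[i, c4, ] - epochs$data[i, c3, ]
    else
      epochs$data[i, c3, ] - epochs$data[i, c4, ]
    mat[r, ] <- d[i0[i] + rel] - mean(d[i0[i] + rel_base])
  }
  amp <- colMeans(mat)
  if (flip) amp <- -amp
  structure(list(time_ms = rel * 1000 / sf, amplitude = amp, n = length(idx),
                 locking = locking,
                 condition = if (is.null(condition)) NA_character_ else condition),
            class = "lrp_waveform")
}

#' @export
print.lrp_waveform <- function(x, ...) {
  cat(sprintf("LRP waveform (%s-locked): %d trials, %g..%g ms, peak %.2f uV\n",
              x$locking, x$n, min(x$time_ms), max(x$time_ms),
              max(abs(x$amplitude))))
  invisible(x)
}

#' Grand-average LRP across subjects
#'
#' Unweighted mean of per-subject LRP waveforms sharing a common time axis.
#'
#' @param lrps A list of `lrp_waveform` objects.
#' @return An `lrp_waveform` whose `n` is the number of subjects.
#' @export
grand_average_lrp <- function(lrps) {
  stopifnot(length(lrps) >= 1L)
  t0 <- lrps[[1]]$time_ms
  for (l in lrps)
    if (!isTRUE(all.equal(l$time_ms, t0)))
      stop("waveforms must share a common time axis")
  amp <- rowMeans(vapply(lrps, function(l) l$amplitude,
                         numeric(length(t0))))
  structure(list(time_ms = t0, amplitude = amp, n = length(lrps),
                 locking = lrps[[1]]$locking, condition = NA_character_),
            class = "lrp_waveform")
}
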