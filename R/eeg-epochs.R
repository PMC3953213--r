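#' Epoched multichannel EEG container
#'
#' In-memory container for epoched EEG: a trials x channels x samples array
#' of voltages (microvolts) plus per-trial events and metadata. The time
#' axis is a uniform grid in ms; per-trial stimulus-onset and response
#' latencies are given on the same axis. Channel labels must include `C3`,
#' `C4` and an eye channel.
#'
#' @param data Numeric array, trials x channels x samples (microvolts).
#' @param sfreq Sampling rate (Hz).
#' @param ch_names Channel labels (length = dim 2 of `data`).
#' @param time_ms Sample times (ms; length = dim 3 of `data`). By
#'   convention 0 is stimulus onset.
#' @param stim_ms Per-trial stimulus-onset latency (ms on `time_ms`).
#' @param resp_ms Per-trial response latency (ms on `time_ms`).
#' @param hand Per-trial response hand, `"left"` or `"right"`.
#' @param condition Per-trial condition label.
#' @param correct Per-trial correctness (logical).
#' @param eog Name of the eye channel.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, sfreq, ch_names, time_ms,
                       stim_ms = rep(0, dim(data)[1]), resp_ms,
                       hand, condition = rep("cond1", dim(data)[1]),
                       correct = rep(TRUE, dim(data)[1]), eog = "EOG") {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  n <- dim(data)[1]
  if (length(ch_names) != dim(data)[2])
    stop("ch_names length must match channel dimension")
  if (length(time_ms) != dim(data)[3])
    stop("time_ms length must match sample dimension")
  for (ch in c("C3", "C4", eog))
    if (!ch %in% ch_names) stop(sprintf("channel '%s' is required", ch))
  if (anyNA(data)) stop("data must not contain NA")
  step <- 1000 / sfreq
  if (max(abs(diff(time_ms) - step)) > 1e-6)
    stop("time_ms must be a uniform grid at the sampling rate")
  stopifnot(length(stim_ms) == n, length(resp_ms) == n, length(hand) == n,
            length(condition) == n, length(correct) == n)
  if (!all(hand %in% c("left", "right")))
    stop("hand must be 'left' or 'right'")
  rng <- range(time_ms)
  if (any(stim_ms < rng[1] | stim_ms > rng[2]) ||
      any(resp_ms < rng[1] | resp_ms > rng[2], na.rm = TRUE))
    stop("event latencies must lie inside the epoch")
  structure(list(data = data, sfreq = sfreq, ch_names = ch_names,
                 time_ms = time_ms, stim_ms = stim_ms, resp_ms = resp_ms,
                 hand = hand, condition = as.character(condition),
                 correct = as.logical(correct), eog = eog),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("EEG epochs: %d trial(s), %d channel(s) (%s), %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2],
              paste(x$ch_names, collapse = ", "),
              dim(x$data)[3], x$sfreq))
  cat(sprintf("  epoch %g..%g ms, conditions: %s\n",
              min(x$time_ms), max(x$time_ms),
              paste(unique(x$condition), collapse = ", ")))
  invisible(x)
}

#' Number of trials in an epochs object
#' @param epochs An [eeg_epochs()] object.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset trials of an epochs object
#' @param epochs An [eeg_epochs()] object.
#' @param keep Integer or logical index of trials to keep.
#' @return A new `eeg_epochs` object.
#' @export
subset_trials <- function(epochs, keep) {
  if (is.logical(keep)) keep <- which(keep)
  if (!length(keep)) stop("no trials left after subsetting")
  eeg_epochs(epochs$data[keep, , , drop = FALSE], epochs$sfreq,
             epochs$ch_names, epochs$time_ms, epochs$stim_ms[keep],
             epochs$resp_ms[keep], epochs$hand[keep],
             epochs$condition[keep], epochs$correct[keep], epochs$eog)
}

#' Write / read epoched EEG as a JSON sidecar plus CSV matrix
#'
#' Plain-text persistence: `<basename>.json` holds the sampling rate,
#' channel labels, time axis and per-trial metadata; `<basename>.csv` holds
#' the voltages, one row per trial x channel.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param basename Path prefix (without extension).
#' @return `read_eeg_epochs` returns an `eeg_epochs` object.
#' @export
write_eeg_epochs <- function(epochs, basename) {
  meta <- list(sfreq = epochs$sfreq, ch_names = epochs$ch_names,
               time_ms = epochs$time_ms, stim_ms = epochs$stim_ms,
               resp_ms = epochs$resp_ms, hand = epochs$hand,
               condition = epochs$condition, correct = epochs$correct,
               eog = epochs$eog, n_trials = dim(epochs$data)[1])
  jsonlite::write_json(meta, paste0(basename, ".json"), digits = NA)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  df <- cbind(data.frame(trial = rep(seq_len(d[1]), each = d[2]),
                         channel = rep(epochs$ch_names, d[1])),
              as.data.frame(flat))
  write.csv(df, paste0(basename, ".csv"), row.names = FALSE)
  invisible(basename)
}

#' @rdname write_eeg_epochs
#' @export
read_eeg_epochs <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"), simplifyVector = TRUE)
  df <- read.csv(paste0(basename, ".csv"), check.names = FALSE)
  ns <- length(meta$time_ms)
  nc <- length(meta$ch_names)
  arr <- array(NA_real_, c(meta$n_trials, nc, ns))
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  for (i in seq_len(nrow(df)))
    arr[df$trial[i], match(df$channel[i], meta$ch_names), ] <- vals[i, ]
  eeg_epochs(arr, meta$sfreq, meta$ch_names, meta$time_ms, meta$stim_ms,
             meta$resp_ms, meta$hand, meta$condition, meta$correct, meta$eog)
}

# ms -> sample offset, round half away from zero
ms_to_samples <- function(ms, sfreq) {
  x <- ms * sfreq / 1000
  as.integer(sign(x) * floor(abs(x) + 0.5))
}
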