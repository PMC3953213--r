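#' Reject artifact-contaminated trials
#'
#' Screens every trial against the standard rejection rules: eyeblinks
#' (running average of the eye channel exceeding `blink_uv`), excessive
#' signal amplitude on any EEG channel, variance outside
#' `[var_min, var_max]` (in microvolts squared), and excess kurtosis above
#' `kurt_max`. Amplitude, variance and kurtosis rules apply to the EEG
#' channels (all channels except the eye channel); the blink rule applies
#' to the eye channel only.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param blink_uv Blink threshold on the running average of the eye
#'   channel (microvolts).
#' @param blink_win_ms Running-average window for blink detection (ms).
#' @param amp_uv Absolute amplitude threshold (microvolts).
#' @param var_max,var_min Variance bounds (microvolts squared).
#' @param kurt_max Excess-kurtosis threshold.
#' @return A list: `epochs` (surviving trials), `report` (data frame with
#'   one row per rejected trial: `trial`, `rule` = first rule tripped in
#'   precedence order blink > amplitude > variance_high > variance_low >
#'   kurtosis, and `rules` = all rules tripped), and `counts` (per-rule
#'   totals over all tripped rules).
#' @export
reject_artifacts <- function(epochs, blink_uv = 100, blink_win_ms = 100,
                             amp_uv = 70, var_max = 80, var_min = 0.1,
                             kurt_max = 5) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  n <- n_trials(epochs)
  eeg_idx <- which(epochs$ch_names != epochs$eog)
  eog_idx <- which(epochs$ch_names == epochs$eog)
  k <- max(ms_to_samples(blink_win_ms, epochs$sfreq), 1L)
  kern <- rep(1 / k, k)

  rules <- c("blink", "amplitude", "variance_high", "variance_low", "kurtosis")
  tripped <- matrix(FALSE, n, length(rules), dimnames = list(NULL, rules))
  for (i in seq_len(n)) {
    eog <- epochs$data[i, eog_idx, ]
    ra <- stats::filter(eog, kern, sides = 2)
    tripped[i, "blink"] <- any(abs(ra) > blink_uv, na.rm = TRUE)
    for (j in eeg_idx) {
      x <- epochs$data[i, j, ]
      if (max(abs(x)) > amp_uv) tripped[i, "amplitude"] <- TRUE
      v <- mean((x - mean(x))^2)
      if (v > var_max) tripped[i, "variance_high"] <- TRUE
      if (v < var_min) tripped[i, "variance_low"] <- TRUE
      if (v > 0) {
        kurt <- mean((x - mean(x))^4) / v^2 - 3
        if (kurt > kurt_max) tripped[i, "kurtosis"] <- TRUE
      }
    }
  }
  bad <- which(rowSums(tripped) > 0)
  report <- data.frame(
    trial = bad,
    rule = vapply(bad, function(i) rules[which(tripped[i, ])[1]], character(1)),
    rules = vapply(bad, function(i)
      paste(rules[tripped[i, ]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  if (length(bad) == n)
    stop("all trials were rejected; check the data or thresholds")
  keep <- setdiff(seq_len(n), bad)
  list(epochs = subset_trials(epochs, keep), report = report,
       counts = colSums(tripped), kept = keep)
}
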