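#' Drift-diffusion model parameters for one condition
#'
#' Container for the pure DDM (no across-trial variability). Evidence evolves
#' as \eqn{dX = v\,dt + s\,dW} between absorbing boundaries at 0 and `a`,
#' starting at `z`. A response at the upper boundary is coded as the
#' right-hand choice, the lower boundary as the left-hand choice. Observed
#' response time is decision time plus the non-decision time `t0`
#' (perceptual plus motor latency). Following the usual scaling convention
#' the noise coefficient is fixed at `s = 0.1` unless overridden.
#'
#' @param v Drift rate (evidence units per second). Sign gives the favored
#'   boundary: positive drifts toward the upper boundary.
#' @param a Boundary separation / decision threshold (evidence units), > 0.
#'   One boundary sits at zero, the other at `a`.
#' @param z Starting point (evidence units), strictly between 0 and `a`.
#'   Defaults to the unbiased value `a / 2`.
#' @param t0 Non-decision time (seconds), >= 0.
#' @param s Noise coefficient (evidence units per sqrt-second), > 0.
#'
#' @return An object of class `ddm_params` (a named list).
#' @examples
#' p <- ddm_params(v = 0.060, a = 0.151, t0 = 0.435)
#' ddm_choice_probability(p)
#' @export
ddm_params <- function(v, a, z = a / 2, t0 = 0, s = 0.1) {
  stopifnot(is.numeric(v), length(v) == 1L, is.finite(v),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(z), length(z) == 1L, is.finite(z),
            is.numeric(t0), length(t0) == 1L, is.finite(t0),
            is.numeric(s), length(s) == 1L, is.finite(s))
  if (a <= 0) stop("threshold 'a' must be > 0")
  if (z <= 0 || z >= a) stop("starting point 'z' must satisfy 0 < z < a")
  if (t0 < 0) stop("non-decision time 't0' must be >= 0")
  if (s <= 0) stop("noise coefficient 's' must be > 0")
  structure(list(v = v, a = a, z = z, t0 = t0, s = s), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "DDM parameters: v = %.4g, a = %.4g, z = %.4g, t0 = %.4g s, s = %.3g\n",
    x$v, x$a, x$z, x$t0, x$s))
  invisible(x)
}

as_ddm_params <- function(x) {
  if (inherits(x, "ddm_params")) return(x)
  ddm_params(v = x$v, a = x$a, z = x$z, t0 = x$t0,
             s = if (is.null(x$s)) 0.1 else x$s)
}

#' Validate a behavioral trial table
#'
#' A trial table is a data frame with one row per trial and columns
#' `trial`, `condition`, `choice` (`"upper"`/`"lower"`), `hand`
#' (`"right"`/`"left"`), `rt` (seconds) and `correct` (logical). Upper-boundary
#' choices map to right-hand responses and lower-boundary choices to
#' left-hand responses.
#'
#' @param trials A data frame.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_trial_table <- function(trials) {
  req <- c("trial", "condition", "choice", "hand", "rt", "correct")
  miss <- setdiff(req, names(trials))
  if (length(miss))
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(trials)) {
    if (!all(trials$choice %in% c("upper", "lower")))
      stop("choice must be 'upper' or 'lower'")
    if (!all(trials$hand %in% c("left", "right")))
      stop("hand must be 'left' or 'right'")
    if (any(!is.finite(trials$rt)) || any(trials$rt <= 0))
      stop("rt must be finite and > 0")
    if (!is.logical(trials$correct))
      stop("correct must be logical")
    ok <- ifelse(trials$choice == "upper", "right", "left") == trials$hand
    if (!all(ok))
      stop("hand labels inconsistent with choices (upper = right, lower = left)")
  }
  invisible(trials)
}

#' Read or write a trial table as CSV
#'
#' Plain CSV with header `trial,condition,choice,hand,rt,correct`; RT in
#' seconds.
#'
#' @param path File path.
#' @param trials A trial table (see [validate_trial_table()]).
#' @return `read_trial_table` returns the validated data frame.
#' @export
read_trial_table <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  trials$correct <- as.logical(trials$correct)
  validate_trial_table(trials)
  trials
}

#' @rdname read_trial_table
#' @export
write_trial_table <- function(trials, path) {
  validate_trial_table(trials)
  write.csv(trials[, c("trial", "condition", "choice", "hand", "rt", "correct")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
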