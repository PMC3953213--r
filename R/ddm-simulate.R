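#' Simulate behavioral trials from the pure DDM
#'
#' Euler-Maruyama path simulation of the two-boundary diffusion for one or
#' more conditions. RT is the first boundary-crossing time plus the
#' condition's non-decision time; the choice is given by the boundary
#' reached (upper = right hand, lower = left hand). Trials that have not
#' been absorbed after `max_t` seconds are dropped with a warning.
#'
#' @param params A [ddm_params()] object or a named list of them (one per
#'   condition).
#' @param n Trials per condition (recycled to the number of conditions).
#' @param dt Integration step in seconds; must be <= 1 ms (default 0.1 ms).
#' @param seed Integer RNG seed; required for reproducibility.
#' @param max_t Non-termination guard (seconds).
#' @param correct_boundary Which boundary counts as the correct response,
#'   per condition (default `"upper"`, i.e. drift points toward the correct
#'   response when positive).
#' @return A trial table (see [validate_trial_table()]).
#' @examples
#' tt <- ddm_simulate(ddm_params(v = 0.2, a = 0.12, t0 = 0.3), n = 100, seed = 1)
#' mean(tt$correct)
#' @export
ddm_simulate <- function(params, n, dt = 1e-4, seed, max_t = 30,
                         correct_boundary = "upper") {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  if (dt > 1e-3) stop("dt must be <= 1 ms")
  if (inherits(params, "ddm_params")) params <- list(condition1 = params)
  stopifnot(length(params) >= 1)
  if (is.null(names(params)) || any(!nzchar(names(params))))
    stop("'params' must be a named list (one entry per condition)")
  n <- rep_len(n, length(params))
  correct_boundary <- rep_len(correct_boundary, length(params))
  set.seed(as.integer(seed))
  out <- vector("list", length(params))
  for (i in seq_along(params)) {
    if (n[i] == 0L) { out[[i]] <- empty_trial_table()[-1]; next }
    p <- as_ddm_params(params[[i]])
    sim <- ddm_simulate_cpp(as.integer(n[i]), p$v, p$a, p$z, p$t0, p$s,
                            dt, max_t)
    bad <- is.na(sim$rt)
    if (any(bad))
      warning(sprintf("%d trial(s) in condition '%s' hit the %g s guard and were dropped",
                      sum(bad), names(params)[i], max_t))
    choice <- ifelse(sim$upper[!bad] == 1L, "upper", "lower")
    out[[i]] <- data.frame(
      condition = names(params)[i],
      choice = choice,
      hand = ifelse(choice == "upper", "right", "left"),
      rt = sim$rt[!bad],
      correct = choice == correct_boundary[i],
      stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, out)
  trials <- cbind(trial = seq_len(nrow(trials)), trials)
  rownames(trials) <- NULL
  if (!nrow(trials)) return(empty_trial_table())
  validate_trial_table(trials)
  trials
}
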