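#' Generate synthetic behavioral data with known ground truth
#'
#' Simulates trial tables from per-condition DDM parameters. In the default
#' (coherence-style) mode every trial's correct response is the upper
#' boundary and the drift points toward it. In bias mode (when `bias_prob`
#' is given) the motion direction of each trial is drawn with the stated
#' probability of the preferred (upper) direction; the drift sign follows
#' the stimulus direction while the starting point stays where the
#' condition's parameters put it, emulating blocks with unequal stimulus
#' proportions.
#'
#' @param params Named list of [ddm_params()] (one per condition).
#' @param n Trials per condition.
#' @param seed Integer seed.
#' @param bias_prob Optional named vector (aligned with `params`) of
#'   probabilities that the stimulus moves in the preferred direction.
#' @param dt Euler step for the path simulation (s).
#' @return A trial table; in bias mode with an extra column `direction`
#'   (`"preferred"`/`"nonpreferred"`).
#' @export
simulate_behavior <- function(params, n, seed, bias_prob = NULL, dt = 1e-4) {
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  if (inherits(params, "ddm_params")) params <- list(cond1 = params)
  if (is.null(bias_prob))
    return(ddm_simulate(params, n = n, dt = dt, seed = seed))

  stopifnot(length(bias_prob) == length(params),
            all(bias_prob > 0 & bias_prob < 1))
  n <- rep_len(n, length(params))
  set.seed(as.integer(seed))
  sub_seeds <- sample.int(.Machine$integer.max, 2L * length(params))
  out <- vector("list", length(params))
  for (i in seq_along(params)) {
    p <- as_ddm_params(params[[i]])
    if (n[i] == 0L) {
      out[[i]] <- empty_trial_table(direction = TRUE)
      next
    }
    set.seed(sub_seeds[2L * i - 1L])
    pref <- runif(n[i]) < bias_prob[i]
    parts <- list()
    if (any(pref)) {
      tt <- ddm_simulate(setNames(list(p), names(params)[i]), n = sum(pref),
                         dt = dt, seed = sub_seeds[2L * i],
                         correct_boundary = "upper")
      tt$direction <- "preferred"
      parts <- c(parts, list(tt))
    }
    if (any(!pref)) {
      # non-preferred stimulus: drift reversed, correct response at the
      # lower boundary; the starting point keeps favoring the upper one
      pn <- ddm_params(v = -p$v, a = p$a, z = p$z, t0 = p$t0, s = p$s)
      tt <- ddm_simulate(setNames(list(pn), names(params)[i]), n = sum(!pref),
                         dt = dt, seed = sub_seeds[2L * i] + 1L,
                         correct_boundary = "lower")
      tt$direction <- "nonpreferred"
      parts <- c(parts, list(tt))
    }
    out[[i]] <- do.call(rbind, parts)
  }
  trials <- do.call(rbind, out)
  trials$trial <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  validate_trial_table(trials)
  trials
}

empty_trial_table <- function(direction = FALSE) {
  df <- data.frame(trial = integer(0), condition = character(0),
                   choice = character(0), hand = character(0),
                   rt = numeric(0), correct = logical(0),
                   stringsAsFactors = FALSE)
  if (direction) df$direction <- character(0)
  df
}
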