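#' Closed-form choice probability of the pure DDM
#'
#' Probability that the diffusion started at `z` reaches the upper boundary
#' `a` before the lower boundary 0:
#' \deqn{P(\mathrm{upper}) = \frac{1 - e^{-2 v z / s^2}}{1 - e^{-2 v a / s^2}}}
#' for \eqn{v \neq 0}, and \eqn{z / a} for \eqn{v = 0}. With an unbiased
#' starting point (\eqn{z = a/2}) this reduces to the logistic form
#' \eqn{1 / (1 + e^{-v a / s^2})}.
#'
#' @param params A [ddm_params()] object.
#' @return Probability of an upper-boundary (right-hand) response.
#' @export
ddm_choice_probability <- function(params) {
  p <- as_ddm_params(params)
  s2 <- p$s^2
  # treat |2 v a / s^2| below machine-noise level as the driftless case
  if (abs(2 * p$v * p$a / s2) < 1e-10) return(p$z / p$a)
  num <- -expm1(clamp_exp(-2 * p$v * p$z / s2))
  den <- -expm1(clamp_exp(-2 * p$v * p$a / s2))
  num / den
}

# keep exp() arguments finite; beyond +-700 the ratio saturates anyway
clamp_exp <- function(x) pmin(pmax(x, -700), 700)

#' Expected decision time of the pure DDM
#'
#' Unconditional mean first-passage time (excluding non-decision time):
#' \deqn{E[DT] = \frac{a}{v} P(\mathrm{upper}) - \frac{z}{v}}
#' for \eqn{v \neq 0}; in the driftless limit \eqn{E[DT] = z (a - z) / s^2}.
#' With an unbiased starting point this equals
#' \eqn{(a / 2v)\,\tanh(v a / 2 s^2)}. Mean RT is `E[DT] + t0`.
#'
#' @param params A [ddm_params()] object.
#' @return Expected decision time in seconds.
#' @export
ddm_mean_decision_time <- function(params) {
  p <- as_ddm_params(params)
  s2 <- p$s^2
  if (abs(p$v) * p$a / s2 < 1e-6) {
    # series about v = 0; leading term of the exact expression
    return(p$z * (p$a - p$z) / s2)
  }
  (p$a * ddm_choice_probability(p) - p$z) / p$v
}
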