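#' First-passage time density of the pure DDM
#'
#' Defective density of the decision time at one boundary (the density of
#' observed RT at `t + t0`). Computed from the standard series solution for
#' the Wiener first-passage problem, switching between the small-time and
#' large-time expansions: for each `t` the expansion needing fewer terms at
#' truncation error `eps` is used (terms are truncated once they fall below
#' `eps`).
#'
#' Densities are defective: each boundary's density integrates to that
#' boundary's choice probability, and the two integrals sum to one.
#'
#' @param t Decision times (seconds, > 0); vectorized.
#' @param params A [ddm_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @param eps Series truncation bound (default 1e-10).
#' @return Density values, same length as `t`.
#' @export
ddm_fpt_density <- function(t, params, boundary = c("upper", "lower"),
                            eps = 1e-10) {
  boundary <- match.arg(boundary)
  p <- as_ddm_params(params)
  if (boundary == "upper") {
    # hitting a from z under drift v == hitting 0 from a - z under drift -v
    p <- ddm_params(v = -p$v, a = p$a, z = p$a - p$z, t0 = p$t0, s = p$s)
  }
  vn <- p$v / p$s
  an <- p$a / p$s
  w <- p$z / p$a
  vapply(t, function(ti) {
    if (!is.finite(ti) || ti <= 0) return(0)
    tau <- ti / an^2
    f0 <- wfpt_f0(tau, w, eps)
    exp(-vn * an * w - vn^2 * ti / 2) / an^2 * f0
  }, numeric(1))
}

# zero-drift unit-boundary first-passage density at the lower boundary,
# normalized time tau, relative start w; Navarro-Fuss style expansion switch
wfpt_f0 <- function(tau, w, eps = 1e-10) {
  # required term counts for each expansion at truncation error eps
  kl <- if (pi * tau * eps < 1) {
    max(sqrt(-2 * log(pi * tau * eps) / (pi^2 * tau)), 1 / (pi * sqrt(tau)))
  } else 1 / (pi * sqrt(tau))
  ks <- if (2 * sqrt(2 * pi * tau) * eps < 1) {
    max(2 + sqrt(-2 * tau * log(2 * eps * sqrt(2 * pi * tau))), sqrt(tau) + 1)
  } else 2
  if (!is.finite(kl) || !is.finite(ks))
    stop(sprintf("first-passage series failed to converge at tau = %g, w = %g",
                 tau, w))
  if (ks < kl) {
    K <- ceiling(ks)
    j <- seq.int(-K, K)
    sum((w + 2 * j) * exp(-(w + 2 * j)^2 / (2 * tau))) / sqrt(2 * pi * tau^3)
  } else {
    K <- ceiling(kl)
    k <- seq_len(K)
    pi * sum(k * exp(-k^2 * pi^2 * tau / 2) * sin(k * pi * w))
  }
}

#' Defective first-passage CDF of the pure DDM
#'
#' Probability that the process has been absorbed at the given boundary by
#' decision time `t`. Evaluated from the large-time series for the tail mass
#' (adaptively truncated), which converges for all `t > 0`; used by the
#' quantile-multinomial fit objective.
#'
#' @inheritParams ddm_fpt_density
#' @return CDF values in `[0, P(boundary)]`, same length as `t`.
#' @export
ddm_fpt_cdf <- function(t, params, boundary = c("upper", "lower"),
                        eps = 1e-12) {
  boundary <- match.arg(boundary)
  p <- as_ddm_params(params)
  if (boundary == "upper") {
    p <- ddm_params(v = -p$v, a = p$a, z = p$a - p$z, t0 = p$t0, s = p$s)
  }
  vn <- p$v / p$s
  an <- p$a / p$s
  w <- p$z / p$a
  p_bound <- 1 - ddm_choice_probability(p)  # lower-boundary mass after reflection
  pref <- exp(clamp_exp(-vn * an * w)) * pi / an^2
  vapply(t, function(ti) {
    if (!is.finite(ti)) stop("non-finite decision time in ddm_fpt_cdf")
    if (ti <= 0) return(0)
    # series terms decay as exp(-k^2 pi^2 ti / (2 an^2)); bound the index
    K <- ceiling(an * sqrt(2 * -log(eps)) / (pi * sqrt(ti))) + 5
    if (K > 2e5)
      stop(sprintf("first-passage CDF series too long at t = %g (params v=%g a=%g z=%g)",
                   ti, p$v, p$a, p$z))
    k <- seq_len(K)
    lam <- (vn^2 + k^2 * pi^2 / an^2) / 2
    tail_mass <- pref * sum(k * sin(k * pi * w) * exp(-lam * ti) / lam)
    min(max(p_bound - tail_mass, 0), 1)
  }, numeric(1))
}
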