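#' Parameter-sharing design for multi-condition DDM fits
#'
#' Declares, for each DDM parameter, whether it is shared across conditions
#' or free to vary per condition. The noise coefficient `s` is always fixed
#' (0.1 by convention) and is not part of the design.
#'
#' @param conditions Character vector of condition labels (>= 1).
#' @param drift,threshold,start_point,ndt `"free"` or `"shared"`.
#' @param s Fixed noise coefficient.
#' @return An object of class `ddm_fit_design`.
#' @examples
#' fit_design(c("low", "high"), drift = "free", threshold = "shared",
#'            start_point = "shared", ndt = "free")
#' @export
fit_design <- function(conditions, drift = "free", threshold = "shared",
                       start_point = "shared", ndt = "free", s = 0.1) {
  conditions <- as.character(conditions)
  if (length(conditions) < 1L || anyDuplicated(conditions))
    stop("'conditions' must be a non-empty set of unique labels")
  spec <- c(drift = drift, threshold = threshold,
            start_point = start_point, ndt = ndt)
  if (!all(spec %in% c("free", "shared")))
    stop("each design field must be 'free' or 'shared'")
  structure(list(conditions = conditions, drift = drift,
                 threshold = threshold, start_point = start_point,
                 ndt = ndt, s = s),
            class = "ddm_fit_design")
}

#' Read / write a fit design as JSON
#' @param path File path.
#' @param design A [fit_design()] object.
#' @return `read_fit_design` returns a `ddm_fit_design` object.
#' @export
read_fit_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_design(x$conditions, drift = x$drift, threshold = x$threshold,
             start_point = x$start_point, ndt = x$ndt,
             s = if (is.null(x$s)) 0.1 else x$s)
}

#' @rdname read_fit_design
#' @export
write_fit_design <- function(design, path) {
  jsonlite::write_json(unclass(design), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- internal: parameter vector layout and transforms ----------------------

# theta blocks: v (raw), log a, qlogis(z / a), log t0
design_layout <- function(design) {
  nc <- length(design$conditions)
  len <- function(mode) if (mode == "free") nc else 1L
  sizes <- c(v = len(design$drift), a = len(design$threshold),
             w = len(design$start_point), t0 = len(design$ndt))
  offs <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(offs) <- names(sizes)
  list(sizes = sizes, offsets = offs, n_par = sum(sizes))
}

theta_to_params <- function(theta, design, layout) {
  nc <- length(design$conditions)
  pick <- function(field, mode) {
    idx <- layout$offsets[[field]] + seq_len(layout$sizes[[field]])
    vals <- theta[idx]
    if (mode == "shared") rep(vals, nc) else vals
  }
  v <- pick("v", design$drift)
  a <- exp(pmin(pick("a", design$threshold), 10))
  w <- plogis(pick("w", design$start_point))
  t0 <- exp(pmin(pick("t0", design$ndt), 10))
  lapply(seq_len(nc), function(i)
    ddm_params(v = v[i], a = a[i], z = w[i] * a[i], t0 = t0[i], s = design$s))
}

params_to_theta <- function(per_cond, design, layout) {
  grab <- function(field, mode, fn) {
    vals <- vapply(per_cond, fn, numeric(1))
    if (mode == "shared") mean(vals) else vals
  }
  c(grab("v", design$drift, function(p) p$v),
    grab("a", design$threshold, function(p) log(p$a)),
    grab("w", design$start_point, function(p) qlogis(p$z / p$a)),
    grab("t0", design$ndt, function(p) log(max(p$t0, 1e-4))))
}

# ---- internal: quantile-binned data summary --------------------------------

# For each condition x choice cell, the observed RT quantile edges and the
# multinomial bin counts. Cells with fewer than min_cell trials are collapsed
# to a single bin carrying the cell's total count.
bin_trials <- function(trials, design, quantiles, min_cell = 10L) {
  lapply(design$conditions, function(cond) {
    tr <- trials[trials$condition == cond, , drop = FALSE]
    if (!nrow(tr)) stop(sprintf("no trials for condition '%s'", cond))
    cells <- lapply(c(upper = "upper", lower = "lower"), function(ch) {
      rts <- tr$rt[tr$choice == ch]
      m <- length(rts)
      if (m < min_cell) {
        list(collapsed = TRUE, n = m)
      } else {
        edges <- unname(quantile(rts, probs = quantiles, type = 7))
        counts <- diff(c(0, findInterval(edges, sort(rts)), m))
        list(collapsed = FALSE, n = m, edges = edges, counts = counts)
      }
    })
    list(condition = cond, n = nrow(tr), cells = cells)
  })
}

cell_loglik <- function(cell, p, boundary) {
  p_choice <- ddm_choice_probability(p)
  if (boundary == "lower") p_choice <- 1 - p_choice
  if (cell$collapsed) {
    if (cell$n == 0L) return(0)
    return(cell$n * log(max(p_choice, 1e-12)))
  }
  dts <- cell$edges - p$t0
  Fe <- numeric(length(dts))
  pos <- dts > 0
  if (any(pos)) Fe[pos] <- ddm_fpt_cdf(dts[pos], p, boundary = boundary)
  Fe <- cummax(Fe)  # enforce monotonicity against series round-off
  probs <- diff(c(0, Fe, max(p_choice, Fe[length(Fe)])))
  sum(cell$counts * log(pmax(probs, 1e-12)))
}

# ---- internal: EZ-style method-of-moments initial values -------------------

ez_init <- function(trials, cond, s) {
  tr <- trials[trials$condition == cond, , drop = FALSE]
  n <- nrow(tr)
  p_up <- mean(tr$choice == "upper")
  p_acc <- min(max(max(p_up, 1 - p_up), 0.51), 1 - 1 / (2 * n))
  rts <- tr$rt[tr$choice == if (p_up >= 0.5) "upper" else "lower"]
  if (length(rts) < 5) rts <- tr$rt
  vrt <- var(rts)
  L <- qlogis(p_acc)
  x <- L * (L * p_acc^2 - L * p_acc + p_acc - 0.5) / max(vrt, 1e-6)
  v <- s * x^(1 / 4)
  if (!is.finite(v) || v <= 0) v <- 0.1
  a <- s^2 * L / v
  if (!is.finite(a) || a <= 0) a <- 0.15
  a <- min(max(a, 0.02), 1.5)
  mdt <- (a / (2 * v)) * tanh(v * a / (2 * s^2))
  t0 <- mean(tr$rt) - mdt
  t0 <- min(max(t0, 0.25 * min(tr$rt)), 0.95 * min(tr$rt))
  if (p_up < 0.5) v <- -v
  ddm_params(v = v, a = a, z = a / 2, t0 = t0, s = s)
}

#' Fit the pure DDM by quantile-multinomial maximum likelihood
#'
#' Bins each condition-by-choice RT distribution at its observed quantiles
#' (default deciles 0.1, 0.3, 0.5, 0.7, 0.9), evaluates the multinomial
#' log-likelihood of the bin counts under the bin probabilities implied by
#' the Wiener first-passage distribution, and maximizes it by Nelder-Mead
#' with seeded multi-starts from perturbed method-of-moments (EZ-style)
#' initial values. Parameters are shared or free across conditions per the
#' [fit_design()]. Choice cells with fewer than `min_cell` trials are
#' collapsed to a single bin.
#'
#' @param trials A trial table (see [validate_trial_table()]).
#' @param design A [fit_design()] object.
#' @param quantiles RT quantiles defining the bins.
#' @param seed Integer seed for the multi-start perturbations.
#' @param n_starts Number of Nelder-Mead starts (first one unperturbed).
#' @param min_cell Minimum trials for a choice cell to keep quantile bins.
#' @param control Passed to [stats::optim()].
#' @return An object of class `ddm_fit`: fitted `params` per condition,
#'   `logLik`, number of free parameters `k`, `n` trials,
#'   `BIC = k log(n) - 2 logLik`, convergence diagnostics.
#' @export
ddm_fit <- function(trials, design, quantiles = c(0.1, 0.3, 0.5, 0.7, 0.9),
                    seed = 1L, n_starts = 10L, min_cell = 10L,
                    control = list(maxit = 3000, reltol = 1e-9)) {
  validate_trial_table(trials)
  stopifnot(inherits(design, "ddm_fit_design"))
  missing_cond <- setdiff(design$conditions, unique(trials$condition))
  if (length(missing_cond))
    stop("conditions absent from data: ", paste(missing_cond, collapse = ", "))
  layout <- design_layout(design)
  binned <- bin_trials(trials, design, quantiles, min_cell = min_cell)

  negll <- function(theta) {
    pc <- tryCatch(theta_to_params(theta, design, layout),
                   error = function(e) NULL)
    if (is.null(pc)) return(1e10)
    ll <- 0
    for (i in seq_along(binned)) {
      ll <- ll + cell_loglik(binned[[i]]$cells$upper, pc[[i]], "upper") +
                 cell_loglik(binned[[i]]$cells$lower, pc[[i]], "lower")
    }
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  init <- lapply(design$conditions, function(cc) ez_init(trials, cc, design$s))
  theta0 <- params_to_theta(init, design, layout)

  set.seed(as.integer(seed))
  best <- NULL
  fails <- 0L
  for (k in seq_len(n_starts)) {
    th <- if (k == 1L) theta0 else theta0 + rnorm(length(theta0), 0, 0.25)
    res <- tryCatch(optim(th, negll, method = "Nelder-Mead", control = control),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) { fails <- fails + 1L; next }
    if (is.null(best) ||
        res$value < best$value - 1e-6 ||
        (abs(res$value - best$value) <= 1e-6 &&
         sum(res$par^2) < sum(best$par^2))) {
      best <- res
    }
  }
  if (is.null(best))
    stop(sprintf("all %d optimizer starts failed", n_starts))
  if (fails > 0L)
    warning(sprintf("%d of %d optimizer starts failed", fails, n_starts))

  pars <- theta_to_params(best$par, design, layout)
  names(pars) <- design$conditions
  n <- nrow(trials[trials$condition %in% design$conditions, , drop = FALSE])
  k_free <- layout$n_par
  ll <- -best$value
  structure(list(
    params = pars, design = design, logLik = ll, k = k_free, n = n,
    BIC = k_free * log(n) - 2 * ll,
    convergence = best$convergence, counts = best$counts,
    quantiles = quantiles), class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Pure DDM fit: %d condition(s), %d free parameter(s), n = %d\n",
              length(x$params), x$k, x$n))
  cat(sprintf("  logLik = %.2f, BIC = %.2f\n", x$logLik, x$BIC))
  for (nm in names(x$params)) {
    p <- x$params[[nm]]
    cat(sprintf("  %-12s v = %8.4f  a = %7.4f  z = %7.4f  t0 = %6.4f\n",
                nm, p$v, p$a, p$z, p$t0))
  }
  invisible(x)
}

#' Write a DDM fit result as JSON
#' @param fit A `ddm_fit` object.
#' @param path File path.
#' @export
write_fit_result <- function(fit, path) {
  out <- list(
    conditions = lapply(fit$params, function(p)
      list(v = p$v, a = p$a, z = p$z, t0 = p$t0, s = p$s)),
    logLik = fit$logLik, k = fit$k, n = fit$n, BIC = fit$BIC,
    convergence = fit$convergence)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
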