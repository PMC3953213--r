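#' LRP onset by 1-degree-of-freedom regression
#'
#' Finds the intersection of a horizontal segment fitted to the initial
#' part of the waveform (slope constrained to zero) with a straight line
#' fitted to the rise toward the peak. The breakpoint between the two
#' segments is chosen by grid search over all samples in the window,
#' minimizing the total sum of squared errors; ties go to the earliest
#' breakpoint. The reported onset is where the fitted rise line crosses
#' the baseline level (clamped to the search window); on an exact
#' flat-then-ramp waveform this is the corner itself. Errors if no rising
#' segment exists (fitted slope <= 0 for every admissible breakpoint).
#'
#' The fitted rise ends at the first crossing of `rise_frac` times the
#' in-window maximum (when that lies inside the window): close to the peak
#' the averaged waveform flattens as per-trial peak times spread, and a
#' straight line fitted through that curvature drags the breakpoint late.
#' Set `rise_frac = 1` to fit all the way to the window end.
#'
#' @param lrp An `lrp_waveform` (or any list with `time_ms`, `amplitude`).
#' @param window_ms Search window `c(start, end)`; should span the baseline
#'   through the rise to peak. Defaults to 0 through the time of the
#'   waveform maximum.
#' @param min_seg Minimum samples per segment.
#' @param rise_frac Fraction of the in-window maximum at which the fitted
#'   rise segment ends.
#' @return Onset latency in ms (the breakpoint).
#' @export
lrp_onset <- function(lrp, window_ms = NULL, min_seg = 3L, rise_frac = 0.5) {
  tt <- lrp$time_ms
  yy <- lrp$amplitude
  if (is.null(window_ms)) {
    window_ms <- c(min(0, tt[1]), tt[which.max(yy)])
    # flat or immediately-peaked waveforms: search the full axis so the
    # no-rise check (rather than a window error) reports the problem
    if (sum(tt >= window_ms[1] & tt <= window_ms[2]) < 2L * min_seg + 2L)
      window_ms[2] <- max(tt)
  }
  sel <- which(tt >= window_ms[1] & tt <= window_ms[2])
  if (rise_frac < 1 && length(sel)) {
    ymax <- max(yy[sel])
    y0 <- yy[sel[1]]
    crossed <- which(yy[sel] >= y0 + rise_frac * (ymax - y0))
    if (length(crossed) && crossed[1] > 2L * min_seg)
      sel <- sel[seq_len(crossed[1])]
  }
  if (length(sel) < 2L * min_seg)
    stop("search window too short for onset regression")
  t <- tt[sel]
  y <- yy[sel]
  n <- length(y)
  best <- list(sse = Inf, b = NA_integer_, slope = NA_real_,
               level = NA_real_, t_mean = NA_real_, y_mean = NA_real_)
  for (b in seq(min_seg, n - min_seg)) {
    y1 <- y[seq_len(b)]
    level <- mean(y1)
    sse1 <- sum((y1 - level)^2)
    t2 <- t[seq(b, n)]
    y2 <- y[seq(b, n)]
    tc <- t2 - mean(t2)
    slope <- sum(tc * y2) / sum(tc^2)
    sse2 <- sum((y2 - mean(y2) - slope * tc)^2)
    sse <- sse1 + sse2
    if (sse < best$sse - 1e-12)
      best <- list(sse = sse, b = b, slope = slope, level = level,
                   t_mean = mean(t2), y_mean = mean(y2))
  }
  if (!is.finite(best$sse) || is.na(best$b) || best$slope <= 0)
    stop("no rise detected in the onset search window")
  onset <- best$t_mean + (best$level - best$y_mean) / best$slope
  min(max(onset, t[1]), t[n])
}

# local maxima filtered by prominence: height above the higher of the two
# flanking troughs (toward the previous/next local maximum or window edge)
# must exceed min_prom * range(y)
prominent_maxima <- function(y, min_prom = 0.2) {
  pk <- local_extrema(y, "max")
  if (!length(pk) || min_prom <= 0) return(pk)
  thr <- min_prom * diff(range(y))
  n <- length(y)
  keep <- logical(length(pk))
  for (i in seq_along(pk)) {
    p <- pk[i]
    # extend each side to the nearest strictly higher point (or the edge);
    # the base on that side is the minimum over the stretch
    jl <- which(y[seq_len(p - 1L)] > y[p])
    left <- min(y[(if (length(jl)) max(jl) else 1L):p])
    jr <- which(y[(p + 1L):n] > y[p]) + p
    right <- min(y[p:(if (length(jr)) min(jr) else n)])
    keep[i] <- (y[p] - max(left, right)) >= thr
  }
  pk[keep]
}

# local maxima (or minima) indices; plateaus count once, at their earliest
# sample; endpoints are excluded
local_extrema <- function(y, find = c("max", "min")) {
  find <- match.arg(find)
  if (find == "min") y <- -y
  n <- length(y)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Peak latency and baseline-to-peak height of an LRP
#'
#' Stimulus-locked: the peak is the first local maximum before the
#' reference RT, and the height is the distance between the waveform at its
#' onset and at the peak. Response-locked: the peak is the last local
#' maximum before the response (time 0) and the height is the distance
#' between that peak and the preceding trough. Plateaus resolve to their
#' earliest sample. Height is invariant to constant offsets.
#'
#' Residual noise in an averaged waveform produces small spurious local
#' maxima; only peaks whose prominence (height above the higher of the two
#' flanking troughs) exceeds `min_prom` times the in-window amplitude range
#' are considered. Set `min_prom = 0` to accept every local maximum.
#'
#' @param lrp An `lrp_waveform`.
#' @param locking `"stimulus"` or `"response"`; defaults to the waveform's
#'   own locking tag.
#' @param rt_ref_ms Stimulus-locked search bound (typically the median RT).
#' @param onset_ms Onset latency for the stimulus-locked height; computed
#'   via [lrp_onset()] when omitted.
#' @param min_prom Minimum peak prominence as a fraction of the in-window
#'   range.
#' @return A list with `peak_latency_ms` and `peak_height_uv`.
#' @export
lrp_peak <- function(lrp, locking = NULL, rt_ref_ms = NULL, onset_ms = NULL,
                     min_prom = 0.2) {
  if (is.null(locking)) locking <- lrp$locking
  locking <- match.arg(locking, c("stimulus", "response"))
  tt <- lrp$time_ms
  yy <- lrp$amplitude
  if (locking == "stimulus") {
    if (is.null(rt_ref_ms)) stop("rt_ref_ms is required for stimulus locking")
    sel <- which(tt <= rt_ref_ms)
    pk <- prominent_maxima(yy[sel], min_prom)
    if (!length(pk)) stop("no local maximum before the reference RT")
    ipk <- sel[pk[1]]
    if (is.null(onset_ms)) onset_ms <- lrp_onset(lrp, c(min(0, tt[1]), tt[ipk]))
    y_on <- yy[which.min(abs(tt - onset_ms))]
    list(peak_latency_ms = tt[ipk], peak_height_uv = yy[ipk] - y_on)
  } else {
    sel <- which(tt < 0)
    pk <- prominent_maxima(yy[sel], min_prom)
    if (!length(pk)) stop("no local maximum before the response")
    ipk <- sel[pk[length(pk)]]
    # preceding trough: last local minimum before the peak, or the window
    # start if the rise is monotone
    tr <- local_extrema(yy[seq_len(ipk)], "min")
    itr <- if (length(tr)) tr[length(tr)] else which.min(yy[seq_len(ipk)])
    list(peak_latency_ms = tt[ipk], peak_height_uv = yy[ipk] - yy[itr])
  }
}

#' Area between two LRP curves
#'
#' Trapezoidal integral of `lrp_low - lrp_high` over the window, in
#' microvolt-milliseconds. With the package's orientation convention
#' (pre-response deflection positive) the area is positive in the rising
#' phase when the high-drift curve sits below the low-drift curve, i.e.
#' when drift separates the waveforms as the threshold-layer account
#' predicts.
#'
#' @param lrp_low,lrp_high Two `lrp_waveform`s on a common time axis
#'   (conventionally the low- and high-drift conditions).
#' @param window_ms Integration window (ms relative to the locking event).
#' @return Signed area (microvolt-ms).
#' @export
lrp_area_between <- function(lrp_low, lrp_high, window_ms) {
  if (!isTRUE(all.equal(lrp_low$time_ms, lrp_high$time_ms)))
    stop("waveforms must share a common time axis")
  tt <- lrp_low$time_ms
  if (window_ms[1] < min(tt) || window_ms[2] > max(tt))
    stop("window outside the overlap of the two waveforms")
  dd <- lrp_low$amplitude - lrp_high$amplitude
  sel <- which(tt >= window_ms[1] & tt <= window_ms[2])
  if (length(sel) < 2L) stop("window contains fewer than two samples")
  # integrate exactly over the requested window: interpolate the endpoints
  x <- tt[sel]
  d <- dd[sel]
  if (x[1] > window_ms[1]) {
    x <- c(window_ms[1], x)
    d <- c(approx(tt, dd, window_ms[1])$y, d)
  }
  if (x[length(x)] < window_ms[2]) {
    x <- c(x, window_ms[2])
    d <- c(d, approx(tt, dd, window_ms[2])$y)
  }
  sum(diff(x) * (head(d, -1) + tail(d, -1)) / 2)
}

#' Neural non-decision time from stimulus- and response-locked LRPs
#'
#' Adds the time until the stimulus-locked LRP departs from baseline (1DF
#' onset) to the interval between the response-locked LRP peak and the
#' motor response: `neural_t0 = onset + |peak latency|` (the response-locked
#' peak latency is negative, in ms before the response). This decomposes
#' the DDM's non-decision time into a perceptual and a motor latency.
#'
#' @param stim_lrp Stimulus-locked `lrp_waveform`.
#' @param resp_lrp Response-locked `lrp_waveform`.
#' @param median_rt_ms Median RT (ms), bounding the onset search window.
#' @param onset_window_ms Optional explicit onset search window.
#' @return A list with `neural_t0_ms`, `onset_ms`, `peak_latency_ms`.
#' @export
lrp_neural_t0 <- function(stim_lrp, resp_lrp, median_rt_ms,
                          onset_window_ms = NULL) {
  if (is.null(onset_window_ms)) onset_window_ms <- c(0, median_rt_ms)
  onset <- lrp_onset(stim_lrp, onset_window_ms)
  pk <- lrp_peak(resp_lrp, "response")
  list(neural_t0_ms = onset + abs(pk$peak_latency_ms),
       onset_ms = onset, peak_latency_ms = pk$peak_latency_ms)
}
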