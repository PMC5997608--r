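# Respirometric signal processing: OUR from paired DO sensors, finite
# differences of the OUR series, and feast-end detection.

#' Uniformly sampled OUR series
#'
#' @param t_min sample times in minutes, uniform grid.
#' @param value OUR values, mg O2/L/min (clipped at 0).
#' @param provenance `"simulated"` or `"file"`.
#' @return A data.frame of class `our_series` with columns `t_min`, `our`,
#'   and attributes `dt_min` (sampling interval) and `provenance`.
#' @export
our_series <- function(t_min, value, provenance = c("simulated", "file")) {
  provenance <- match.arg(provenance)
  if (length(t_min) != length(value)) stop("t_min and value lengths differ")
  if (length(t_min) < 2L) stop("an OUR series needs at least two samples")
  d <- diff(t_min)
  if (any(abs(d - d[1]) > 1e-8)) stop("OUR series must be uniformly sampled")
  structure(data.frame(t_min = t_min, our = pmax(value, 0)),
            dt_min = d[1], provenance = provenance,
            class = c("our_series", "data.frame"))
}

#' OUR from a dual dissolved-oxygen measurement
#'
#' In a recirculating respirometer the oxygen uptake rate equals the DO drop
#' across the unaerated reaction tank divided by its hydraulic residence
#' time: OUR = (DO_in - DO_out) / tau, clipped at zero.
#'
#' @param do_in inflow DO, mg/L.
#' @param do_out outflow DO, mg/L.
#' @param residence_time_min hydraulic residence time of the reaction tank
#'   (V_reaction / recirculation flow), minutes, > 0.
#' @return OUR in mg O2/L/min.
#' @export
our_from_dual_do <- function(do_in, do_out, residence_time_min) {
  if (!is.numeric(residence_time_min) || any(residence_time_min <= 0))
    stop("residence time must be positive")
  pmax((do_in - do_out) / residence_time_min, 0)
}

# trailing (causal) or centered running median
our_smooth <- function(x, w = 3, causal = FALSE) {
  if (w <= 1) return(x)
  if (causal) {
    n <- length(x)
    vapply(seq_len(n), function(i) stats::median(x[max(1, i - w + 1):i]),
           numeric(1))
  } else {
    as.numeric(stats::runmed(x, k = if (w %% 2 == 1) w else w + 1,
                             endrule = "keep"))
  }
}

#' Finite-difference derivative of an OUR series
#'
#' Computes (OUR[n+1] - OUR[n]) / dt, optionally after moving-median
#' pre-smoothing, which suppresses single-sample sensor spikes without
#' biasing monotone segments (the median of collinear points is the middle
#' point, so a linear ramp keeps its exact slope).
#'
#' @param series an [our_series()], or a numeric vector with `dt_min` given.
#' @param n index of the left sample; `NULL` returns the derivative at every
#'   admissible point (length `length(series) - lag`).
#' @param smooth_w moving-median window (1 = none).
#' @param lag difference lag in samples: (sm[n + lag] - sm[n]) / (lag x dt).
#'   The raw rule uses adjacent samples (lag 1); the controller differences
#'   across 2 minutes (lag 4) to keep the sign noise-robust.
#' @param causal use a trailing window (as the online controller does)
#'   instead of a centered one.
#' @param dt_min sampling interval in minutes when `series` is a bare vector.
#' @return Signed rate(s), mg O2/L/min per minute.
#' @export
d_our_dt <- function(series, n = NULL, smooth_w = 1, lag = 1, causal = FALSE,
                     dt_min = NULL) {
  if (inherits(series, "our_series")) {
    x <- series$our
    dt_min <- attr(series, "dt_min")
  } else {
    x <- as.numeric(series)
    if (is.null(dt_min)) stop("dt_min required for a bare numeric series")
  }
  if (lag < 1) stop("lag must be at least 1 sample")
  sm <- our_smooth(x, smooth_w, causal = causal)
  m <- length(sm)
  if (m <= lag) stop("series shorter than the difference lag")
  d <- (sm[(1 + lag):m] - sm[1:(m - lag)]) / (lag * dt_min)
  if (is.null(n)) return(d)
  if (any(n < 1L | n + lag > m)) stop("index out of range")
  d[n]
}

#' Detect the end of the feast phase from the OUR signal
#'
#' The feast ends when, after the substrate budget is exhausted, the OUR
#' falls back to the endogenous baseline: the first time at which
#' OUR <= baseline * (1 + tol) + tol_abs holds for `k` consecutive samples.
#' The absolute floor `tol_abs` keeps detection meaningful when the
#' estimated baseline is zero.
#'
#' @param series an [our_series()].
#' @param baseline endogenous OUR level, mg O2/L/min (estimated from a
#'   pre-feed window).
#' @param tol relative tolerance above baseline.
#' @param k number of consecutive samples required.
#' @param after_min only consider samples at or after this time (e.g. the
#'   budget-exhaustion time).
#' @param tol_abs absolute tolerance floor, mg O2/L/min.
#' @return Detected feast-end time in minutes. If the condition is never
#'   met, the last timestamp is returned with a warning.
#' @export
detect_feast_end <- function(series, baseline, tol = 0.1, k = 4,
                             after_min = 0, tol_abs = 0.02) {
  stopifnot(inherits(series, "our_series"))
  if (baseline < 0) stop("baseline must be non-negative")
  thresh <- baseline * (1 + tol) + tol_abs
  ok <- series$our <= thresh & series$t_min >= after_min
  n <- length(ok)
  if (n >= k) {
    runs <- ok
    for (j in seq_len(k - 1)) runs <- runs & c(ok[-seq_len(j)], rep(FALSE, j))
    hit <- which(runs)
    if (length(hit)) return(series$t_min[hit[1]])
  }
  warning("OUR never returned to baseline; returning end of series")
  series$t_min[n]
}
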