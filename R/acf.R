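#' Windowed normalized autocorrelation function
#'
#' Computes the normalized autocorrelation of a scalar property over the
#' window `[0, t]` spanned by the series:
#' \deqn{C(\Delta, t) = C'(\Delta, t) / C'(0, t), \qquad
#'       C'(\Delta, t) = \frac{1}{n_\Delta} \sum \delta R(t') \,
#'       \delta R(t' + \Delta)}
#' where \eqn{\delta R = R - \langle R \rangle} is taken about the mean of
#' the window itself, and the sum runs over the \eqn{n_\Delta} admissible
#' sample pairs at lag \eqn{\Delta} (the unbiased `n - k` denominator, the
#' discrete analogue of the `1/(t - \Delta)` prefactor of the continuous
#' definition).
#'
#' The default estimator uses an FFT with explicit pair-count correction;
#' `method = "direct"` is the O(n k) sum kept as an independent
#' cross-check (the two agree to ~1e-10 and are tested to do so).
#'
#' @param series A [property_series()].
#' @param max_lag Largest lag in ps. Defaults to half the window span,
#'   which is also the hard cap.
#' @param method `"fft"` (default) or `"direct"`.
#'
#' @return An object of class `acf_curve`: list with `lags` (ps), `values`
#'   (dimensionless, `values[1] == 1`), `window` (span in ps) and `dt`.
#' @examples
#' s <- ou_process(tau = 50, sigma = 1, dt = 1, n = 5000, seed = 1)
#' a <- normalized_acf(s, max_lag = 200)
#' plot(a$lags, a$values, type = "l")
#' @export
normalized_acf <- function(series, max_lag = NULL,
                           method = c("fft", "direct")) {
  stopifnot(inherits(series, "property_series"))
  method <- match.arg(method)
  n <- length(series$values)
  dt <- series$dt
  span <- (n - 1) * dt
  cap <- 0.5 * span
  if (is.null(max_lag)) max_lag <- cap
  if (max_lag > cap + 1e-9 * cap) {
    stop("max_lag exceeds half the window span (", signif(cap, 6), " ps)",
         call. = FALSE)
  }
  k_max <- floor(max_lag / dt + 1e-9)
  x <- series$values - mean(series$values)
  if (sum(x^2) == 0) {
    stop("degenerate signal: zero variance over the window; ",
         "autocorrelation undefined", call. = FALSE)
  }
  if (method == "fft") {
    sums <- acf_lag_sums_fft(x, k_max)
  } else {
    sums <- acf_lag_sums_direct(x, k_max)
  }
  cp <- sums / (n - 0:k_max)   # unbiased per-lag pair count
  structure(
    list(lags = dt * (0:k_max), values = cp / cp[1], window = span, dt = dt),
    class = "acf_curve"
  )
}

# raw lag sums  S_k = sum_i x_i x_{i+k}  for k = 0..k_max, via zero-padded FFT
acf_lag_sums_fft <- function(x, k_max) {
  n <- length(x)
  np <- stats::nextn(2L * n, 2)
  f <- stats::fft(c(x, rep(0, np - n)))
  s <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / np
  s[seq_len(k_max + 1L)]
}

# direct O(n k) sum; independent oracle for the FFT path
acf_lag_sums_direct <- function(x, k_max) {
  n <- length(x)
  vapply(0:k_max, function(k) {
    sum(x[seq_len(n - k)] * x[seq_len(n - k) + k])
  }, numeric(1))
}

#' @export
print.acf_curve <- function(x, ...) {
  cat(sprintf("<acf_curve> window %g ps, %d lags up to %g ps\n",
              x$window, length(x$lags), x$lags[length(x$lags)]))
  invisible(x)
}

#' Characteristic decorrelation time of an ACF
#'
#' Extracts the characteristic decorrelation time \eqn{\tau_c} as the
#' smallest lag at which the normalized ACF has decayed to `1/e`, with
#' linear interpolation between the bracketing lags. If the curve never
#' reaches `1/e` within the computed lags, \eqn{\tau_c} is reported as the
#' largest lag with `crossing_found = FALSE`. An alternative definition,
#' the integral of the ACF up to its first zero crossing, is available via
#' `method = "integrated"`.
#'
#' @param acf An [normalized_acf()] result.
#' @param threshold Decay level defining \eqn{\tau_c} (default `1/e`).
#' @param method `"crossing"` (default) or `"integrated"`.
#' @return List with `tau_c` (ps) and `crossing_found` (logical).
#' @export
decorrelation_time <- function(acf, threshold = exp(-1),
                               method = c("crossing", "integrated")) {
  stopifnot(inherits(acf, "acf_curve"))
  method <- match.arg(method)
  v <- acf$values
  lags <- acf$lags
  if (method == "integrated") {
    nz <- which(v <= 0)
    stop_at <- if (length(nz)) nz[1] else length(v)
    tau <- sum(v[seq_len(stop_at)]) * acf$dt
    return(list(tau_c = max(tau, acf$dt), crossing_found = length(nz) > 0))
  }
  below <- which(v <= threshold)
  if (!length(below)) {
    return(list(tau_c = lags[length(lags)], crossing_found = FALSE))
  }
  k <- below[1]
  if (k == 1L) return(list(tau_c = 0, crossing_found = TRUE))
  frac <- (v[k - 1] - threshold) / (v[k - 1] - v[k])
  list(tau_c = lags[k - 1] + frac * (lags[k] - lags[k - 1]),
       crossing_found = TRUE)
}

#' Decorrelation curve over trajectory prefixes
#'
#' The central convergence diagnostic: \eqn{\tau_c} recomputed on growing
#' prefixes `[0, t]` of the trajectory and plotted against t (log-log).
#' While the trajectory still discovers new slow motions, \eqn{\tau_c}
#' grows with t (sub-diffusively, roughly a power law); once all motions
#' contributing to the property are sampled, the curve plateaus.
#'
#' @param series A [property_series()].
#' @param prefixes Optional vector of prefix spans in ps. Defaults to a
#'   log-spaced grid with `points_per_decade` points per decade from
#'   `100 * dt` to the full span (the full span is always included).
#' @param points_per_decade Density of the default grid (default 10).
#' @param min_prefix Smallest allowed prefix, in samples (default 10).
#' @param ... Passed to [normalized_acf()] / [decorrelation_time()].
#'
#' @return An object of class `decorrelation_curve`: data frame with
#'   columns `t_ps`, `tau_c_ps`, `crossing_found`.
#' @export
decorrelation_curve <- function(series, prefixes = NULL,
                                points_per_decade = 10, min_prefix = 10,
                                ...) {
  stopifnot(inherits(series, "property_series"))
  n <- length(series$values)
  dt <- series$dt
  span <- (n - 1) * dt
  if (is.null(prefixes)) {
    lo <- max(100 * dt, min_prefix * dt)
    if (lo >= span) stop("series too short for a prefix grid", call. = FALSE)
    lg <- seq(log10(lo), log10(span), by = 1 / points_per_decade)
    prefixes <- unique(c(10^lg, span))
  } else {
    prefixes <- sort(unique(as.numeric(prefixes)))
    if (any(diff(prefixes) <= 0)) stop("prefixes must be increasing")
    if (any(prefixes > span + 1e-9 * span)) {
      stop("prefix exceeds the series span (", signif(span, 6), " ps)",
           call. = FALSE)
    }
    if (any(prefixes < min_prefix * dt)) {
      stop("prefixes must span at least ", min_prefix, " samples",
           call. = FALSE)
    }
  }
  # snap to the sample grid and drop duplicates
  ns <- unique(pmin(n, 1L + floor(prefixes / dt + 1e-9)))
  ns <- ns[ns >= min_prefix]
  rows <- lapply(ns, function(m) {
    sub <- property_series(series$values[seq_len(m)], dt = dt,
                           label = series$label)
    ac <- normalized_acf(sub, ...)
    dc <- decorrelation_time(ac)
    data.frame(t_ps = (m - 1) * dt, tau_c_ps = dc$tau_c,
               crossing_found = dc$crossing_found)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("decorrelation_curve", "data.frame")
  attr(out, "label") <- series$label
  out
}

#' Plateau onset (convergence time) of a decorrelation curve
#'
#' Detects the time at which a decorrelation curve reaches a clear, flat
#' plateau. The onset `t_conv` is the earliest prefix length satisfying
#' both conditions: (i) every \eqn{\tau_c} from there to the end of the
#' curve stays within `band` (relative) of the final \eqn{\tau_c}, and
#' (ii) the curve is locally flat at entry, i.e. the change from the
#' previous grid point is itself within `band` (a band can be entered on a
#' jump, which is not a plateau; `require_flat = FALSE` disables this and
#' reverts to pure band entry). The curve is declared `converged` only when
#' the plateau additionally spans at least `min_tail` of the log-time axis
#' — a short terminal flat stretch is reported but not trusted.
#'
#' @param dc A [decorrelation_curve()].
#' @param band Relative half-width of the plateau band (default 0.10).
#' @param min_tail Minimum plateau extent as a fraction of the log10 time
#'   axis (default 0.25).
#' @param require_flat Require local flatness at plateau entry
#'   (default TRUE).
#' @return List with `t_conv` (ps), `converged` (logical), `tau_final` (ps)
#'   and `plateau_frac` (plateau extent as a fraction of the log axis).
#' @export
dc_convergence_time <- function(dc, band = 0.10, min_tail = 0.25,
                                require_flat = TRUE) {
  stopifnot(inherits(dc, "decorrelation_curve"))
  if (nrow(dc) < 10) stop("decorrelation curve needs >= 10 points",
                          call. = FALSE)
  tau <- dc$tau_c_ps
  tt <- dc$t_ps
  nf <- length(tau)
  tau_final <- tau[nf]
  in_band <- abs(tau - tau_final) <= band * tau_final
  entry <- nf
  for (i in nf:1) {
    if (in_band[i]) entry <- i else break
  }
  onset <- entry
  if (require_flat && entry > 1) {
    onset <- NA_integer_
    for (i in entry:nf) {
      if (abs(tau[i] - tau[i - 1]) <= band * tau[i - 1]) {
        onset <- i
        break
      }
    }
    if (is.na(onset)) onset <- nf
  }
  t_conv <- tt[onset]
  lspan <- log10(tt[nf]) - log10(tt[1])
  plateau_frac <- if (lspan > 0) (log10(tt[nf]) - log10(t_conv)) / lspan else 1
  converged <- plateau_frac >= min_tail && onset < nf
  list(t_conv = t_conv, converged = converged, tau_final = tau_final,
       plateau_frac = plateau_frac)
}

#' Power-law fit to a decorrelation curve
#'
#' Least-squares fit of `log10(tau_c)` versus `log10(t)` over a time range,
#' giving the exponent of the self-similar (sub-diffusive) regime
#' \eqn{\tau_c \sim t^{\alpha}} that precedes a plateau. Reference protein
#' data place the pre-plateau exponent near 0.9.
#'
#' @param dc A [decorrelation_curve()].
#' @param fit_range Length-2 numeric, time interval in ps (default: whole
#'   curve).
#' @return List with `exponent`, `prefactor` (so that
#'   `tau_c = prefactor * t^exponent`), and `n_points`.
#' @export
fit_power_law <- function(dc, fit_range = NULL) {
  stopifnot(inherits(dc, "decorrelation_curve"))
  if (is.null(fit_range)) fit_range <- range(dc$t_ps)
  stopifnot(length(fit_range) == 2, fit_range[1] < fit_range[2])
  sel <- dc$t_ps >= fit_range[1] & dc$t_ps <= fit_range[2]
  if (sum(sel) < 5) stop("fewer than 5 points in the fit range",
                         call. = FALSE)
  if (any(dc$tau_c_ps[sel] <= 0)) stop("non-positive tau_c in fit range",
                                       call. = FALSE)
  fit <- stats::lm(log10(dc$tau_c_ps[sel]) ~ log10(dc$t_ps[sel]))
  cf <- stats::coef(fit)
  list(exponent = unname(cf[2]), prefactor = 10^unname(cf[1]),
       n_points = sum(sel))
}

#' Convergence-time estimate from an oscillation period
#'
#' For a property dominated by an oscillation of period T, the
#' decorrelation curve plateaus after roughly one and a half periods; this
#' helper applies that rule of thumb.
#'
#' @param period Oscillation period (any time unit).
#' @return `1.5 * period`, same unit.
#' @examples
#' period_convergence_estimate(63000)  # ~ 94,500 ps
#' @export
period_convergence_estimate <- function(period) {
  stopifnot(is.numeric(period), all(period > 0))
  1.5 * period
}

#' Effective oscillation period from a combined transition rate
#'
#' A combined forward-plus-backward transition rate of r events per unit
#' time corresponds to a full cycle (one forward and one backward event)
#' every `2 / r`: the effective period of the slow inter-region
#' "oscillation" that the rate describes.
#'
#' @param combined_rate Combined two-way transition rate (events per ns).
#' @return Period in ns.
#' @examples
#' rate_to_period(1 / 9.9)  # 19.8 ns
#' @export
rate_to_period <- function(combined_rate) {
  stopifnot(is.numeric(combined_rate))
  if (any(combined_rate <= 0)) stop("rate must be positive", call. = FALSE)
  2 / combined_rate
}
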