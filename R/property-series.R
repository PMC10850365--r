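#' Uniformly sampled scalar property time series
#'
#' Container for a scalar observable extracted from a trajectory (a distance,
#' a dihedral angle, an energy, ...) sampled on a uniform time grid in
#' picoseconds. All autocorrelation and convergence diagnostics in the
#' package operate on this class.
#'
#' @param values Numeric vector of observable values.
#' @param dt Sampling interval in ps. Ignored if `times` is given.
#' @param times Optional explicit time axis in ps; must be strictly
#'   increasing and uniformly spaced (relative tolerance `1e-6`).
#' @param t0 Time of the first sample in ps (default 0).
#' @param label Short description of the observable (used in plots and CSV
#'   headers).
#'
#' @return An object of class `property_series` with fields `times`,
#'   `values`, `dt` and `label`.
#' @examples
#' s <- property_series(sin(0.01 * seq(0, 1000, by = 1)), dt = 1)
#' s
#' @export
property_series <- function(values, dt = NULL, times = NULL, t0 = 0,
                            label = "property") {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("a property series needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("property values must all be finite", call. = FALSE)
  }
  if (is.null(times)) {
    if (is.null(dt) || dt <= 0) {
      stop("either `times` or a positive `dt` must be supplied",
           call. = FALSE)
    }
    times <- t0 + dt * (seq_along(values) - 1)
  } else {
    times <- as.numeric(times)
    if (length(times) != length(values)) {
      stop("`times` and `values` differ in length", call. = FALSE)
    }
    steps <- diff(times)
    if (any(steps <= 0)) {
      stop("time axis must be strictly increasing (first violation at row ",
           which(steps <= 0)[1] + 1, ")", call. = FALSE)
    }
    dt <- steps[1]
    if (any(abs(steps - dt) > 1e-6 * dt)) {
      stop("time axis is not uniform (first violation at row ",
           which(abs(steps - dt) > 1e-6 * dt)[1] + 1, ")", call. = FALSE)
    }
  }
  structure(
    list(times = times, values = values, dt = dt, label = as.character(label)),
    class = "property_series"
  )
}

#' @export
print.property_series <- function(x, ...) {
  cat(sprintf(
    "<property_series> '%s': %d samples, dt = %g ps, span = %g ps\n",
    x$label, length(x$values), x$dt, x$times[length(x$times)] - x$times[1]
  ))
  invisible(x)
}

#' @export
length.property_series <- function(x) length(x$values)

#' @export
as.data.frame.property_series <- function(x, ...) {
  data.frame(time_ps = x$times, value = x$values)
}

#' Extract a trajectory prefix
#'
#' Returns the sub-series covering the first `t` picoseconds (measured from
#' the first sample). Used internally by all prefix-convergence analyses.
#'
#' @param series A [property_series()].
#' @param t Prefix span in ps.
#' @return A `property_series` over `[t0, t0 + t]`.
#' @export
series_prefix <- function(series, t) {
  stopifnot(inherits(series, "property_series"))
  n <- min(length(series$values),
           1L + floor(t / series$dt + 1e-9))
  if (n < 2L) stop("prefix too short: fewer than 2 samples", call. = FALSE)
  property_series(series$values[seq_len(n)], dt = series$dt,
                  t0 = series$times[1], label = series$label)
}

#' Running (cumulative) average of a property
#'
#' The average of the observable between time 0 and t, for every t on the
#' sampling grid. Its stabilisation is the basis of the operational
#' equilibrium verdict: a property is considered equilibrated once this
#' curve stays within a small band of its final value for a significant
#' trailing portion of the trajectory.
#'
#' @param series A [property_series()].
#' @return A `property_series` of running means on the same time grid.
#' @export
running_average <- function(series) {
  stopifnot(inherits(series, "property_series"))
  v <- cumsum(series$values) / seq_along(series$values)
  property_series(v, dt = series$dt, t0 = series$times[1],
                  label = paste0("<", series$label, ">(t)"))
}

#' Operational equilibrium verdict on a property
#'
#' Declares a property "equilibrated" when the fluctuations of its running
#' average about the final average stay below a tolerance for the whole
#' trailing fraction of the trajectory. The convergence time `t_c` is the
#' earliest time from which the condition holds through to the end.
#'
#' @param series A [property_series()].
#' @param fluct_tol Relative tolerance on `|<A>(t) - <A>(T)|`, as a fraction
#'   of the fluctuation scale (default 0.05).
#' @param tail_frac Fraction of the trajectory (by time, counted from the
#'   end) over which the condition must hold (default 0.5).
#' @param scale Fluctuation scale; defaults to the sample standard deviation
#'   of the values. For a zero-variance series an absolute tolerance of
#'   `fluct_tol` is used and recorded in the verdict.
#'
#' @return An object of class `equilibrium_verdict`: list with `converged`,
#'   `t_c` (ps, `NA` when not converged), `final_average`, `fluctuation`
#'   (a `property_series` of `|<A>(t) - <A>(T)|/scale`), and the thresholds
#'   used.
#' @export
equilibrium_verdict <- function(series, fluct_tol = 0.05, tail_frac = 0.5,
                                scale = NULL) {
  stopifnot(inherits(series, "property_series"))
  stopifnot(fluct_tol > 0, tail_frac > 0, tail_frac <= 1)
  ra <- running_average(series)
  final <- ra$values[length(ra$values)]
  scale_fallback <- FALSE
  if (is.null(scale)) {
    scale <- stats::sd(series$values)
    if (!is.finite(scale) || scale == 0) {
      scale <- 1
      scale_fallback <- TRUE
    }
  }
  dev <- abs(ra$values - final) / scale
  n <- length(dev)
  tail_start <- series$times[1] +
    (1 - tail_frac) * (series$times[n] - series$times[1])
  in_tail <- series$times >= tail_start
  converged <- all(dev[in_tail] <= fluct_tol)
  t_c <- NA_real_
  if (converged) {
    ok <- dev <= fluct_tol
    # earliest index from which the band holds through to T
    idx <- n
    for (i in n:1) {
      if (ok[i]) idx <- i else break
    }
    t_c <- series$times[idx]
  }
  structure(
    list(
      converged = converged,
      t_c = t_c,
      final_average = final,
      fluctuation = property_series(dev, dt = series$dt,
                                    t0 = series$times[1],
                                    label = paste0("|<A>(t) - <A>(T)| / scale")),
      fluct_tol = fluct_tol,
      tail_frac = tail_frac,
      scale = scale,
      absolute_scale_fallback = scale_fallback
    ),
    class = "equilibrium_verdict"
  )
}

#' @export
print.equilibrium_verdict <- function(x, ...) {
  cat("<equilibrium_verdict>\n")
  cat(sprintf("  converged: %s\n", x$converged))
  if (x$converged) cat(sprintf("  t_c: %g ps\n", x$t_c))
  cat(sprintf("  final average: %g\n", x$final_average))
  cat(sprintf("  tolerance: %g x scale (%g), tail fraction %g\n",
              x$fluct_tol, x$scale, x$tail_frac))
  invisible(x)
}
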