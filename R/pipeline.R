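#' Run configuration for the analysis pipeline
#'
#' Declarative description of one diagnostic run: the input series, which
#' stages to execute, and every threshold the stages use. The resolved
#' configuration (defaults filled in, seed included) is written beside the
#' outputs of every run, so results are reproducible from the output
#' directory alone.
#'
#' @param input Path to a series CSV (see [read_series_csv()]), or a
#'   [property_series()] directly.
#' @param stages Character vector among `"acf"`, `"dc"`, `"verdict"`
#'   (default all three).
#' @param max_lag ACF lag cap in ps (default: half the series span).
#' @param band,min_tail Plateau parameters for [dc_convergence_time()].
#' @param fluct_tol,tail_frac Verdict parameters for
#'   [equilibrium_verdict()].
#' @param seed Integer seed recorded with the run (stochastic stages only).
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input, stages = c("acf", "dc", "verdict"),
                       max_lag = NULL, band = 0.10, min_tail = 0.25,
                       fluct_tol = 0.05, tail_frac = 0.5, seed = 1,
                       out_dir = tempfile("mdequil_run_")) {
  stages <- match.arg(stages, c("acf", "dc", "verdict"), several.ok = TRUE)
  if (is.character(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  structure(
    list(input = input, stages = stages, max_lag = max_lag, band = band,
         min_tail = min_tail, fluct_tol = fluct_tol,
         tail_frac = tail_frac, seed = seed, out_dir = out_dir),
    class = "run_config"
  )
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (inherits(out$input, "property_series")) {
    out$input <- sprintf("<in-memory series '%s', %d samples>",
                         out$input$label, length(out$input$values))
  }
  out
}

#' Execute the diagnostic pipeline
#'
#' Runs the requested stages in dependency order on one property series,
#' writing per-stage CSVs, a machine-readable `summary.json` (per-metric
#' verdicts with convergence times, package version, seed and resolved
#' configuration) and, when `figures = TRUE`, log-log decorrelation and
#' running-average figures. A stage failure halts the run naming the
#' stage; outputs of completed stages are retained.
#'
#' @param config A [run_config()].
#' @param figures Write PNG figures (default TRUE).
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config, figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  series <- if (inherits(config$input, "property_series")) {
    config$input
  } else {
    read_series_csv(config$input)
  }
  summary <- list(
    package = "mdequil",
    version = as.character(utils::packageVersion("mdequil")),
    seed = config$seed,
    config = config_as_list(config),
    series = list(label = series$label, n = length(series$values),
                  dt_ps = series$dt)
  )
  jsonlite::write_json(summary$config,
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage <- "none"
  tryCatch({
    if ("acf" %in% config$stages) {
      stage <- "acf"
      ac <- normalized_acf(series, max_lag = config$max_lag)
      utils::write.csv(data.frame(lag_ps = ac$lags, acf = ac$values),
                       file.path(config$out_dir, "acf.csv"),
                       row.names = FALSE)
      dct <- decorrelation_time(ac)
      summary$acf <- list(tau_c_ps = dct$tau_c,
                          crossing_found = dct$crossing_found,
                          window_ps = ac$window)
    }
    if ("dc" %in% config$stages) {
      stage <- "dc"
      dc <- decorrelation_curve(series)
      write_dc_csv(dc, file.path(config$out_dir, "dc.csv"))
      conv <- dc_convergence_time(dc, band = config$band,
                                  min_tail = config$min_tail)
      summary$dc <- list(t_conv_ps = conv$t_conv,
                         converged = conv$converged,
                         tau_final_ps = conv$tau_final,
                         plateau_frac = conv$plateau_frac)
      if (figures) plot_dc(dc, conv,
                           file.path(config$out_dir, "dc.png"))
    }
    if ("verdict" %in% config$stages) {
      stage <- "verdict"
      v <- equilibrium_verdict(series, fluct_tol = config$fluct_tol,
                               tail_frac = config$tail_frac)
      summary$verdict <- list(converged = v$converged, t_c_ps = v$t_c,
                              final_average = v$final_average,
                              fluct_tol = v$fluct_tol,
                              tail_frac = v$tail_frac)
      if (figures) plot_running_average(series,
                                        file.path(config$out_dir,
                                                  "running_average.png"))
    }
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(summary)
}

#' Log-log decorrelation-curve figure
#'
#' @param dc A [decorrelation_curve()].
#' @param conv Optional [dc_convergence_time()] result; marks the plateau
#'   onset.
#' @param path Output file (PNG); `NULL` returns the ggplot object.
#' @return The ggplot object, invisibly.
#' @export
plot_dc <- function(dc, conv = NULL, path = NULL) {
  df <- as.data.frame(dc)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = t_ps,
                                        y = tau_c_ps)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "observation time t (ps)",
                  y = expression(tau[c] ~ "(ps)"),
                  title = attr(dc, "label")) +
    ggplot2::theme_minimal()
  if (!is.null(conv)) {
    p <- p + ggplot2::geom_vline(xintercept = conv$t_conv,
                                 linetype = "dashed")
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
  }
  invisible(p)
}

#' Running-average figure with final-value band
#'
#' @param series A [property_series()].
#' @param path Output file (PNG); `NULL` returns the ggplot object.
#' @return The ggplot object, invisibly.
#' @export
plot_running_average <- function(series, path = NULL) {
  ra <- running_average(series)
  df <- as.data.frame(ra)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = time_ps,
                                        y = value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = df$value[nrow(df)],
                        linetype = "dashed") +
    ggplot2::labs(x = "t (ps)", y = "running average",
                  title = series$label) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
  }
  invisible(p)
}

#' Free-energy landscape figure
#'
#' @param surface A [pmf()] result (1D profile or 2D heat map).
#' @param path Output file (PNG); `NULL` returns the ggplot object.
#' @return The ggplot object, invisibly.
#' @export
plot_fes <- function(surface, path = NULL) {
  stopifnot(inherits(surface, "free_energy_surface"))
  if (is.matrix(surface$F)) {
    ex <- surface$edges[[1]]
    ey <- surface$edges[[2]]
    df <- expand.grid(x = (ex[-1] + ex[-length(ex)]) / 2,
                      y = (ey[-1] + ey[-length(ey)]) / 2)
    df$F <- as.numeric(surface$F)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                          fill = F)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "white",
                                    name = "F (kcal/mol)") +
      ggplot2::labs(x = "psi (deg)", y = "phi (deg)") +
      ggplot2::theme_minimal()
  } else {
    ex <- surface$edges[[1]]
    df <- data.frame(x = (ex[-1] + ex[-length(ex)]) / 2, F = surface$F)
    p <- ggplot2::ggplot(df, ggplot2::aes(x = x, y = F)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "angle (deg)", y = "F (kcal/mol)") +
      ggplot2::theme_minimal()
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
  }
  invisible(p)
}

#' Regenerate the analytic decorrelation study end-to-end
#'
#' Generates the six reference analytic signals
#' ([analytic_suite_params()]) on a uniform grid, computes every
#' decorrelation curve and plateau onset, and tabulates the results
#' against the closed-form expectations: each pure sine of period T should
#' plateau near `1.5 * T` (checked via [period_convergence_estimate()]),
#' and the composite signal should converge only when its slowest
#' component does. Deterministic: rerunning with the same arguments
#' reproduces the table bit for bit.
#'
#' @param out_dir Output directory for CSVs and figures (`NULL`: no files
#'   written).
#' @param dt Sampling interval in ps (default 5).
#' @param t_max Signal span in ps (default 3e5).
#' @param figures Write per-system DC figures (default `!is.null(out_dir)`).
#' @return Data frame with one row per system: plateau onset `t_conv_ps`,
#'   its log10, the `converged` flag, final `tau_c`, and for pure sines
#'   the period and the 1.5-period estimate.
#' @export
demo_analytic_suite <- function(out_dir = NULL, dt = 5, t_max = 3e5,
                                figures = !is.null(out_dir)) {
  params <- analytic_suite_params()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  grid <- seq(0, t_max, by = dt)
  rows <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    s <- composite_function(p, grid)
    s$label <- nm
    dc <- decorrelation_curve(s)
    conv <- dc_convergence_time(dc)
    freqs <- c(p$C, p$D, p$E)
    period <- if (sum(freqs > 0) >= 1) 2 * pi / min(freqs[freqs > 0]) else
      NA_real_
    if (!is.null(out_dir)) {
      write_dc_csv(dc, file.path(out_dir, paste0("dc_", nm, ".csv")))
      if (figures) {
        plot_dc(dc, conv, file.path(out_dir, paste0("dc_", nm, ".png")))
      }
    }
    data.frame(
      system = nm,
      t_conv_ps = conv$t_conv,
      log10_t_conv = log10(conv$t_conv),
      converged = conv$converged,
      tau_final_ps = conv$tau_final,
      slowest_period_ps = period,
      period_rule_ps = ifelse(is.na(period), NA_real_,
                              period_convergence_estimate(period))
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "analytic_suite.csv"),
                     row.names = FALSE)
  }
  out
}
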