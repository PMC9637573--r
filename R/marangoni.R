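#' Thermal Marangoni number
#'
#' Dimensionless group comparing thermocapillary driving with viscous
#' and thermal dissipation:
#' \deqn{Ma = -\frac{d\sigma}{dT}\,\frac{R\,\Delta T}{\eta\,\alpha}}
#' where \eqn{d\sigma/dT} is the surface-tension temperature derivative
#' (mean of the triple-line and centre values), `R` the drop radius,
#' \eqn{\Delta T = T_{TPCL} - T_{center}}, \eqn{\eta} the dynamic
#' viscosity and \eqn{\alpha} the thermal diffusivity. The
#' surface-tension derivative is supplied in mN/(m.°C) and converted to
#' N/(m.°C) internally.
#'
#' @param dsigma_dT_mean Mean surface-tension derivative, mN/(m.°C).
#' @param R Drop radius, m.
#' @param dT Edge-centre temperature difference, °C.
#' @param eta Dynamic viscosity, Pa.s.
#' @param alpha Thermal diffusivity (consistent with `eta`, see
#'   [thermal_diffusivity()]).
#' @return Dimensionless Marangoni number. Vectorised over `dT` and
#'   `dsigma_dT_mean`.
#' @export
marangoni_number <- function(dsigma_dT_mean, R, dT, eta, alpha) {
  if (any(eta <= 0) || any(alpha <= 0) || any(R <= 0)) {
    abort("eta, alpha and R must be positive.")
  }
  -(dsigma_dT_mean * 1e-3) * R * dT / (eta * alpha)
}

#' Marangoni number trajectory from an edge-centre series
#'
#' Turns thermography output into a Marangoni trajectory: per time
#' point, the surface-tension derivative is averaged at the measured
#' TPCL and centre temperatures, viscosity is blood viscosity at the
#' film-mean temperature, and the Marangoni number follows from
#' [marangoni_number()]. The full per-time input trace is retained for
#' audit.
#'
#' @param thermal An `edge_center_series` (from [edge_center_series()]).
#' @param R Drop radius, m (constant over the series under CCR mode).
#' @param props A [blood_properties()] object whose `sigma_fit` is set.
#' @param alpha_mode `"si"` (true m^2/s, default) or `"paper_numeric"`
#'   (density plugged in as its g/ml numeral).
#' @return A tibble of class `marangoni_traj` with columns
#'   `t_s, Ma, dsigma_dT_mN, eta_Pas, dT_C`; attributes `R_m`, `alpha`.
#' @export
marangoni_series <- function(thermal, R, props,
                             alpha_mode = c("si", "paper_numeric")) {
  alpha_mode <- match.arg(alpha_mode)
  stopifnot(inherits(props, "blood_properties"))
  if (is.null(props$sigma_fit)) abort("`props$sigma_fit` is required (fit_surface_tension).")
  if (nrow(thermal) == 0) abort("Empty edge-centre series.")
  alpha <- thermal_diffusivity(props$lambda, props$rho, props$cp, mode = alpha_mode)
  dsig <- dsigma_dT(props$sigma_fit, thermal$T_tpcl, thermal$T_center)
  eta <- blood_viscosity((thermal$T_tpcl + thermal$T_center) / 2, props$ht)
  Ma <- marangoni_number(dsig, R, thermal$dT, eta, alpha)
  out <- tibble(t_s = thermal$t_s, Ma = Ma,
                dsigma_dT_mN = dsig, eta_Pas = eta, dT_C = thermal$dT)
  attr(out, "R_m") <- R
  attr(out, "alpha") <- alpha
  attr(out, "alpha_mode") <- alpha_mode
  class(out) <- c("marangoni_traj", class(out))
  out
}

# Continuous two-segment piecewise-linear SSE with break at ts
two_segment_sse <- function(t, y, ts) {
  X <- cbind(1, t, pmax(t - ts, 0))
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Breakpoint of a two-rate Marangoni trajectory
#'
#' Fits a continuous two-segment piecewise-linear model with the break
#' at each candidate sample time and returns the SSE-minimising break.
#' When the best two-segment fit improves on a single straight line by
#' less than `min_improve` (fractional SSE), the trajectory is flagged
#' as having no breakpoint and `NA` is returned.
#'
#' @param traj A `marangoni_traj` (or any data frame with `t_s`, `Ma`).
#' @param min_improve Minimum fractional SSE improvement over the
#'   single-line fit (default 0.01).
#' @return Breakpoint time in seconds, or `NA_real_` (no breakpoint).
#'   The attribute `"sse_improvement"` carries the fractional gain.
#' @export
detect_breakpoint <- function(traj, min_improve = 0.01) {
  t <- traj$t_s
  y <- traj$Ma
  n <- length(t)
  if (n < 8) abort("Need at least 8 points.")
  if (sd(y) == 0) {
    out <- NA_real_
    attr(out, "sse_improvement") <- 0
    return(out)
  }
  fit1 <- lm.fit(cbind(1, t), y)
  sse1 <- sum(fit1$residuals^2)
  if (sse1 / sum((y - mean(y))^2) < 1e-12) {
    # already an exact straight line
    out <- NA_real_
    attr(out, "sse_improvement") <- 0
    return(out)
  }
  cand <- t[3:(n - 2)]
  sse2 <- vapply(cand, function(ts) two_segment_sse(t, y, ts), numeric(1))
  best <- which.min(sse2)
  improve <- if (sse1 > 0) (sse1 - sse2[best]) / sse1 else 0
  out <- if (improve < min_improve) NA_real_ else cand[best]
  attr(out, "sse_improvement") <- improve
  out
}

#' Early and late Marangoni growth rates
#'
#' Splits the trajectory at the breakpoint `ts` and reports the mean
#' growth rate before the break, `(Ma(ts) - Ma(t0)) / (ts - t0)`, and
#' the rate over a `window`-second stretch after it,
#' `(Ma(ts + window) - Ma(ts)) / window` — the construction behind the
#' reported "units per second" rates. Ma is interpolated linearly at
#' the evaluation times.
#'
#' @param traj A `marangoni_traj`.
#' @param ts Breakpoint, s, strictly inside the time span.
#' @param window Late-rate window, s (default 100).
#' @return A `rate_analysis` object: `ts`, `early_rate`, `late_rate`
#'   (Ma units/s), `ratio` (late/early).
#' @export
two_segment_rates <- function(traj, ts, window = 100) {
  t <- traj$t_s
  y <- traj$Ma
  if (ts <= min(t) || ts >= max(t)) abort("`ts` must lie strictly inside the span.")
  if (ts + window > max(t)) abort("Late-rate window exceeds the series span.")
  ma_at <- function(tt) approx(t, y, xout = tt)$y
  early <- (ma_at(ts) - y[1]) / (ts - t[1])
  late <- (ma_at(ts + window) - ma_at(ts)) / window
  structure(
    list(ts = ts, early_rate = early, late_rate = late,
         ratio = if (early > 0) late / early else NA_real_,
         window = window),
    class = "rate_analysis"
  )
}

#' @export
print.rate_analysis <- function(x, ...) {
  cat(sprintf("<rate_analysis> break at %g s: early %.4g /s, late %.4g /s (window %g s), ratio %.4g\n",
              x$ts, x$early_rate, x$late_rate, x$window, x$ratio))
  invisible(x)
}

#' @rdname two_segment_rates
#' @param x A `rate_analysis`.
#' @param ... Unused.
#' @export
tidy.rate_analysis <- function(x, ...) {
  tibble(ts_s = x$ts, early_rate = x$early_rate, late_rate = x$late_rate,
         ratio = x$ratio, window_s = x$window)
}

#' Classify the evaporation regime of a drop
#'
#' Three-way refinement of the two observed categories: `capillary`
#' (no dome, Marangoni number without significant two-rate structure —
#' unheated behaviour), `marangoni_delayed` (dome forming after more
#' than 10% of the lifetime — moderate heating) and
#' `marangoni_immediate` (dome from the start — strong heating).
#' Mapping back to two classes: category 1 = `capillary`, category 2 =
#' both `marangoni` labels.
#'
#' A detected breakpoint only counts against the capillary label when
#' its late/early rate ratio reaches `ratio_min`, so that noise-chasing
#' breaks on a slowly, linearly growing trajectory do not reclassify an
#' unheated drop.
#'
#' @param geom A `droplet_series`.
#' @param traj A `marangoni_traj` for the same drop.
#' @param onset_frac Dome-onset fraction of lifetime separating delayed
#'   from immediate (default 0.1).
#' @param ratio_min Minimum late/early rate ratio for a breakpoint to be
#'   regime-defining (default 3).
#' @return One of `"capillary"`, `"marangoni_delayed"`,
#'   `"marangoni_immediate"`.
#' @export
classify_regime <- function(geom, traj, onset_frac = 0.1, ratio_min = 3) {
  lifetime <- max(geom$t_s)
  onset <- detect_dome_formation(geom)
  if (!is.na(onset)) {
    return(if (onset > onset_frac * lifetime) "marangoni_delayed" else "marangoni_immediate")
  }
  ts <- detect_breakpoint(traj)
  if (!is.na(ts) && ts + 1 < max(traj$t_s)) {
    window <- min(100, max(traj$t_s) - ts)
    rates <- tryCatch(two_segment_rates(traj, ts, window = window),
                      error = function(e) NULL)
    if (!is.null(rates) && is.finite(rates$ratio) && rates$ratio >= ratio_min) {
      return("marangoni_delayed")
    }
  }
  "capillary"
}

#' Write a Marangoni trajectory and rate report
#'
#' Trajectory as CSV (`t_s,Ma`), the rate analysis and input trace as a
#' JSON audit file.
#'
#' @param traj A `marangoni_traj`.
#' @param rates A `rate_analysis` (optional).
#' @param dir Output directory.
#' @export
write_marangoni_report <- function(traj, rates = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(traj[, c("t_s", "Ma")], file.path(dir, "marangoni.csv"),
            row.names = FALSE, quote = FALSE)
  audit <- list(R_m = attr(traj, "R_m"), alpha = attr(traj, "alpha"),
                alpha_mode = attr(traj, "alpha_mode"),
                trace = as.data.frame(traj))
  if (!is.null(rates)) audit$rates <- unclass(rates)
  jsonlite::write_json(audit, file.path(dir, "marangoni_audit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
autoplot.marangoni_traj <- function(object, ...) {
  ggplot(object, aes(x = .data$t_s, y = .data$Ma)) +
    geom_line() +
    labs(x = "time (s)", y = "Marangoni number",
         title = "Thermal Marangoni number trajectory") +
    theme_minimal()
}
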