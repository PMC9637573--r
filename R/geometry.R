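#' Droplet evaporation time series
#'
#' Constructs the canonical per-drop trajectory table: time, volume,
#' apex height, left/right contact angles and base diameter. Under
#' constant-contact-radius (CCR) evaporation — the pinned-contact-line
#' regime blood shows on hydrophilic glass — the base diameter stays
#' constant while volume, height and angle shrink.
#'
#' @param t Time, s (strictly increasing).
#' @param V Volume, ul.
#' @param H Apex height, mm.
#' @param theta_l,theta_r Left and right contact angles, degrees.
#' @param D Base diameter, mm.
#' @param Ts Substrate temperature, °C (scalar attribute).
#' @return A tibble of class `droplet_series` with columns
#'   `t_s, V_ul, H_mm, theta_l_deg, theta_r_deg, D_mm` and attribute `Ts`.
#' @export
droplet_series <- function(t, V, H, theta_l, theta_r, D, Ts = NA_real_) {
  if (is.unsorted(t, strictly = TRUE)) abort("`t` must be strictly increasing.")
  out <- tibble(t_s = t, V_ul = V, H_mm = H,
                theta_l_deg = theta_l, theta_r_deg = theta_r, D_mm = D)
  attr(out, "Ts") <- Ts
  class(out) <- c("droplet_series", class(out))
  out
}

#' Read / write a droplet time series as CSV
#'
#' Plain CSV with header `t_s,V_ul,H_mm,theta_l_deg,theta_r_deg,D_mm`.
#' The substrate temperature travels in a `# Ts_C:` comment line.
#'
#' @param path File path.
#' @return `read_droplet_series()` returns a `droplet_series` tibble.
#' @export
read_droplet_series <- function(path) {
  first <- readLines(path, n = 1L)
  Ts <- NA_real_
  skip <- 0L
  if (startsWith(first, "#")) {
    Ts <- as.numeric(sub(".*Ts_C:\\s*", "", first))
    skip <- 1L
  }
  df <- read.csv(path, skip = skip)
  need <- c("t_s", "V_ul", "H_mm", "theta_l_deg", "theta_r_deg", "D_mm")
  if (!all(need %in% names(df))) {
    abort(paste0("Droplet CSV must have columns: ", paste(need, collapse = ", ")))
  }
  droplet_series(df$t_s, df$V_ul, df$H_mm, df$theta_l_deg, df$theta_r_deg,
                 df$D_mm, Ts = Ts)
}

#' @rdname read_droplet_series
#' @param series A `droplet_series`.
#' @export
write_droplet_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# Ts_C: %g", attr(series, "Ts") %||% NA_real_), con)
  write.csv(as.data.frame(series), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Spherical-cap volume
#'
#' Volume of a spherical cap of base diameter `D` and contact angle
#' `theta`: with \eqn{r = D/2} and apex height \eqn{h = r\tan(\theta/2)},
#' \deqn{V = \frac{\pi h}{6}(3 r^2 + h^2).}
#' Strictly increasing in both arguments.
#'
#' @param D Base diameter, mm.
#' @param theta Contact angle, degrees, in (0, 180).
#' @return Volume in ul (1 mm^3 = 1 ul). Vectorised.
#' @examples
#' spherical_cap_volume(2, 90)  # hemisphere of radius 1 mm: 2*pi/3
#' @export
spherical_cap_volume <- function(D, theta) {
  if (any(D <= 0)) abort("`D` must be positive.")
  if (any(theta <= 0 | theta >= 180)) abort("`theta` must lie in (0, 180) degrees.")
  r <- D / 2
  h <- r * tan(theta * pi / 360)
  pi * h / 6 * (3 * r^2 + h^2)
}

#' Apex height of a spherical cap
#' @inheritParams spherical_cap_volume
#' @return Height, mm.
#' @export
spherical_cap_height <- function(D, theta) {
  (D / 2) * tan(theta * pi / 360)
}

#' Side-view contour of a spherical cap
#'
#' Samples the circular arc of a spherical cap sitting on the baseline
#' `z = 0` — the noiseless side-view profile a drop-shape analyser sees.
#'
#' @inheritParams spherical_cap_volume
#' @param n Number of contour points.
#' @param noise_sd Gaussian noise added to `z`, mm (default 0).
#' @return A tibble with columns `x_mm`, `z_mm`, ordered left to right.
#' @export
cap_profile <- function(D, theta, n = 181, noise_sd = 0) {
  r <- D / 2
  th <- theta * pi / 180
  h <- r * tan(th / 2)
  Rc <- (r^2 + h^2) / (2 * h)
  z0 <- h - Rc
  psi <- seq(-th, th, length.out = n)
  x <- Rc * sin(psi)
  z <- z0 + Rc * cos(psi)
  z <- pmax(z, 0)
  if (noise_sd > 0) z <- pmax(z + rnorm(n, 0, noise_sd), 0)
  tibble(x_mm = x, z_mm = z)
}

# Kasa algebraic circle fit: minimises sum((x^2+z^2) + D x + E z + F)^2.
# Returns centre (a, b) and radius r, or NULL when degenerate (collinear).
fit_circle <- function(x, z) {
  A <- cbind(x, z, 1)
  y <- -(x^2 + z^2)
  qr_A <- qr(A)
  if (qr_A$rank < 3) return(NULL)
  co <- qr.coef(qr_A, y)
  a <- -co[1] / 2
  b <- -co[2] / 2
  r2 <- a^2 + b^2 - co[3]
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(a = unname(a), b = unname(b), r = sqrt(unname(r2)))
}

# Contact angle at a baseline intersection of a fitted circle.
# Centre height b fixes the angle: cos(theta) = -b / r.
circle_contact_angle <- function(circ) {
  acos(max(-1, min(1, -circ$b / circ$r))) * 180 / pi
}

#' Contact angles from a side-view contour
#'
#' Fits a circle to the contour locally near each baseline contact point
#' and reports the tangent angle at the baseline intersection — the
#' standard drop-shape-analysis circle-fit method, robust to pixel noise.
#' The local window holds the points within a fraction of the profile
#' height of each contact point (at least 5 points).
#'
#' @param profile A data frame / tibble with columns `x_mm`, `z_mm` (or a
#'   two-column matrix), describing a contour that touches the baseline
#'   `z = 0` on both sides.
#' @param window_frac Fraction of the profile's height span used as the
#'   local-fit radius around each contact point (default 0.6).
#' @param baseline_tol Tolerance for "touching" the baseline, as a
#'   fraction of the height span (default 0.02).
#' @return A tibble with one row: `theta_l_deg`, `theta_r_deg`.
#' @examples
#' extract_contact_angle(cap_profile(4.8, 50))
#' @export
extract_contact_angle <- function(profile, window_frac = 0.6,
                                  baseline_tol = 0.02) {
  if (is.matrix(profile)) profile <- tibble(x_mm = profile[, 1], z_mm = profile[, 2])
  x <- profile$x_mm
  z <- profile$z_mm
  ord <- order(x)
  x <- x[ord]; z <- z[ord]
  hspan <- max(z) - min(z)
  if (hspan <= 0) abort("Profile is degenerate (no height span).")
  tol <- baseline_tol * hspan
  on_base <- which(z <= min(z) + tol)
  if (length(on_base) < 2) abort("Profile does not reach the baseline at two points.")
  i_left <- min(on_base)
  i_right <- max(on_base)

  one_side <- function(i_contact) {
    d <- sqrt((x - x[i_contact])^2 + (z - z[i_contact])^2)
    keep <- which(d <= window_frac * hspan)
    if (length(keep) < 5) {
      keep <- order(d)[seq_len(min(5, length(d)))]
      if (length(keep) < 5) abort("Fewer than 5 points near a contact point.")
    }
    circ <- fit_circle(x[keep], z[keep])
    if (is.null(circ)) {
      # collinear points: tangent from a straight-line fit
      sl <- coef(lm(z[keep] ~ x[keep]))[2]
      if (!is.finite(sl)) sl <- 0
      return(atan(abs(sl)) * 180 / pi)
    }
    circle_contact_angle(circ)
  }

  tibble(theta_l_deg = one_side(i_left), theta_r_deg = one_side(i_right))
}

#' Volume-shrinkage slope of the initial linear regime
#'
#' Blood-drop volume decreases linearly at the start of evaporation; the
#' slope of that initial segment is an evaporation-rate descriptor. The
#' fitting window starts at the first 20% of samples and grows forward
#' while the linear fit keeps \eqn{r^2 \ge} `r2_min`, which is this
#' package's operational definition of "the initial linear segment".
#'
#' @param series A `droplet_series` (or any data frame with `t_s`, `V_ul`).
#' @param r2_min Minimum r-squared for the window to keep growing
#'   (default 0.98).
#' @param init_frac Initial window as a fraction of the series (default 0.2).
#' @return A `shrinkage_fit` object: `slope` (ul/s), `intercept` (ul),
#'   `r2`, `window` (start/end time, s), `n`.
#' @export
volume_shrinkage_slope <- function(series, r2_min = 0.98, init_frac = 0.2) {
  t <- series$t_s
  V <- series$V_ul
  n <- length(t)
  if (n < 10) abort("Need at least 10 samples.")
  if (length(unique(t)) < 2) abort("All timestamps equal.")

  fit_window <- function(k) {
    tt <- t[1:k]; vv <- V[1:k]
    sxx <- sum((tt - mean(tt))^2)
    sxy <- sum((tt - mean(tt)) * (vv - mean(vv)))
    slope <- sxy / sxx
    icpt <- mean(vv) - slope * mean(tt)
    ss_tot <- sum((vv - mean(vv))^2)
    ss_res <- sum((vv - icpt - slope * tt)^2)
    r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
    list(slope = slope, intercept = icpt, r2 = r2)
  }

  k <- max(10L, ceiling(init_frac * n))
  best <- fit_window(k)
  while (k < n) {
    cand <- fit_window(k + 1L)
    if (cand$r2 < r2_min) break
    k <- k + 1L
    best <- cand
  }
  structure(
    list(slope = best$slope, intercept = best$intercept, r2 = best$r2,
         window = c(t[1], t[k]), n = k),
    class = "shrinkage_fit"
  )
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf("<shrinkage_fit> slope = %.5g ul/s over t = [%g, %g] s (n = %d, r2 = %.4f)\n",
              x$slope, x$window[1], x$window[2], x$n, x$r2))
  invisible(x)
}

#' @rdname volume_shrinkage_slope
#' @param x,object A `shrinkage_fit`.
#' @param ... Unused.
#' @export
tidy.shrinkage_fit <- function(x, ...) {
  tibble(term = c("slope_ul_s", "intercept_ul"),
         estimate = c(x$slope, x$intercept))
}

#' @rdname volume_shrinkage_slope
#' @export
glance.shrinkage_fit <- function(x, ...) {
  tibble(r.squared = x$r2, nobs = x$n,
         window_start_s = x$window[1], window_end_s = x$window[2])
}

#' Volume-diameter scaling per substrate temperature
#'
#' Fits the power law \eqn{V = c\,D^k} (ordinary least squares on logs)
#' separately for each substrate temperature. The power law nests the
#' spherical-cap relation \eqn{V \propto D^3} at fixed contact angle and
#' lets deposit diameter be mapped back to initial volume.
#'
#' @param records A data frame with columns `V0_ul`, `D_mm`, `Ts_C`
#'   (one row per drop).
#' @return A `vd_fit` object; its `table` field is a tibble with one row
#'   per temperature: `Ts_C`, `c`, `k`, `r2`, `n`.
#' @export
fit_volume_diameter <- function(records) {
  if (any(records$V0_ul <= 0) || any(records$D_mm <= 0)) {
    abort("Volumes and diameters must be positive for the log-log fit.")
  }
  tab <- list_rbind(map(split(records, records$Ts_C), function(d) {
    if (nrow(d) < 3) abort("Need >= 3 drops per temperature.")
    lv <- log(d$V0_ul); ld <- log(d$D_mm)
    m <- lm(lv ~ ld)
    ss_tot <- sum((lv - mean(lv))^2)
    r2 <- if (ss_tot == 0) 1 else 1 - sum(m$residuals^2) / ss_tot
    tibble(Ts_C = d$Ts_C[1], c = exp(unname(coef(m)[1])), k = unname(coef(m)[2]),
           r2 = r2, n = nrow(d))
  }))
  structure(list(table = tab), class = "vd_fit")
}

#' @export
print.vd_fit <- function(x, ...) {
  cat("<vd_fit> V = c * D^k per substrate temperature\n")
  print(x$table)
  invisible(x)
}

#' @rdname fit_volume_diameter
#' @param x A `vd_fit`.
#' @param ... Unused.
#' @export
tidy.vd_fit <- function(x, ...) x$table

#' Predict drop volume from deposit diameter and temperature
#'
#' @param fit A `vd_fit` from [fit_volume_diameter()].
#' @param D Diameter(s), mm.
#' @param Ts Substrate temperature, °C (must be one of the fitted groups).
#' @return Predicted volume, ul.
#' @export
predict_volume <- function(fit, D, Ts) {
  stopifnot(inherits(fit, "vd_fit"))
  row <- fit$table[fit$table$Ts_C == Ts, ]
  if (nrow(row) == 0) abort(sprintf("No V-D fit for Ts = %g degC.", Ts))
  row$c * D^row$k
}

#' Dome-formation onset from the height trace
#'
#' Marangoni-driven dome formation shows as the apex height rising above
#' its running minimum instead of decreasing monotonically. Onset is the
#' earliest time at which `H` exceeds the running minimum by more than
#' `threshold` (fractional) and keeps rising for at least `min_rise`
#' consecutive samples. A small absolute guard (`min_abs_rise`, as a
#' fraction of the initial height) suppresses noise triggers late in the
#' lifetime when the running minimum approaches zero.
#'
#' @param series A `droplet_series` (needs `t_s`, `H_mm`).
#' @param threshold Fractional rise above the running minimum (default 0.05).
#' @param min_rise Number of consecutive rising samples required (default 3).
#' @param min_abs_rise Minimum rise as a fraction of `H[1]` (default 0.02).
#' @return Onset time in seconds, or `NA_real_` when no dome forms.
#' @export
detect_dome_formation <- function(series, threshold = 0.05, min_rise = 3,
                                  min_abs_rise = 0.02) {
  t <- series$t_s
  H <- series$H_mm
  n <- length(H)
  if (n < min_rise + 1) return(NA_real_)
  if (n >= 5) H <- stats::runmed(H, 3)  # light smoothing against pixel noise
  runmin <- cummin(H)
  floor_abs <- min_abs_rise * H[1]
  for (i in seq_len(n - min_rise)) {
    if (H[i] > runmin[i] * (1 + threshold) && H[i] - runmin[i] > floor_abs) {
      rising <- all(diff(H[i:min(n, i + min_rise)]) > -1e-12)
      if (rising) return(t[i])
    }
  }
  NA_real_
}

#' @export
autoplot.droplet_series <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("V_ul", "H_mm", "theta_l_deg", "D_mm"),
                        names_to = "quantity", values_to = "value")
  ggplot(long, aes(x = .data$t_s, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y") +
    labs(x = "time (s)", y = NULL,
         title = sprintf("Droplet trajectory (Ts = %g degC)",
                         attr(object, "Ts") %||% NA_real_)) +
    theme_minimal()
}
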