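#' Study design for a synthetic evaporation campaign
#'
#' The default design mirrors the reference study shape: four substrate
#' temperatures (23, 37, 60, 90 °C) with 18 replicate drops each (72
#' records) of nominal initial volume 11 ul.
#'
#' @param temperatures Substrate temperatures, °C.
#' @param replicates Drops per temperature.
#' @param base_volume_ul Nominal initial volume, ul.
#' @param volume_jitter Fractional s.d. of the per-drop initial volume
#'   (default 0.05).
#' @param seed Master seed; every downstream random draw derives from it.
#' @return A `study_design` list.
#' @export
study_design <- function(temperatures = c(23, 37, 60, 90), replicates = 18,
                         base_volume_ul = 11, volume_jitter = 0.05, seed = 1) {
  if (replicates < 1) abort("`replicates` must be >= 1.")
  structure(list(temperatures = temperatures, replicates = replicates,
                 base_volume_ul = base_volume_ul,
                 volume_jitter = volume_jitter, seed = seed),
            class = "study_design")
}

#' Generate the study records
#'
#' Expands a design into one record per drop with an independent child
#' seed, so each drop's trajectories, frames and deposit are
#' reproducible in isolation. Deterministic given the master seed.
#'
#' @param design A [study_design()].
#' @return A tibble: `drop_id, Ts_C, replicate, V0_ul, seed`.
#' @export
generate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  n <- length(design$temperatures) * design$replicates
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(design$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  v0 <- design$base_volume_ul *
    pmax(0.5, 1 + design$volume_jitter * rnorm(n))
  tibble(
    drop_id = sprintf("d%03d", seq_len(n)),
    Ts_C = rep(design$temperatures, each = design$replicates),
    replicate = rep(seq_len(design$replicates), times = length(design$temperatures)),
    V0_ul = v0,
    seed = seeds
  )
}

#' Scenario configuration for one substrate temperature
#'
#' Per-temperature defaults of the synthetic generator: trajectory
#' regime and lifetime, dome onset, the prescribed Marangoni-number
#' schedule, evaporative centre cooling, thermal rendering settings and
#' deposit morphology scales. Defaults emulate the observed
#' phenomenology: at 23 °C all shape descriptors decrease linearly over
#' about 1200 s for 11 ul; at 37 °C the Marangoni number grows at 1.66
#' units/s until 900 s and at 55 units/s afterwards, forming a delayed
#' dome; at 60 and 90 °C the dome forms from the start over much
#' shorter lifetimes.
#'
#' @param Ts Substrate temperature, °C (one of the design temperatures
#'   or any value; parameters interpolate sensibly).
#' @param noise_frac Fractional trajectory noise (default 0.01).
#' @param pixel_noise_C Thermal pixel noise s.d., °C (default 0.02).
#' @param grid_px Thermal frame size, pixels (default 128).
#' @param drop_radius_px Drop radius in the frames, pixels (default
#'   0.3125 of the grid: 40 px at the default 128).
#' @param deposit_px Height-map size, pixels (default 96).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(Ts, noise_frac = 0.01, pixel_noise_C = 0.02,
                            grid_px = 128, drop_radius_px = round(0.3125 * grid_px),
                            deposit_px = 128) {
  regime <- if (Ts < 30) "linear" else if (Ts < 50) "delayed_dome" else "immediate_dome"
  base_lifetime <- if (Ts < 30) 1200 else if (Ts < 50) 1100 else if (Ts < 75) 500 else 250
  dome_onset <- if (regime == "delayed_dome") 900 else if (regime == "immediate_dome") 0 else NA_real_
  # prescribed Ma(t): slopes in Ma units per second
  ma <- switch(regime,
    linear = list(kind = "linear", rate = 0.25),
    delayed_dome = list(kind = "piecewise", early_rate = 1.66, late_rate = 55,
                        break_s = 900),
    immediate_dome = list(kind = "linear", rate = if (Ts < 75) 2.5 else 3.2)
  )
  cooling <- 0.5 + 0.06 * Ts   # evaporative centre cooling below substrate, degC
  amp <- 1.5 + 0.045 * Ts      # deposit relief scale, um
  structure(list(
    Ts = Ts, regime = regime, base_lifetime_s = base_lifetime,
    dome_onset_s = dome_onset, ma_target = ma,
    center_cooling_C = cooling, noise_frac = noise_frac,
    pixel_noise_C = pixel_noise_C, grid_px = grid_px,
    drop_radius_px = drop_radius_px, gamma = 2, ring_width = 2,
    deposit_px = deposit_px,
    deposit = list(
      amp_um = amp,
      rim_frac = 1.5,
      dome_frac = switch(regime, linear = -0.8, delayed_dome = 0.6,
                         immediate_dome = if (Ts < 75) 1.5 else 2.5),
      n_cracks = round(10 + 0.3 * Ts),
      n_rings = 1 + floor(Ts / 30),
      n_blobs = 8,
      blob_axis_ratio = max(1.1, 2.6 - 0.017 * Ts),
      crack_depth_frac = 0.6,
      texture_frac = 0.05,
      dispersion = 0.05
    )
  ), class = "scenario_config")
}

#' Evaluate the prescribed Marangoni schedule of a scenario
#'
#' @param config A `scenario_config`.
#' @param t Times, s.
#' @return Ma values (dimensionless).
#' @export
ma_target <- function(config, t) {
  m <- config$ma_target
  if (m$kind == "linear") return(m$rate * t)
  ifelse(t <= m$break_s,
         m$early_rate * t,
         m$early_rate * m$break_s + m$late_rate * (t - m$break_s))
}

# Geometry closure: base diameter and initial height from (V0, theta0)
initial_geometry <- function(V0_ul, theta0 = 50) {
  th <- theta0 * pi / 360
  f <- pi * tan(th) * (3 + tan(th)^2) / 6
  r <- (V0_ul / f)^(1 / 3)
  list(D_mm = 2 * r, H0_mm = r * tan(th))
}

#' Initial side-view contour of the default drop
#'
#' The t = 0 spherical-cap contour implied by the initial volume and
#' the 50° initial contact angle — the noiseless profile used to test
#' contact-angle extraction.
#'
#' @param V0_ul Initial volume, ul (default 11).
#' @param theta0 Initial contact angle, degrees (default 50).
#' @param n Number of contour points.
#' @return A tibble `x_mm, z_mm` (see [cap_profile()]).
#' @export
initial_cap_profile <- function(V0_ul = 11, theta0 = 50, n = 181) {
  geo <- initial_geometry(V0_ul, theta0)
  cap_profile(geo$D_mm, theta0, n = n)
}

#' Generate a synthetic droplet trajectory
#'
#' Constant-contact-radius trajectories in three regimes. At 23 °C,
#' volume, height and contact angle decrease linearly to zero over the
#' lifetime (about 1200 s for 11 ul). At 37 °C the decline is linear
#' until the dome onset (900 s), after which height and angle rise
#' before the final decay. At 60/90 °C the dome grows from the start
#' over a much shorter lifetime. Lifetime scales with initial volume;
#' additive Gaussian noise defaults to 1% of each channel's initial
#' value.
#'
#' @param record One row of [generate_study()] (or a list with `Ts_C`,
#'   `V0_ul`, `seed`).
#' @param config A [scenario_config()]; defaults to the record's Ts.
#' @param noise_frac Override for the trajectory noise fraction.
#' @param dt_s Sample interval, s (default lifetime/240).
#' @return A `droplet_series`.
#' @export
generate_droplet_series <- function(record, config = scenario_config(record$Ts_C),
                                    noise_frac = config$noise_frac, dt_s = NULL) {
  Ts <- record$Ts_C
  V0 <- record$V0_ul
  tf <- config$base_lifetime_s * (V0 / 11)
  if (is.null(dt_s)) dt_s <- tf / 240
  t <- seq(0, tf, by = dt_s)
  x <- t / tf
  geo <- initial_geometry(V0)
  theta0 <- 50

  V <- V0 * (1 - x)
  if (config$regime == "linear") {
    Hsh <- 1 - x
  } else if (config$regime == "delayed_dome") {
    onset <- config$dome_onset_s * (V0 / 11)
    Hsh <- ifelse(t <= onset,
                  1 - x,
                  (1 - onset / tf) * (tf - t) / (tf - onset) +
                    0.35 * sin(pi * (t - onset) / (tf - onset)))
  } else {
    Hsh <- (1 - x) + 0.8 * sin(pi * x)
  }
  H <- geo$H0_mm * Hsh
  theta <- theta0 * Hsh
  D <- rep(geo$D_mm, length(t))

  if (noise_frac > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(record$seed %% .Machine$integer.max)
    n <- length(t)
    V <- pmax(V + rnorm(n, 0, noise_frac * V0), 0)
    H <- pmax(H + rnorm(n, 0, noise_frac * geo$H0_mm), 0)
    theta <- pmax(theta + rnorm(n, 0, noise_frac * theta0), 0)
    D <- D + rnorm(n, 0, 0.1 * noise_frac * geo$D_mm)
  }
  droplet_series(t, V, H, theta, theta, D, Ts = Ts)
}

#' Invert a Marangoni schedule to an edge-centre temperature schedule
#'
#' Solves the Marangoni formula pointwise for \eqn{\Delta T} given a
#' target Ma(t). Because the surface-tension derivative and viscosity
#' depend on \eqn{T_{TPCL} = T_{center} + \Delta T}, the solution is
#' found by fixed-point iteration to `tol` °C.
#'
#' @param Ma Target Ma values (>= 0), one per time point.
#' @param R Drop radius, m.
#' @param props A [blood_properties()] with `sigma_fit`.
#' @param T_center Centre temperature schedule, °C (scalar or vector).
#' @param alpha_mode `"si"` (default) or `"paper_numeric"`.
#' @param tol Convergence tolerance, °C (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return \eqn{\Delta T(t)} in °C.
#' @export
invert_marangoni_to_deltaT <- function(Ma, R, props, T_center,
                                       alpha_mode = c("si", "paper_numeric"),
                                       tol = 1e-6, max_iter = 100) {
  alpha_mode <- match.arg(alpha_mode)
  stopifnot(inherits(props, "blood_properties"))
  if (is.null(props$sigma_fit)) abort("`props$sigma_fit` is required.")
  if (any(Ma < 0)) abort("`Ma` must be nonnegative.")
  alpha <- thermal_diffusivity(props$lambda, props$rho, props$cp, mode = alpha_mode)
  Tc <- rep_len(T_center, length(Ma))
  dT <- rep(0, length(Ma))
  for (i in seq_len(max_iter)) {
    Tt <- Tc + dT
    dsig <- dsigma_dT(props$sigma_fit, Tt, Tc)          # mN/(m.degC), negative
    eta <- blood_viscosity((Tt + Tc) / 2, props$ht)
    dT_new <- -Ma * eta * alpha / (dsig * 1e-3 * R)
    if (max(abs(dT_new - dT)) < tol) return(dT_new)
    dT <- dT_new
  }
  warn("Fixed-point inversion did not converge to tolerance; returning last iterate.")
  dT
}

#' Render synthetic thermal frames
#'
#' Builds a radial surface-temperature field inside the drop,
#' \eqn{T(r,t) = T_{center}(t) + \Delta T(t)\, s(r)} with
#' \eqn{s(r) \propto (r/R)^\gamma}, and the substrate temperature
#' outside, plus Gaussian pixel noise. The radial shape is affinely
#' normalized on the pixel grid so that the analyzer's sampling
#' convention (annulus mean minus centre-disc mean at the default ring
#' width) returns exactly the prescribed \eqn{\Delta T}; this makes the
#' generator-analyzer round trip exact up to pixel noise.
#'
#' @param record A study record (needs `seed`).
#' @param t Frame times, s.
#' @param deltaT \eqn{\Delta T(t)} values, °C, one per frame.
#' @param T_center Centre temperature schedule, °C (scalar or vector).
#' @param config A [scenario_config()] supplying grid size, radius,
#'   `gamma`, `ring_width`, pixel noise and the substrate temperature.
#' @param pixel_pitch mm per pixel (default 0.05).
#' @return A `thermal_frames` object.
#' @export
generate_thermal_frames <- function(record, t, deltaT, T_center, config,
                                    pixel_pitch = 0.05) {
  n <- config$grid_px
  R <- config$drop_radius_px
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  rg <- radius_grid(n, n, ctr)
  inside <- rg <= R
  raw <- (pmin(rg, R) / R)^config$gamma
  disc <- rg <= config$ring_width
  ann <- rg >= R - config$ring_width & rg <= R
  m_disc <- mean(raw[disc])
  m_ann <- mean(raw[ann])
  shape <- (raw - m_disc) / (m_ann - m_disc)

  Tc <- rep_len(T_center, length(t))
  frames <- array(config$Ts, dim = c(n, n, length(t)))
  for (i in seq_along(t)) {
    f <- matrix(config$Ts, n, n)
    f[inside] <- Tc[i] + deltaT[i] * shape[inside]
    frames[, , i] <- f
  }
  if (config$pixel_noise_C > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed((record$seed + 1L) %% .Machine$integer.max)
    frames <- frames + array(rnorm(length(frames), 0, config$pixel_noise_C),
                             dim = dim(frames))
  }
  thermal_frames(frames, t, pixel_pitch, ctr, R)
}

#' Centre-temperature schedule of a scenario
#'
#' The drop surface sits below the substrate temperature by an
#' evaporative-cooling offset that relaxes slightly over the lifetime.
#'
#' @param config A `scenario_config`.
#' @param t Times, s.
#' @param lifetime_s Drop lifetime, s.
#' @return Centre temperatures, °C.
#' @export
center_temperature <- function(config, t, lifetime_s) {
  config$Ts - config$center_cooling_C * (1 - 0.3 * t / lifetime_s)
}

# Gaussian-blurred white noise scaled to a target sd: fine surface texture
smooth_texture <- function(n, sd_um, blur_sigma = 1.5) {
  if (sd_um <= 0) return(matrix(0, n, n))
  w <- matrix(rnorm(n * n), n, n)
  sm <- EBImage::gblur(w, sigma = blur_sigma)
  sm <- as.matrix(sm)
  sm * sd_um / sd(as.vector(sm))
}

#' Generate a synthetic deposit height map
#'
#' Phenomenological dried-deposit morphology (pattern statistics, not a
#' crack-mechanics model). The unheated regime has a raised peripheral
#' rim, a central cavity and a coronal band with radial and
#' ortho-radial crack grooves; heated regimes replace the cavity with a
#' central dome and denser cracking. Relief amplitude, dome height and
#' crack count scale monotonically with substrate temperature, so the
#' 16 texture parameters carry a programmed temperature effect, with a
#' small per-drop dispersion. The deposit diameter is tied to the
#' initial volume through the spherical-cap geometry. Reproducible per
#' record seed.
#'
#' @param record A study record (`Ts_C`, `V0_ul`, `seed`).
#' @param config A [scenario_config()].
#' @return A `height_map` (pitch chosen so the deposit spans ~80% of
#'   the grid).
#' @export
generate_deposit <- function(record, config = scenario_config(record$Ts_C)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed((record$seed + 2L) %% .Machine$integer.max)

  cfg <- config$deposit
  n <- config$deposit_px
  geo <- initial_geometry(record$V0_ul)
  D_um <- geo$D_mm * 1000
  pitch <- D_um * 1.25 / n
  ctr <- c((n + 1) / 2, (n + 1) / 2)
  rg <- radius_grid(n, n, ctr)
  R <- (D_um / 2) / pitch                       # deposit radius in px
  rr <- rg / R

  mult <- max(0.2, 1 + cfg$dispersion * rnorm(1))
  amp <- cfg$amp_um * mult

  soft_band <- function(r, lo, hi, w = 0.02) {
    # smooth indicator of lo < r/R < hi
    1 / (1 + exp(-(rr - lo) / w)) * 1 / (1 + exp((rr - hi) / w))
  }

  z <- matrix(0, n, n)
  # peripheral rim (coffee-ring analogue)
  z <- z + cfg$rim_frac * amp * exp(-((rg - 0.93 * R)^2) / (2 * (0.035 * R)^2))
  # raised coronal band, separated from the rim by a trough
  z <- z + amp * soft_band(rr, 0.36, 0.84)
  # central cavity (cold) or dome (hot)
  z <- z + cfg$dome_frac * amp * exp(-rg^2 / (2 * (0.15 * R)^2))
  # aggregates in the inner annulus: elongated at low Ts (outward
  # capillary flow stretches them radially), rounder under Marangoni
  # recirculation at high Ts
  q <- cfg$blob_axis_ratio
  a_px <- sqrt(45 * q / pi); b_px <- a_px / q
  for (bi in seq_len(cfg$n_blobs)) {
    th_b <- runif(1, -pi, pi)
    r_b <- runif(1, 0.20, 0.28) * R
    cb <- ctr + r_b * c(sin(th_b), cos(th_b))
    phi <- runif(1, 0, pi)
    u <- cos(phi) * (matrix(seq_len(n), n, n) - cb[1]) +
      sin(phi) * (matrix(seq_len(n), n, n, byrow = TRUE) - cb[2])
    v <- -sin(phi) * (matrix(seq_len(n), n, n) - cb[1]) +
      cos(phi) * (matrix(seq_len(n), n, n, byrow = TRUE) - cb[2])
    z <- z + 1.8 * amp * exp(-((u / a_px)^2 + (v / b_px)^2))
  }
  # radial cracks cutting the coronal band into wedge patterns
  row_off <- matrix(seq_len(n), n, n) - ctr[1]
  col_off <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr[2]
  ang <- atan2(row_off, col_off)
  depth <- (1 + cfg$crack_depth_frac) * amp
  band <- rr > 0.33 & rr < 0.87
  for (a in runif(cfg$n_cracks, -pi, pi)) {
    d_ang <- abs(atan2(sin(ang - a), cos(ang - a)))
    arc <- d_ang * rg                            # arc distance in px
    z <- z - depth * exp(-(arc / 1.1)^2) * band
  }
  # ortho-radial (azimuthal) crack circles inside the band
  ring_radii <- seq(0.36, 0.84, length.out = cfg$n_rings + 2)
  for (rc in ring_radii[-c(1, cfg$n_rings + 2)] * R) {
    z <- z - depth * exp(-((rg - rc) / 1.1)^2)
  }
  # trough isolating the band from the rim
  z <- z - depth * exp(-((rg - 0.875 * R) / 1.1)^2)
  # fine texture everywhere inside the deposit
  z <- z + smooth_texture(n, cfg$texture_frac * amp) * (rr < 1)
  # substrate outside
  z[rr >= 1] <- 0
  height_map(z, lateral_pitch = pitch)
}
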