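#' Analyse one synthetic drop end to end
#'
#' Generates the drop's trajectory, thermal frames and deposit from its
#' record, then runs the full analysis chain: shrinkage slope, dome
#' onset, edge-centre thermography, Marangoni trajectory and regime
#' classification, and the 16-parameter texture report.
#'
#' @param record One row of [generate_study()].
#' @param config A [scenario_config()]; defaults to the record's Ts.
#' @param props A [blood_properties()]; the default carries the
#'   package's default surface-tension curve.
#' @param include_thermal Run the thermography/Marangoni stage
#'   (default TRUE).
#' @param n_frames Thermal frames per drop (default 48).
#' @return A one-row tibble: record fields, `D_mm`, `slope_ul_s`,
#'   `slope_r2`, `dome_onset_s`, `regime`, and the texture parameters.
#' @export
run_drop <- function(record, config = scenario_config(record$Ts_C),
                     props = default_blood_properties(),
                     include_thermal = TRUE, n_frames = 48) {
  series <- generate_droplet_series(record, config)
  shrink <- volume_shrinkage_slope(series)
  onset <- detect_dome_formation(series)
  geo <- initial_geometry(record$V0_ul)

  regime <- NA_character_
  if (include_thermal) {
    tf <- max(series$t_s)
    t <- seq(0, tf, length.out = n_frames)
    Tc <- center_temperature(config, t, tf)
    R_m <- geo$D_mm / 2 * 1e-3
    dT <- invert_marangoni_to_deltaT(ma_target(config, t), R_m, props, Tc)
    frames <- generate_thermal_frames(record, t, dT, Tc, config)
    ecs <- edge_center_series(frames, ring_width = config$ring_width)
    traj <- marangoni_series(ecs, R_m, props)
    regime <- classify_regime(series, traj)
  }

  deposit <- generate_deposit(record, config)
  report <- full_report(deposit)

  dplyr::bind_cols(
    as_tibble(record),
    tibble(D_mm = geo$D_mm, slope_ul_s = shrink$slope, slope_r2 = shrink$r2,
           dome_onset_s = onset, regime = regime),
    report
  )
}

#' Default blood properties with the default surface-tension curve
#'
#' The package's default sigma(T) is an invented but plausible
#' logarithmic decline (-11.5 ln T + 88 mN/m), not a measured fit; all
#' other constants are the measured sheep-blood values.
#'
#' @return A [blood_properties()] object.
#' @export
default_blood_properties <- function() {
  blood_properties(sigma_fit = default_sigma_fit())
}

#' Run the full synthetic study
#'
#' Generates the study records, processes every drop with [run_drop()]
#' (per-drop failures are caught, flagged and skipped rather than
#' aborting the study), fits the volume-diameter relation and computes
#' the per-parameter significance table. Fully deterministic given the
#' design's master seed.
#'
#' @param design A [study_design()].
#' @param props A [blood_properties()].
#' @param include_thermal Run the thermography/Marangoni stage per drop.
#' @param grid_px Thermal frame size used at study scale (default 64; a
#'   modest grid keeps a 72-drop run fast while leaving the edge-centre
#'   reduction well resolved).
#' @param deposit_px Height-map size per deposit (default 128).
#' @param quiet Suppress progress messages.
#' @return A `study_bundle`: list with `records`, `drops` (per-drop
#'   results), `significance`, `vd_fit`, `failed` (drop ids) and
#'   `manifest` (seed, settings, content hash).
#' @export
run_study <- function(design = study_design(), props = default_blood_properties(),
                      include_thermal = TRUE, grid_px = 64, deposit_px = 128,
                      quiet = TRUE) {
  records <- generate_study(design)
  rows <- vector("list", nrow(records))
  failed <- character(0)
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    cfg <- scenario_config(rec$Ts_C, grid_px = grid_px, deposit_px = deposit_px)
    rows[[i]] <- tryCatch(
      run_drop(rec, cfg, props, include_thermal = include_thermal),
      error = function(e) {
        warn(sprintf("Drop %s failed: %s", rec$drop_id, conditionMessage(e)))
        failed <<- c(failed, rec$drop_id)
        NULL
      })
    if (!quiet && i %% 10 == 0) message(sprintf("processed %d/%d drops", i, nrow(records)))
  }
  drops <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  sig <- NULL
  vd <- NULL
  if (length(unique(drops$Ts_C)) >= 2 && min(table(drops$Ts_C)) >= 2) {
    sig <- significance_table(drops)
  }
  if (min(table(drops$Ts_C)) >= 3) {
    vd <- fit_volume_diameter(drops)
  }
  manifest <- list(
    seed = design$seed,
    n_records = nrow(records), n_processed = nrow(drops),
    temperatures = design$temperatures, replicates = design$replicates,
    include_thermal = include_thermal, grid_px = grid_px,
    deposit_px = deposit_px,
    content_hash = rlang::hash(drops)
  )
  structure(list(records = records, drops = drops, significance = sig,
                 vd_fit = vd, failed = failed, manifest = manifest),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d/%d drops processed (seed %s)\n",
              x$manifest$n_processed, x$manifest$n_records, x$manifest$seed))
  if (!is.null(x$significance)) {
    cat(sprintf("  significant parameters (p < %g): %d/%d\n", x$significance$alpha,
                sum(x$significance$anova$significant), nrow(x$significance$anova)))
  }
  invisible(x)
}

#' @rdname run_study
#' @param x A `study_bundle`.
#' @param ... Unused.
#' @export
glance.study_bundle <- function(x, ...) {
  tibble(n_records = x$manifest$n_records,
         n_processed = x$manifest$n_processed,
         n_failed = length(x$failed),
         max_anova_p = if (is.null(x$significance)) NA_real_ else max(x$significance$anova$p.value),
         content_hash = x$manifest$content_hash)
}

#' Write a study bundle to disk
#'
#' Study-level CSVs (records, per-drop results, ANOVA and pairwise
#' tables) plus a JSON manifest that suffices to reproduce the run.
#'
#' @param bundle A `study_bundle`.
#' @param dir Output directory.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$records, file.path(dir, "records.csv"), row.names = FALSE, quote = FALSE)
  write.csv(bundle$drops, file.path(dir, "drops.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$significance)) write_significance_table(bundle$significance, dir)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Marangoni-rate round trip for one scenario
#'
#' The forward-inverse closure exercised on a single drop: the
#' scenario's prescribed Ma(t) is inverted to an edge-centre
#' temperature schedule, rendered as thermal frames, reduced back with
#' [edge_center_series()] and [marangoni_series()], and the recovered
#' trajectory's two-segment rates are computed at the prescribed
#' breakpoint.
#'
#' @param Ts Substrate temperature, °C (default 37, the delayed-dome
#'   scenario with rates 1.66 and 55 units/s around 900 s).
#' @param V0_ul Initial volume, ul (default 11).
#' @param seed Record seed.
#' @param pixel_noise_C Thermal pixel noise, °C (default 0: noiseless).
#' @param dt_s Frame interval, s (default 10).
#' @param t_max_s Last frame time, s (default lifetime, at least
#'   breakpoint + 140 s for the delayed-dome scenario).
#' @param props A [blood_properties()].
#' @return List: `traj` (recovered `marangoni_traj`), `rates`
#'   (`rate_analysis` at the prescribed breakpoint), `target`
#'   (prescribed Ma at the frame times), `config`.
#' @export
marangoni_round_trip <- function(Ts = 37, V0_ul = 11, seed = 1,
                                 pixel_noise_C = 0, dt_s = 10, t_max_s = NULL,
                                 props = default_blood_properties()) {
  config <- scenario_config(Ts, pixel_noise_C = pixel_noise_C)
  tf <- config$base_lifetime_s * (V0_ul / 11)
  if (is.null(t_max_s)) {
    t_max_s <- tf
    if (config$regime == "delayed_dome") {
      t_max_s <- max(tf, config$ma_target$break_s + 140)
    }
  }
  t <- seq(0, t_max_s, by = dt_s)
  geo <- initial_geometry(V0_ul)
  R_m <- geo$D_mm / 2 * 1e-3
  Tc <- center_temperature(config, t, t_max_s)
  target <- ma_target(config, t)
  dT <- invert_marangoni_to_deltaT(target, R_m, props, Tc)
  rec <- list(seed = seed)
  frames <- generate_thermal_frames(rec, t, dT, Tc, config)
  ecs <- edge_center_series(frames, ring_width = config$ring_width)
  traj <- marangoni_series(ecs, R_m, props)
  rates <- if (config$regime == "delayed_dome") {
    two_segment_rates(traj, config$ma_target$break_s)
  } else NULL
  list(traj = traj, rates = rates, target = target, config = config)
}

#' Validate a run configuration file
#'
#' Reads a YAML configuration and validates it against the pipeline
#' schema, collecting all problems (unknown keys, wrong types, invalid
#' values) into one error report rather than failing one key at a time.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list (fields `design`, `properties`,
#'   `analysis`, `seed`); aborts with the collected messages otherwise.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  known_top <- c("design", "properties", "analysis", "seed")
  for (k in setdiff(names(raw), known_top)) note(sprintf("unknown top-level key: `%s`", k))

  d <- raw$design %||% list()
  known_d <- c("temperatures", "replicates", "base_volume_ul", "volume_jitter")
  for (k in setdiff(names(d), known_d)) note(sprintf("design: unknown key `%s`", k))
  if (!is.null(d$replicates) &&
      (!is.numeric(d$replicates) || d$replicates < 1 || d$replicates != round(d$replicates))) {
    note("design: `replicates` must be a positive integer")
  }
  if (!is.null(d$temperatures) && (!is.numeric(d$temperatures) || length(d$temperatures) < 1)) {
    note("design: `temperatures` must be a numeric vector")
  }
  if (!is.null(d$base_volume_ul) && (!is.numeric(d$base_volume_ul) || d$base_volume_ul <= 0)) {
    note("design: `base_volume_ul` must be positive")
  }

  p <- raw$properties %||% list()
  known_p <- c("lambda", "rho", "cp", "ht", "sigma_fit")
  for (k in setdiff(names(p), known_p)) note(sprintf("properties: unknown key `%s`", k))
  for (k in c("lambda", "rho", "cp")) {
    if (!is.null(p[[k]]) && (!is.numeric(p[[k]]) || p[[k]] <= 0)) {
      note(sprintf("properties: `%s` must be positive", k))
    }
  }
  if (!is.null(p$ht) && (!is.numeric(p$ht) || p$ht < 0 || p$ht > 100)) {
    note("properties: `ht` must lie in [0, 100]")
  }
  if (!is.null(p$sigma_fit)) {
    if (!all(c("a", "b") %in% names(p$sigma_fit))) {
      note("properties: `sigma_fit` needs fields `a` and `b`")
    }
  }

  a <- raw$analysis %||% list()
  known_a <- c("alpha_mode", "include_thermal", "grid_px", "deposit_px")
  for (k in setdiff(names(a), known_a)) note(sprintf("analysis: unknown key `%s`", k))
  if (!is.null(a$alpha_mode) && !a$alpha_mode %in% c("si", "paper_numeric")) {
    note("analysis: `alpha_mode` must be \"si\" or \"paper_numeric\"")
  }

  if (!is.null(raw$seed) && !is.numeric(raw$seed)) note("`seed` must be numeric")

  if (length(errs) > 0) {
    abort(paste0("Invalid configuration:\n", paste0("  - ", errs, collapse = "\n")))
  }
  structure(list(design = d, properties = p, analysis = a,
                 seed = raw$seed %||% 1), class = "run_config")
}

#' Run the pipeline from a configuration
#'
#' Builds the design and properties from a validated configuration (a
#' `run_config` or a YAML path), runs the full study and optionally
#' writes the report bundle.
#'
#' @param config A `run_config` from [validate_config()] or a YAML path.
#' @param out_dir Optional output directory for [write_bundle()].
#' @return The `study_bundle`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "run_config"))
  d <- config$design
  design <- study_design(
    temperatures = d$temperatures %||% c(23, 37, 60, 90),
    replicates = d$replicates %||% 18,
    base_volume_ul = d$base_volume_ul %||% 11,
    volume_jitter = d$volume_jitter %||% 0.05,
    seed = config$seed
  )
  p <- config$properties
  sigma_fit <- if (!is.null(p$sigma_fit)) {
    log_fit(p$sigma_fit$a, p$sigma_fit$b)
  } else {
    default_sigma_fit()
  }
  props <- blood_properties(
    lambda = p$lambda %||% 0.52, rho = p$rho %||% 1.04873,
    cp = p$cp %||% 3617, ht = p$ht %||% 35, sigma_fit = sigma_fit
  )
  a <- config$analysis
  bundle <- run_study(design, props,
                      include_thermal = a$include_thermal %||% TRUE,
                      grid_px = a$grid_px %||% 64,
                      deposit_px = a$deposit_px %||% 128)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}
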