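#' Thermal frame series
#'
#' Container for an infrared frame stack: per-frame 2-D surface
#' temperature grids (°C) with acquisition times, pixel pitch and the
#' drop's centre/radius in pixel coordinates. Frames are stored row-major
#' with (1,1) the top-left pixel (R matrix convention); physical
#' coordinates follow from `pixel_pitch`.
#'
#' @param frames 3-D array `[row, col, frame]` of temperatures, °C, or a
#'   list of equal-shape matrices.
#' @param t Frame times, s (strictly increasing).
#' @param pixel_pitch mm per pixel.
#' @param center Drop centre, `c(row, col)` in pixels.
#' @param drop_radius Drop radius, pixels (>= 3).
#' @return An object of class `thermal_frames`.
#' @export
thermal_frames <- function(frames, t, pixel_pitch, center, drop_radius) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) abort("All frames must share one shape.")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3) abort("`frames` must be a [row, col, frame] array.")
  if (dim(frames)[3] != length(t)) abort("length(t) must match the number of frames.")
  if (is.unsorted(t, strictly = TRUE)) abort("`t` must be strictly increasing.")
  if (drop_radius < 3) abort("`drop_radius` must be >= 3 pixels.")
  if (center[1] < 1 || center[1] > dim(frames)[1] ||
      center[2] < 1 || center[2] > dim(frames)[2]) {
    abort("`center` must lie inside the grid.")
  }
  structure(
    list(frames = frames, t = t, pixel_pitch = pixel_pitch,
         center = center, drop_radius = drop_radius),
    class = "thermal_frames"
  )
}

#' @export
print.thermal_frames <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<thermal_frames> %d frames of %dx%d px, t = [%g, %g] s, pitch %g mm/px, radius %g px\n",
              d[3], d[1], d[2], min(x$t), max(x$t), x$pixel_pitch, x$drop_radius))
  invisible(x)
}

#' Centre-line temperature profile
#'
#' Extracts the temperature along the horizontal line through the drop
#' centre, spanning `radius` pixels either side — the standard
#' "profile of a line passing through the centre of the drop".
#'
#' @param frame A temperature matrix, °C.
#' @param center `c(row, col)` pixel coordinates of the drop centre.
#' @param radius Half-length of the line, pixels.
#' @return Numeric vector of length `2 * radius + 1`.
#' @export
center_line_profile <- function(frame, center, radius) {
  row <- round(center[1])
  cols <- round(center[2]) + (-radius:radius)
  if (row < 1 || row > nrow(frame) || any(cols < 1) || any(cols > ncol(frame))) {
    abort("Profile line exits the frame.")
  }
  frame[row, cols]
}

# Pixel-distance grid from a centre, in pixels
radius_grid <- function(nr, nc, center) {
  rr <- matrix(seq_len(nr), nr, nc) - center[1]
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  sqrt(rr^2 + cc^2)
}

#' Edge-centre temperature series
#'
#' Reduces a thermal frame stack to the two time series entering the
#' Marangoni number: the temperature at the triple line (TPCL) — the
#' mean over an annulus of width `ring_width` just inside the drop
#' radius — and at the centre — the mean over a disc of radius
#' `ring_width` — plus their difference
#' \eqn{\Delta T = T_{TPCL} - T_{center}}.
#'
#' @param series A `thermal_frames` object.
#' @param ring_width Sampling ring/disc width, pixels (default 2).
#' @return A tibble of class `edge_center_series` with columns
#'   `t_s, T_tpcl, T_center, dT`.
#' @export
edge_center_series <- function(series, ring_width = 2) {
  stopifnot(inherits(series, "thermal_frames"))
  d <- dim(series$frames)
  rg <- radius_grid(d[1], d[2], series$center)
  disc <- rg <= ring_width
  ann <- rg >= series$drop_radius - ring_width & rg <= series$drop_radius
  if (!any(ann)) abort("TPCL annulus is empty.")
  nt <- d[3]
  T_c <- numeric(nt); T_e <- numeric(nt)
  for (i in seq_len(nt)) {
    f <- series$frames[, , i]
    T_c[i] <- mean(f[disc])
    T_e[i] <- mean(f[ann])
  }
  out <- tibble(t_s = series$t, T_tpcl = T_e, T_center = T_c,
                dT = T_e - T_c)
  class(out) <- c("edge_center_series", class(out))
  out
}

#' Locate the triple line radius in a frame
#'
#' Azimuthally averages the frame into 1-pixel radius bins and returns
#' the radius of maximum absolute radial gradient — the thermal
#' discontinuity at the drop edge. When no clear gradient exists (for
#' example a uniform frame) the supplied `mask_radius` is returned.
#'
#' @param frame Temperature matrix, °C.
#' @param center `c(row, col)` pixels.
#' @param mask_radius Fallback radius, pixels (optional).
#' @param min_contrast Minimum radial-step contrast, °C, below which the
#'   gradient is deemed undetectable (default 0.1).
#' @return Radius in pixels.
#' @export
locate_tpcl <- function(frame, center, mask_radius = NULL, min_contrast = 0.1) {
  rg <- radius_grid(nrow(frame), ncol(frame), center)
  rmax <- floor(min(center[1] - 1, nrow(frame) - center[1],
                    center[2] - 1, ncol(frame) - center[2]))
  bins <- round(rg)
  keep <- bins <= rmax
  prof <- tapply(frame[keep], bins[keep], mean)
  r_vals <- as.numeric(names(prof))
  grad <- abs(diff(prof))
  if (length(grad) == 0 || max(grad) < min_contrast) {
    if (!is.null(mask_radius)) return(mask_radius)
    abort("No detectable radial gradient and no mask radius supplied.")
  }
  i <- which.max(grad)
  (r_vals[i] + r_vals[i + 1]) / 2
}

#' Write / read a thermal frame stack
#'
#' Frames are stored either as a directory of plain ASCII grids (one file
#' per frame, whitespace-separated, text-only) or as a multi-page TIFF
#' with temperatures min-max scaled to [0, 1]; a sidecar JSON holds the
#' times, pixel pitch, centre, radius and (for TIFF) the scaling.
#'
#' @param series A `thermal_frames`.
#' @param dir Output directory.
#' @param format `"ascii"` or `"tiff"`.
#' @return `read_thermal_frames()` returns a `thermal_frames` object.
#' @export
write_thermal_frames <- function(series, dir, format = c("ascii", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(t = series$t, pixel_pitch = series$pixel_pitch,
               center = series$center, drop_radius = series$drop_radius,
               format = format)
  nt <- dim(series$frames)[3]
  if (format == "ascii") {
    for (i in seq_len(nt)) {
      write.table(series$frames[, , i],
                  file.path(dir, sprintf("frame_%04d.txt", i)),
                  row.names = FALSE, col.names = FALSE)
    }
  } else {
    lo <- min(series$frames); hi <- max(series$frames)
    scale <- if (hi > lo) hi - lo else 1
    meta$tiff_offset <- lo
    meta$tiff_scale <- scale
    pages <- lapply(seq_len(nt), function(i) (series$frames[, , i] - lo) / scale)
    tiff::writeTIFF(pages, file.path(dir, "frames.tif"), bits.per.sample = 16L)
  }
  jsonlite::write_json(meta, file.path(dir, "frames.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_thermal_frames
#' @export
read_thermal_frames <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "frames.json"), simplifyVector = TRUE)
  if (identical(meta$format, "ascii")) {
    files <- sort(list.files(dir, pattern = "^frame_\\d+\\.txt$", full.names = TRUE))
    mats <- lapply(files, function(f) as.matrix(read.table(f)))
    mats <- lapply(mats, unname)
    frames <- array(unlist(mats), dim = c(dim(mats[[1]]), length(mats)))
  } else {
    pages <- tiff::readTIFF(file.path(dir, "frames.tif"), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    frames <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    frames <- frames * meta$tiff_scale + meta$tiff_offset
  }
  thermal_frames(frames, meta$t, meta$pixel_pitch, meta$center, meta$drop_radius)
}

#' @export
autoplot.edge_center_series <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("T_tpcl", "T_center", "dT"),
                              names_to = "series", values_to = "T_C")
  ggplot(long, aes(x = .data$t_s, y = .data$T_C, colour = .data$series)) +
    geom_line() +
    labs(x = "time (s)", y = "temperature (degC)",
         title = "TPCL / centre temperatures and their difference") +
    theme_minimal()
}
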