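#' Deposit height map
#'
#' Container for a leveled or raw height grid of a dried deposit.
#' Defaults mirror a focus-variation scan at x10: lateral pitch 1.76 um,
#' vertical resolution 0.1 um. Masked (NA or `mask == FALSE`) pixels —
#' for example no-data points inside deep cracks — are excluded from all
#' statistics.
#'
#' @param z Matrix of heights, um.
#' @param lateral_pitch um per pixel (default 1.76).
#' @param vertical_resolution um (default 0.1); metadata only.
#' @param mask Optional logical matrix of valid pixels.
#' @return An object of class `height_map`.
#' @export
height_map <- function(z, lateral_pitch = 1.76, vertical_resolution = 0.1,
                       mask = NULL) {
  if (!is.matrix(z)) abort("`z` must be a matrix.")
  if (lateral_pitch <= 0) abort("`lateral_pitch` must be positive.")
  if (is.null(mask)) mask <- !is.na(z)
  if (!identical(dim(mask), dim(z))) abort("`mask` must match `z` in shape.")
  mask <- mask & !is.na(z)
  if (any(!is.finite(z[mask]))) abort("Heights must be finite on the mask.")
  structure(
    list(z = z, lateral_pitch = lateral_pitch,
         vertical_resolution = vertical_resolution, mask = mask),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %dx%d px at %g um/px, z in [%.3g, %.3g] um (%d masked px)\n",
              nrow(x$z), ncol(x$z), x$lateral_pitch,
              min(x$z[x$mask]), max(x$z[x$mask]), sum(!x$mask)))
  invisible(x)
}

valid_heights <- function(map) map$z[map$mask]

#' Level a height map
#'
#' The standard F-operator applied before any S-parameter: subtracts
#' the least-squares plane (fit on valid pixels) so the residual surface
#' has zero mean. Idempotent.
#'
#' @param map A `height_map`.
#' @return A leveled `height_map`.
#' @export
level_surface <- function(map) {
  stopifnot(inherits(map, "height_map"))
  if (sum(map$mask) < 3) abort("Need at least 3 valid pixels to level.")
  nr <- nrow(map$z); nc <- ncol(map$z)
  xs <- matrix(seq_len(nr), nr, nc)
  ys <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  idx <- which(map$mask)
  X <- cbind(1, xs[idx], ys[idx])
  co <- qr.coef(qr(X), map$z[idx])
  co[is.na(co)] <- 0
  plane <- co[1] + co[2] * xs + co[3] * ys
  z <- map$z - plane
  z[map$mask] <- z[map$mask] - mean(z[map$mask])
  height_map(z, map$lateral_pitch, map$vertical_resolution, map$mask)
}

#' Height parameters (Sq, Sa, Sp, Sv, Sz)
#'
#' Moments and extrema of the height distribution of a leveled surface:
#' Sq (root-mean-square height), Sa (arithmetic mean height), Sp
#' (maximum peak height), Sv (maximum pit depth) and Sz = Sp + Sv
#' (maximum height).
#'
#' @param map A leveled `height_map`.
#' @return One-row tibble with `Sq, Sa, Sp, Sv, Sz` in um.
#' @export
height_params <- function(map) {
  z <- valid_heights(map)
  if (length(z) == 0) abort("Empty mask.")
  Sp <- max(z); Sv <- -min(z)
  tibble(Sq = sqrt(mean(z^2)), Sa = mean(abs(z)),
         Sp = Sp, Sv = Sv, Sz = Sp + Sv)
}

#' Abbott-Firestone (areal material ratio) curve
#'
#' The cumulative height distribution of the surface: for each height
#' `c`, the percentage of the surface at or above `c`. Monotone
#' non-increasing in `c`; the inverse lookup is [smc()].
#'
#' @param map A leveled `height_map`.
#' @param n_bins Number of material-ratio grid points (default 1000).
#' @return A tibble of class `abbott_curve` with columns `ratio_pct`
#'   (0-100) and `height` (um, the height whose material ratio is
#'   `ratio_pct`).
#' @export
abbott_curve <- function(map, n_bins = 1000) {
  z <- valid_heights(map)
  p <- seq(0, 100, length.out = n_bins + 1)
  h <- quantile(z, 1 - p / 100, names = FALSE, type = 7)
  out <- tibble(ratio_pct = p, height = h)
  class(out) <- c("abbott_curve", class(out))
  out
}

#' Material ratio at a height
#'
#' Percentage of the surface at or above height `c`.
#'
#' @param map A leveled `height_map`.
#' @param c Height, um.
#' @return Material ratio, percent.
#' @export
material_ratio <- function(map, c) {
  z <- valid_heights(map)
  vapply(c, function(ci) 100 * mean(z >= ci), numeric(1))
}

#' Inverse areal material ratio (Smc)
#'
#' Height `c` at which the surface material ratio equals `p`%; computed
#' as the `(1 - p/100)` quantile of the height distribution. Monotone
#' non-increasing in `p`.
#'
#' @param map A leveled `height_map`.
#' @param p Material ratio, percent, in (0, 100). Default 10.
#' @return Height, um.
#' @export
smc <- function(map, p = 10) {
  if (any(p <= 0 | p >= 100)) abort("`p` must lie in (0, 100).")
  z <- valid_heights(map)
  quantile(z, 1 - p / 100, names = FALSE, type = 7)
}

# Abbott curve on a fine fixed grid, as used by the functional and
# volume parameter constructions. Returns p (percent) and c(p) (um).
abbott_grid <- function(map, dp = 0.1) {
  p <- seq(0, 100, by = dp)
  h <- quantile(valid_heights(map), 1 - p / 100, names = FALSE, type = 7)
  list(p = p, c = h, dp = dp)
}

#' Functional parameters (Sk, Svk)
#'
#' Core construction of the functional parameter family: the 40%-wide
#' window of the Abbott curve with the smallest secant slope defines
#' the equivalent line (least-squares line over that window, extended
#' to 0% and 100% material ratio). Sk is the height difference of the
#' equivalent line's endpoints (core roughness). The curve's crossings
#' of those endpoint heights give Smr1/Smr2; Spk and Svk follow from
#' the triangle-equivalence rule on the areas enclosed above Smr1 and
#' below Smr2 (reduced peak height / reduced valley depth).
#'
#' @param map A leveled `height_map`.
#' @param window_pct Width of the minimum-slope window, percent
#'   (default 40, the standard's value).
#' @return One-row tibble: `Sk`, `Svk`, `Spk`, `Smr1`, `Smr2`.
#' @export
functional_params <- function(map, window_pct = 40) {
  g <- abbott_grid(map)
  if (length(unique(g$c)) < 3) {
    return(tibble(Sk = 0, Svk = 0, Spk = 0, Smr1 = 0, Smr2 = 100))
  }
  w <- round(window_pct / g$dp)
  n <- length(g$p)
  starts <- 1:(n - w)
  drops <- g$c[starts] - g$c[starts + w]
  i0 <- starts[which.min(drops)]
  idx <- i0:(i0 + w)
  line <- lm(g$c[idx] ~ g$p[idx])
  c0 <- unname(coef(line)[1])                 # equivalent line at 0%
  c100 <- unname(coef(line)[1] + coef(line)[2] * 100)
  Sk <- c0 - c100
  Smr1 <- material_ratio(map, c0)
  Smr2 <- material_ratio(map, c100)
  # peak area above c0 over [0, Smr1]; valley area below c100 over [Smr2, 100]
  above <- pmax(g$c - c0, 0)
  below <- pmax(c100 - g$c, 0)
  A1 <- sum((above[-1] + above[-n]) / 2 * g$dp)
  A2 <- sum((below[-1] + below[-n]) / 2 * g$dp)
  Spk <- if (Smr1 > 0) 2 * A1 / Smr1 else 0
  Svk <- if (Smr2 < 100) 2 * A2 / (100 - Smr2) else 0
  tibble(Sk = Sk, Svk = Svk, Spk = Spk, Smr1 = Smr1, Smr2 = Smr2)
}

#' Functional volume parameters (Vv, Vmc, Vvc)
#'
#' Void and material volumes per unit area integrated from the Abbott
#' curve: `Vv` is the void volume at material ratio `p` (volume between
#' the surface and the horizontal plane at height c(p), over the part
#' of the surface below it); `Vmc` the core material volume between the
#' ratios `p` and `q`; `Vvc = Vv(p) - Vv(q)` the core void volume.
#'
#' @param map A leveled `height_map`.
#' @param p,q Material ratios, percent (defaults 10 and 80, `p < q`).
#' @return One-row tibble `Vv, Vmc, Vvc` in um^3/um^2.
#' @export
volume_params <- function(map, p = 10, q = 80) {
  if (p >= q) abort("`p` must be smaller than `q`.")
  g <- abbott_grid(map)
  trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  void_at <- function(pp) {
    cp <- quantile(valid_heights(map), 1 - pp / 100, names = FALSE, type = 7)
    sel <- g$p >= pp
    trapz(g$p[sel], cp - g$c[sel]) / 100
  }
  mat_at <- function(pp) {
    cp <- quantile(valid_heights(map), 1 - pp / 100, names = FALSE, type = 7)
    sel <- g$p <= pp
    trapz(g$p[sel], g$c[sel] - cp) / 100
  }
  Vv <- void_at(p)
  Vmc <- mat_at(q) - mat_at(p)
  Vvc <- Vv - void_at(q)
  tibble(Vv = Vv, Vmc = Vmc, Vvc = Vvc)
}

#' Read / write height maps
#'
#' ASCII grids carry a 3-line header (`ncols`, `nrows`, `pitch_um`)
#' followed by whitespace-separated heights in um (text-only, the
#' preferred interchange format here); float TIFF is supported through
#' min-max scaling with a sidecar JSON.
#'
#' @param map A `height_map`.
#' @param path Output path (`.txt`/`.asc` for ASCII, `.tif` for TIFF).
#' @return `read_height_map()` returns a `height_map`.
#' @export
write_height_map <- function(map, path) {
  if (grepl("\\.tiff?$", path)) {
    lo <- min(map$z[map$mask]); hi <- max(map$z[map$mask])
    scale <- if (hi > lo) hi - lo else 1
    z <- map$z; z[!map$mask] <- lo
    tiff::writeTIFF((z - lo) / scale, path, bits.per.sample = 16L)
    jsonlite::write_json(
      list(pitch_um = map$lateral_pitch, vres_um = map$vertical_resolution,
           offset = lo, scale = scale),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("ncols %d", ncol(map$z)),
                 sprintf("nrows %d", nrow(map$z)),
                 sprintf("pitch_um %.12g", map$lateral_pitch)), con)
    write.table(map$z, con, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_height_map
#' @export
read_height_map <- function(path) {
  if (grepl("\\.tiff?$", path)) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    z <- tiff::readTIFF(path) * meta$scale + meta$offset
    return(height_map(z, meta$pitch_um, meta$vres_um))
  }
  hdr <- readLines(path, n = 3)
  pitch <- as.numeric(sub("pitch_um\\s+", "", hdr[3]))
  z <- unname(as.matrix(read.table(path, skip = 3)))
  height_map(z, lateral_pitch = pitch)
}

#' @export
autoplot.height_map <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$z)), col = seq_len(ncol(object$z)))
  df$z <- as.vector(object$z)
  df$z[!as.vector(object$mask)] <- NA
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$z)) +
    geom_raster() +
    scale_fill_viridis_c(name = "z (um)") +
    coord_equal() +
    labs(x = "x (px)", y = "y (px)", title = "Deposit height map") +
    theme_minimal()
}
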