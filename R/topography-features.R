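# 8-connected component labeling via an explicit pixel-adjacency graph.
# EBImage's bwlabel is 4-connected; deposit cracks and diagonal contact
# between blob patterns require 8-connectivity, so labeling is done here.
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  id <- matrix(0L, nr, nc)
  id[idx] <- seq_along(idx)

  pair_edges <- function(dr, dc) {
    rows <- seq_len(nr - abs(dr)); cols <- seq_len(nc - abs(dc))
    rA <- if (dr >= 0) rows else rows + abs(dr)
    rB <- if (dr >= 0) rows + dr else rows
    cA <- if (dc >= 0) cols else cols + abs(dc)
    cB <- if (dc >= 0) cols + dc else cols
    A <- id[rA, cA, drop = FALSE]; B <- id[rB, cB, drop = FALSE]
    ok <- A > 0L & B > 0L
    cbind(A[ok], B[ok])
  }
  edges <- do.call(rbind, list(pair_edges(1, 0), pair_edges(0, 1),
                               pair_edges(1, 1), pair_edges(1, -1)))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Feature parameters (S10z, S5v, S5p)
#'
#' Watershed segmentation of the surface into hills and dales with
#' tolerance-based merging of insignificant features (features whose
#' local relief is below `pruning` of Sz are merged with a neighbour,
#' the Wolf-pruning convention). S5p is the mean height of the five
#' highest significant peaks, S5v the mean depth of the five deepest
#' significant pits, and S10z = S5p + S5v. When fewer than five
#' significant features exist, all available ones are used and the
#' result is flagged.
#'
#' @param map A leveled `height_map`.
#' @param pruning Relief threshold as a fraction of Sz (default 0.05).
#' @return One-row tibble: `S10z, S5v, S5p, n_peaks, n_pits, flagged`.
#' @export
feature_params <- function(map, pruning = 0.05) {
  z <- map$z
  z[!map$mask] <- min(z[map$mask])
  Sz <- max(z[map$mask]) - min(z[map$mask])
  if (Sz == 0) {
    return(tibble(S10z = 0, S5v = 0, S5p = 0,
                  n_peaks = 0L, n_pits = 0L, flagged = TRUE))
  }
  tol <- pruning * Sz

  top_features <- function(field, heights) {
    # watershed basins grow from local maxima of `field`; tolerance
    # merges features with relief below `tol`
    w <- EBImage::watershed(field - min(field) + 1e-9, tolerance = tol)
    w <- as.integer(w)
    k <- max(w)
    if (k == 0) return(numeric(0))
    vapply(seq_len(k), function(i) max(heights[w == i]), numeric(1))
  }

  peaks <- top_features(z, z)
  pits <- top_features(-z, -z)
  peaks <- sort(peaks, decreasing = TRUE)
  pits <- sort(pits, decreasing = TRUE)
  S5p <- if (length(peaks)) mean(head(pmax(peaks, 0), 5)) else 0
  S5v <- if (length(pits)) mean(head(pmax(pits, 0), 5)) else 0
  tibble(S10z = S5p + S5v, S5v = S5v, S5p = S5p,
         n_peaks = length(peaks), n_pits = length(pits),
         flagged = length(peaks) < 5 || length(pits) < 5)
}

#' Segment a deposit into patterns
#'
#' Binarizes the surface at a height threshold (automatic Otsu threshold
#' by default), labels 8-connected components and discards components
#' smaller than `min_area_px` pixels. Per pattern, reports area, maximum
#' (Feret) diameter, equivalent diameter \eqn{\sqrt{4A/\pi}} and peak
#' height.
#'
#' @param map A leveled `height_map`.
#' @param threshold Height threshold in um, or `"otsu"` (default).
#' @param min_area_px Minimum component size, pixels (default 20).
#' @return A `pattern_set`: list with `labels` (integer matrix) and
#'   `table` (tibble: `id, area_um2, dmax_um, deq_um, peak_um, n_px`).
#' @export
segment_patterns <- function(map, threshold = "otsu", min_area_px = 20) {
  z <- map$z
  zv <- z[map$mask]
  if (identical(threshold, "otsu")) {
    lo <- min(zv); hi <- max(zv)
    if (hi <= lo) abort("Flat surface: no pattern survives thresholding.")
    zn <- matrix(0, nrow(z), ncol(z))
    zn[map$mask] <- (zv - lo) / (hi - lo)
    threshold <- lo + EBImage::otsu(EBImage::Image(zn)) * (hi - lo)
  }
  bw <- map$mask & z >= threshold
  lab <- label_components_8(bw)
  if (max(lab) == 0) abort("No pattern survives thresholding.")
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area_px)
  if (length(keep) == 0) abort("No pattern survives the minimum-area filter.")

  pitch <- map$lateral_pitch
  out_lab <- matrix(0L, nrow(z), ncol(z))
  rows <- lapply(seq_along(keep), function(new_id) {
    old <- keep[new_id]
    px <- which(lab == old, arr.ind = TRUE)
    out_lab[px] <<- new_id
    hull <- tryCatch(grDevices::chull(px[, 1], px[, 2]), error = function(e) seq_len(nrow(px)))
    hp <- px[hull, , drop = FALSE]
    dmax <- sqrt(max(as.vector(stats::dist(hp))^2, 0)) * pitch
    area <- nrow(px) * pitch^2
    tibble(id = new_id, area_um2 = area, dmax_um = dmax,
           deq_um = sqrt(4 * area / pi), peak_um = max(z[lab == old]),
           n_px = nrow(px))
  })
  structure(list(labels = out_lab, table = list_rbind(rows), pitch = pitch),
            class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d patterns, pitch %g um/px\n", nrow(x$table), x$pitch))
  print(x$table)
  invisible(x)
}

# Minimum pixel distance between boundary pixels of two labelled patterns
pattern_boundaries <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  is_bnd <- core > 0 &
    (pad[1:nr, 2:(nc + 1)] != core | pad[3:(nr + 2), 2:(nc + 1)] != core |
       pad[2:(nr + 1), 1:nc] != core | pad[2:(nr + 1), 3:(nc + 2)] != core)
  px <- which(is_bnd, arr.ind = TRUE)
  split.data.frame(px, core[is_bnd])
}

#' Pattern (particle) parameters
#'
#' Sample means over all patterns of three descriptors: circularity
#' (pattern area over the area of the disc whose diameter is the
#' pattern's maximum diameter), compactness (equivalent over maximum
#' diameter) and coplanarity (maximum vertical distance between a
#' pattern's peak and the peaks of its neighbours). Neighbourhood is
#' boundary proximity within `neighbor_dist_px` pixels; an isolated
#' pattern is paired with its nearest pattern.
#'
#' @param patterns A `pattern_set`.
#' @param neighbor_dist_px Neighbour search distance, pixels (default 5).
#' @return One-row tibble: `coplanarity` (um), `circularity`,
#'   `compactness` (both dimensionless in (0, 1]).
#' @export
pattern_params <- function(patterns, neighbor_dist_px = 5) {
  tab <- patterns$table
  k <- nrow(tab)
  if (k == 0) abort("Empty pattern set.")
  circ <- pmin(tab$area_um2 / (pi * (tab$dmax_um / 2)^2), 1)
  comp <- pmin(tab$deq_um / tab$dmax_um, 1)

  copl <- 0
  if (k > 1) {
    bnd <- pattern_boundaries(patterns$labels)
    bnd <- bnd[order(as.numeric(names(bnd)))]
    mind <- matrix(Inf, k, k)
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        a <- as.matrix(bnd[[i]]); b <- as.matrix(bnd[[j]])
        d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
        mind[i, j] <- mind[j, i] <- sqrt(min(d2))
      }
    }
    copl_i <- vapply(seq_len(k), function(i) {
      nb <- which(mind[i, ] <= neighbor_dist_px)
      if (length(nb) == 0) nb <- which.min(mind[i, ])
      max(abs(tab$peak_um[i] - tab$peak_um[nb]))
    }, numeric(1))
    copl <- mean(copl_i)
  }
  tibble(coplanarity = copl,
         circularity = mean(circ), compactness = mean(comp))
}

#' Full areal texture report
#'
#' Levels the map and computes the 16 selected texture parameters:
#' height (Sq, Sp, Sv, Sz, Sa), inverse material ratio (Smc at 10%),
#' feature (S10z, S5v), functional (Sk, Svk), volume (Vv, Vmc, Vvc) and
#' pattern (coplanarity, circularity, compactness) parameters.
#' Deterministic given the map and settings. When no pattern survives
#' segmentation (a flat or featureless surface) the three pattern
#' parameters are `NA` and `n_patterns = 0`.
#'
#' @param map A `height_map` (raw; leveling is applied here).
#' @param smc_p Material ratio for Smc, percent (default 10).
#' @param vol_p,vol_q Material ratios for the volume parameters
#'   (defaults 10 and 80).
#' @param pattern_threshold Threshold for [segment_patterns()]
#'   (default `"otsu"`).
#' @param pruning Feature-pruning fraction of Sz (default 0.05).
#' @return One-row tibble with the 16 parameters (um where dimensional)
#'   plus bookkeeping columns `n_patterns`, `features_flagged`.
#' @export
full_report <- function(map, smc_p = 10, vol_p = 10, vol_q = 80,
                        pattern_threshold = "otsu", pruning = 0.05) {
  lv <- level_surface(map)
  hp <- height_params(lv)
  fp <- functional_params(lv)
  vp <- volume_params(lv, p = vol_p, q = vol_q)
  ft <- feature_params(lv, pruning = pruning)
  pats <- tryCatch(segment_patterns(lv, threshold = pattern_threshold),
                   error = function(e) NULL)
  pp <- if (is.null(pats)) {
    tibble(coplanarity = NA_real_, circularity = NA_real_, compactness = NA_real_)
  } else {
    pattern_params(pats)
  }
  tibble(
    Sq = hp$Sq, Sp = hp$Sp, Sv = hp$Sv, Sz = hp$Sz, Sa = hp$Sa,
    Smc = smc(lv, p = smc_p),
    S10z = ft$S10z, S5v = ft$S5v,
    Sk = fp$Sk, Svk = fp$Svk,
    Vv = vp$Vv, Vmc = vp$Vmc, Vvc = vp$Vvc,
    coplanarity = pp$coplanarity, circularity = pp$circularity,
    compactness = pp$compactness,
    n_patterns = if (is.null(pats)) 0L else nrow(pats$table),
    features_flagged = ft$flagged
  )
}

#' Names of the 16 selected texture parameters
#' @return Character vector, in report order.
#' @export
texture_parameter_names <- function() {
  c("Sq", "Sp", "Sv", "Sz", "Sa", "Smc", "S10z", "S5v", "Sk", "Svk",
    "Vv", "Vmc", "Vvc", "coplanarity", "circularity", "compactness")
}
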