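# Sub-window machinery for the local Pearson correlation coefficient (LPCC).
# A slice is partitioned into square tiles (default 8 x 8 pixels; edge tiles
# may be smaller). Tiles are classified from the brain mask as
# background-only (S_b), tissue-only (S_t) or mixed (S_bt); tissue-containing
# tiles share equal weight 1/(L - N_b) and background-only tiles weight 0,
# and the LPCC is the weighted sum of per-tile Pearson coefficients between
# the object slice and the b0 reference slice.

#' Pearson correlation between two pixel regions
#'
#' Plain Pearson correlation with one deliberate departure: if either region
#' has zero variance the coefficient is defined as 0 rather than NA, so that
#' signal-destroyed (flat) tiles score as uncorrelated instead of undefined.
#'
#' @param region_a,region_b numeric vectors/matrices of identical shape with
#'   at least 2 pixels.
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(region_a, region_b) {
  if (length(region_a) != length(region_b)) stop("regions must have the same shape")
  if (length(region_a) < 2) stop("regions need at least 2 pixels")
  a <- as.vector(region_a) - mean(region_a)
  b <- as.vector(region_b) - mean(region_b)
  va <- sum(a * a); vb <- sum(b * b)
  if (va <= 0 || vb <= 0) return(0)
  sum(a * b) / sqrt(va * vb)
}

#' Partition a slice into sub-windows and classify them against the mask
#'
#' @param mask_slice binary matrix (tissue = 1).
#' @param window square sub-window size in pixels (>= 2).
#' @return a `subwindow_grid`: list with `tile_id` (integer matrix mapping
#'   each pixel to its tile), `class` (per-tile factor `S_b`/`S_t`/`S_bt`),
#'   `N_b` (background-only count), `L` (tile count) and `window`.
#' @export
classify_tiles <- function(mask_slice, window = 8) {
  stopifnot(window >= 2)
  n1 <- nrow(mask_slice); n2 <- ncol(mask_slice)
  bi <- ceiling(seq_len(n1) / window)
  bj <- ceiling(seq_len(n2) / window)
  nbi <- max(bi)
  tile_id <- matrix(bi, n1, n2) + (matrix(bj, n1, n2, byrow = TRUE) - 1L) * nbi
  L <- nbi * max(bj)
  group <- as.vector(tile_id)
  n_px <- tabulate(group, L)  # every tile holds >= 1 pixel: partition
  frac <- as.vector(rowsum(as.numeric(mask_slice > 0), group)) / n_px
  cls <- ifelse(frac == 0, "S_b", ifelse(frac == 1, "S_t", "S_bt"))
  structure(list(tile_id = tile_id, group = group, n_px = n_px,
                 class = as.vector(cls),
                 N_b = sum(cls == "S_b"), L = L, window = window),
            class = "subwindow_grid")
}

#' Per-tile weights for the LPCC
#'
#' Background-only tiles get weight 0; every tissue-containing tile (S_t or
#' S_bt) gets the equal weight `1/(L - N_b)`, so the weights sum to 1.
#'
#' @param grid a [classify_tiles()] result.
#' @return numeric vector of per-tile weights (tile order).
#' @export
tile_weights <- function(grid) {
  if (grid$L == grid$N_b) stop("slice contains no tissue tiles: nothing to score")
  w <- rep(0, grid$L)
  w[grid$class != "S_b"] <- 1 / (grid$L - grid$N_b)
  w
}

#' Local Pearson correlation coefficient between a DWI slice and a reference
#'
#' `lpcc = sum_tiles w_tile * pearson(object_tile, reference_tile)` with the
#' weighting of [tile_weights()]. Mixed tiles use all their pixels
#' (background included): the tissue/background edge itself carries
#' alignment information.
#'
#' @param object_slice,reference_slice numeric matrices of identical shape.
#' @param mask_slice binary tissue mask of the same shape.
#' @param window sub-window size in pixels (default 8).
#' @param grid optionally, a precomputed [classify_tiles()] grid (must match
#'   `mask_slice`); avoids reclassification in tight loops.
#' @param ref_stats precomputed reference tile statistics (internal use).
#' @return the LPCC (<= 1).
#' @export
lpcc <- function(object_slice, reference_slice, mask_slice, window = 8,
                 grid = NULL, ref_stats = NULL) {
  if (!all(dim(object_slice) == dim(reference_slice))) stop("slice shapes differ")
  if (is.null(grid)) grid <- classify_tiles(mask_slice, window)
  w <- tile_weights(grid)
  r <- tile_pearson(object_slice, reference_slice, grid, ref_stats)
  sum(w * r)
}

# Vectorized per-tile Pearson from sufficient statistics. Reference-side
# statistics can be precomputed with tile_ref_stats() when many object
# slices are scored against the same reference.
tile_pearson <- function(object_slice, reference_slice, grid, ref_stats = NULL) {
  x <- as.vector(object_slice)
  n <- grid$n_px; id <- grid$group
  if (is.null(ref_stats)) ref_stats <- tile_ref_stats(reference_slice, grid)
  y <- ref_stats$y
  sx <- rowsum(x, id); sxx <- rowsum(x * x, id); sxy <- rowsum(x * y, id)
  vx <- sxx - sx^2 / n
  vy <- ref_stats$vy
  cv <- sxy - sx * ref_stats$sy / n
  r <- numeric(grid$L)
  ok <- vx > 0 & vy > 0
  r[ok] <- cv[ok] / sqrt(vx[ok] * vy[ok])
  pmin(pmax(r, -1), 1)
}

tile_ref_stats <- function(reference_slice, grid) {
  y <- as.vector(reference_slice)
  sy <- rowsum(y, grid$group)
  syy <- rowsum(y * y, grid$group)
  list(y = y, sy = sy, vy = syy - sy^2 / grid$n_px)
}

#' Global normalized correlation coefficient (NCC) for a slice
#'
#' The conventional baseline: a single Pearson coefficient over all pixels of
#' the brain bounding box of the slice.
#'
#' @inheritParams lpcc
#' @return the NCC in `[-1, 1]` (0 if either image is flat).
#' @export
ncc <- function(object_slice, reference_slice, mask_slice) {
  if (!all(dim(object_slice) == dim(reference_slice))) stop("slice shapes differ")
  idx <- which(mask_slice > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("slice contains no tissue: nothing to score")
  ri <- range(idx[, 1]); rj <- range(idx[, 2])
  pearson(object_slice[ri[1]:ri[2], rj[1]:rj[2]],
          reference_slice[ri[1]:ri[2], rj[1]:rj[2]])
}
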