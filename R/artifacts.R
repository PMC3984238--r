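#' Describe one motion-artifact event
#'
#' @param kind one of `"complete_loss"` (whole-slice signal dropout),
#'   `"local_loss"` (dropout in a contiguous in-slice region),
#'   `"mismatch"` (integer in-plane translation of one slice) or
#'   `"volume_misalignment"` (rigid in-plane rotation + translation of a
#'   whole volume).
#' @param volume_index measurement volume affected (1-based).
#' @param slice_index axial slice affected (ignored for
#'   `volume_misalignment`).
#' @param magnitude severity. For `complete_loss`/`local_loss`: residual
#'   tissue-signal scale in `[0, 0.1]` (0 = full dropout). For `mismatch`:
#'   unused. For `volume_misalignment`: rotation angle in degrees.
#' @param geometry kind-specific descriptor. `local_loss`: fraction of the
#'   slice's tissue area covered by the lost region (default 0.3).
#'   `mismatch`: integer pixel offset `c(dx, dy)` (default `c(6, 0)`).
#'   `volume_misalignment`: translation in pixels `c(dx, dy)` (default
#'   `c(2, 2)`).
#' @return an `artifact_event` object.
#' @export
artifact_event <- function(kind = c("complete_loss", "local_loss", "mismatch",
                                    "volume_misalignment"),
                           volume_index, slice_index = NA_integer_,
                           magnitude = 0, geometry = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("complete_loss", "local_loss")) {
    if (magnitude < 0 || magnitude > 0.1) {
      stop("signal-loss magnitude must lie in [0, 0.1] (residual signal scale)")
    }
  }
  if (is.null(geometry)) {
    geometry <- switch(kind,
      complete_loss = NULL,
      local_loss = 0.3,
      mismatch = c(6L, 0L),
      volume_misalignment = c(2, 2))
  }
  structure(list(kind = kind, volume_index = as.integer(volume_index),
                 slice_index = as.integer(slice_index),
                 magnitude = magnitude, geometry = geometry),
            class = "artifact_event")
}

#' Inject motion artifacts into a DWI dataset
#'
#' Signal-loss artifacts are applied post-noise: the affected tissue signal
#' is attenuated and re-passed through the magnitude (Rician) channel so that
#' the noise floor survives, mimicking real dropout slices where only
#' background noise remains. `mismatch` translates one slice by an integer
#' offset; `volume_misalignment` applies a rigid in-plane transform to every
#' slice of a volume (bilinear resampling, zero fill).
#'
#' @param dataset a `dwi_dataset`.
#' @param events list of [artifact_event()]s.
#' @param seed seed for the re-noising of signal-loss regions.
#' @param allow_b0 allow events on b0 volumes (needed to test b0 reference
#'   screening); off by default.
#' @return the modified dataset, with a `truth_labels` tibble attached
#'   (`volume`, `slice`, `kind`) listing every affected (volume, slice) pair;
#'   clean pairs are absent from the table.
#' @export
inject_artifacts <- function(dataset, events, seed = 1L, allow_b0 = FALSE) {
  d <- dim(dataset$data)
  labels <- list()
  seen <- character()
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  for (ev in events) {
    stopifnot(inherits(ev, "artifact_event"))
    if (ev$volume_index < 1 || ev$volume_index > d[4]) stop("volume_index out of bounds")
    if (!allow_b0 && dataset$grad$bval[ev$volume_index] == 0) {
      stop("event targets a b0 reference volume; set allow_b0 = TRUE if intended")
    }
    slices <- if (ev$kind == "volume_misalignment") seq_len(d[3]) else ev$slice_index
    if (ev$kind != "volume_misalignment" &&
        (is.na(ev$slice_index) || ev$slice_index < 1 || ev$slice_index > d[3])) {
      stop("slice_index out of bounds")
    }
    key <- paste(ev$volume_index, slices)
    if (any(key %in% seen)) stop("overlapping artifact events on one (volume, slice)")
    seen <- c(seen, key)

    for (z in slices) {
      sl <- dataset$data[, , z, ev$volume_index]
      msl <- dataset$mask[, , z] > 0
      sl <- switch(ev$kind,
        complete_loss = attenuate_region(sl, msl, ev$magnitude, dataset$sigma),
        local_loss = attenuate_region(sl, msl & local_region(msl, ev$geometry),
                                      ev$magnitude, dataset$sigma),
        mismatch = shift_slice(sl, ev$geometry),
        volume_misalignment = rigid_resample(sl, ev$magnitude, ev$geometry))
      dataset$data[, , z, ev$volume_index] <- sl
      labels[[length(labels) + 1]] <-
        tibble::tibble(volume = ev$volume_index, slice = z, kind = ev$kind)
    }
  }
  dataset$truth_labels <- if (length(labels)) dplyr::bind_rows(labels) else
    tibble::tibble(volume = integer(), slice = integer(), kind = character())
  dataset
}

# Scale the signal in `region` by `magnitude` and re-apply the magnitude
# noise channel so the noise floor remains.
attenuate_region <- function(slice, region, magnitude, sigma) {
  v <- magnitude * slice[region]
  if (sigma > 0) v <- rician(v, sigma)
  slice[region] <- v
  slice
}

# Contiguous disc covering `fraction` of the slice's tissue area, grown
# around a random tissue pixel.
local_region <- function(mask_slice, fraction) {
  idx <- which(mask_slice, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("local_loss on a slice with no tissue")
  center <- idx[sample.int(nrow(idx), 1), ]
  d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2
  n_target <- max(1L, round(fraction * nrow(idx)))
  keep <- idx[order(d2)[seq_len(n_target)], , drop = FALSE]
  out <- matrix(FALSE, nrow(mask_slice), ncol(mask_slice))
  out[keep] <- TRUE
  out
}

# Integer translation with zero fill.
shift_slice <- function(slice, offset) {
  dx <- as.integer(offset[1]); dy <- as.integer(offset[2])
  n1 <- nrow(slice); n2 <- ncol(slice)
  out <- matrix(0, n1, n2)
  src_i <- seq_len(n1) - dx
  src_j <- seq_len(n2) - dy
  ok_i <- src_i >= 1 & src_i <= n1
  ok_j <- src_j >= 1 & src_j <= n2
  out[ok_i, ok_j] <- slice[src_i[ok_i], src_j[ok_j]]
  out
}

# Rigid in-plane rotation (degrees, about the slice center) plus translation,
# bilinear interpolation, zero fill.
rigid_resample <- function(slice, angle_deg, translation) {
  n1 <- nrow(slice); n2 <- ncol(slice)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ci <- (n1 + 1) / 2; cj <- (n2 + 1) / 2
  gi <- matrix(seq_len(n1), n1, n2) - ci
  gj <- matrix(seq_len(n2), n1, n2, byrow = TRUE) - cj
  # inverse map: output pixel -> source coordinate
  si <- ct * gi + st * gj + ci - translation[1]
  sj <- -st * gi + ct * gj + cj - translation[2]
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2
    out <- numeric(length(ii))
    out[ok] <- slice[cbind(ii[ok], jj[ok])]
    out
  }
  v <- (1 - fi) * (1 - fj) * val(i0, j0) +
    fi * (1 - fj) * val(i0 + 1, j0) +
    (1 - fi) * fj * val(i0, j0 + 1) +
    fi * fj * val(i0 + 1, j0 + 1)
  matrix(v, n1, n2)
}
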