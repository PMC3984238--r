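#' Normalize a group of correlation scores by its maximum
#'
#' Scores within one (slice, shell) group are divided by the group maximum,
#' so the best-matching direction scores exactly 1.
#'
#' @param scores numeric vector (one group).
#' @return normalized scores.
#' @export
normalize_scores <- function(scores) {
  if (length(scores) == 0) stop("empty score group")
  m <- max(scores)
  if (m <= 0) stop("group maximum is not positive: whole group corrupt, slice unusable")
  scores / m
}

#' Mean - 3 SD rejection threshold for normalized scores
#'
#' @param normalized_scores one (slice, shell) group of normalized scores.
#' @param nsigma multiplier on the standard deviation (default 3).
#' @return the threshold `mean - nsigma * sd`; scores strictly below it are
#'   rejected (ties kept).
#' @export
rejection_threshold <- function(normalized_scores, nsigma = 3) {
  if (length(normalized_scores) < 3) stop("need at least 3 scores to set a threshold")
  mean(normalized_scores) - nsigma * sd(normalized_scores)
}

#' Relative difference between an artifact-free and an artifact coefficient
#'
#' `(coef_free - coef_artifact) / coef_free`: the statistic used to compare
#' how strongly LPCC and NCC react to the same artifact.
#'
#' @param coef_artifact_free,coef_artifact correlation coefficients.
#' @return the relative difference.
#' @export
relative_difference <- function(coef_artifact_free, coef_artifact) {
  if (any(coef_artifact_free == 0)) stop("artifact-free coefficient must be nonzero")
  (coef_artifact_free - coef_artifact) / coef_artifact_free
}

#' Screen b0 volumes and build the per-slice b0 reference
#'
#' Each b0 slice is scored by its mean LPCC against the other b0 slices;
#' scores are normalized by their maximum and each b0 is excluded when it
#' falls below the `mean - nsigma*sd` threshold of the *other* b0s'
#' scores (leave-one-out: with as few as 5 b0 volumes, a threshold that
#' includes the outlier itself can never be exceeded — the largest possible
#' z-score among n values is (n-1)/sqrt(n)). Surviving b0 slices are
#' voxel-averaged into the reference.
#'
#' @param dataset a `dwi_dataset` (or plain list with `data`, `grad`,
#'   `mask`).
#' @param window LPCC sub-window size in pixels.
#' @param nsigma threshold factor.
#' @return list with `reference` (3D array, one reference slice per axial
#'   slice) and `kept` (tibble: `slice`, `volume`, `score_norm`, `kept`).
#' @export
select_b0_reference <- function(dataset, window = 8, nsigma = 3) {
  b0_vols <- dataset$grad$volume[dataset$grad$bval == 0]
  if (length(b0_vols) < 2) stop("need at least 2 b0 volumes")
  d <- dim(dataset$data)
  reference <- array(NA_real_, d[1:3])
  rows <- list()
  for (z in seq_len(d[3])) {
    msl <- dataset$mask[, , z]
    if (!any(msl > 0)) next
    grid <- classify_tiles(msl, window)
    slices <- lapply(b0_vols, function(v) dataset$data[, , z, v])
    nb <- length(b0_vols)
    pm <- matrix(1, nb, nb)
    for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
      pm[i, j] <- pm[j, i] <- lpcc(slices[[i]], slices[[j]], msl, grid = grid)
    }
    score <- (rowSums(pm) - 1) / (nb - 1)  # mean LPCC against the others
    sn <- normalize_scores(score)
    keep <- vapply(seq_len(nb), function(i) {
      if (nb < 4) return(TRUE)  # leave-one-out sd needs >= 3 others
      thr <- mean(sn[-i]) - nsigma * sd(sn[-i])
      !(sn[i] < thr)
    }, logical(1))
    if (!any(keep)) stop(sprintf("all b0 volumes rejected at slice %d: dataset unusable", z))
    reference[, , z] <- Reduce(`+`, slices[keep]) / sum(keep)
    rows[[z]] <- tibble::tibble(slice = z, volume = b0_vols,
                                score_norm = sn, kept = keep)
  }
  list(reference = reference, kept = dplyr::bind_rows(rows))
}

#' Slice-wise motion-artifact QC for a DKI dataset
#'
#' Builds the b0 reference via [select_b0_reference()], scores every
#' (slice, shell, direction) measurement slice with the LPCC and the global
#' NCC against the reference slice, normalizes both per (slice, shell)
#' group by the group maximum, and rejects measurements whose normalized
#' LPCC falls strictly below the `mean - nsigma*sd` group threshold.
#'
#' @param dataset a `dwi_dataset`.
#' @param window sub-window size in pixels (default 8).
#' @param nsigma threshold factor (default 3).
#' @return a `qc_report`: list with `scores` (tibble: `slice`, `bval`,
#'   `shell`, `direction_index`, `volume`, `lpcc`, `ncc`, `lpcc_norm`,
#'   `ncc_norm`, `threshold`, `rejected`), `b0` (the b0 screening tibble),
#'   `reference` (3D array) and the parameters used.
#' @export
run_qc <- function(dataset, window = 8, nsigma = 3) {
  grad <- dataset$grad
  if (!any(grad$bval > 0)) stop("dataset has no nonzero shell")
  ref <- select_b0_reference(dataset, window, nsigma)
  d <- dim(dataset$data)
  dwi <- grad[grad$bval > 0, ]
  rows <- vector("list", d[3])
  for (z in seq_len(d[3])) {
    msl <- dataset$mask[, , z]
    if (!any(msl > 0)) next
    grid <- classify_tiles(msl, window)
    refsl <- ref$reference[, , z]
    rstats <- tile_ref_stats(refsl, grid)
    idxm <- which(msl > 0, arr.ind = TRUE)
    ri <- range(idxm[, 1]); rj <- range(idxm[, 2])
    refbox <- refsl[ri[1]:ri[2], rj[1]:rj[2]]
    lp <- nc <- numeric(nrow(dwi))
    for (k in seq_len(nrow(dwi))) {
      obj <- dataset$data[, , z, dwi$volume[k]]
      lp[k] <- lpcc(obj, refsl, msl, grid = grid, ref_stats = rstats)
      nc[k] <- pearson(obj[ri[1]:ri[2], rj[1]:rj[2]], refbox)
    }
    rows[[z]] <- tibble::tibble(slice = z, bval = dwi$bval, shell = dwi$shell,
                                direction_index = dwi$dir_index,
                                volume = dwi$volume, lpcc = lp, ncc = nc)
  }
  scores <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$slice, .data$shell) |>
    dplyr::mutate(lpcc_norm = normalize_scores(.data$lpcc),
                  ncc_norm = normalize_scores(.data$ncc),
                  threshold = rejection_threshold(.data$lpcc_norm, nsigma),
                  rejected = .data$lpcc_norm < .data$threshold) |>
    dplyr::ungroup()
  structure(list(scores = scores, b0 = ref$kept, reference = ref$reference,
                 window = window, nsigma = nsigma),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d slice-measurements scored (window %d, %g sigma)\n",
              nrow(x$scores), x$window, x$nsigma))
  cat(sprintf("  rejected: %d (%.2f%%); b0 volumes excluded: %d\n",
              sum(x$scores$rejected), 100 * mean(x$scores$rejected),
              sum(!x$b0$kept)))
  invisible(x)
}

#' Tidy a QC report into one row per scored slice-measurement
#' @param x a `qc_report`.
#' @param ... unused.
#' @return the scores tibble.
#' @export
tidy.qc_report <- function(x, ...) x$scores

#' One-row summary of a QC report
#' @param x a `qc_report`.
#' @param ... unused.
#' @return tibble with rejection counts and rates.
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(n_scored = nrow(x$scores),
                 n_rejected = sum(x$scores$rejected),
                 rejection_rate = mean(x$scores$rejected),
                 n_b0_excluded = sum(!x$b0$kept),
                 window = x$window, nsigma = x$nsigma)
}
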