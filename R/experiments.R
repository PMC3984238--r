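# Seeded experiments packaging the package's validation studies: detector
# sensitivity/specificity over replicate phantoms, and the paired
# LPCC-versus-NCC relative-difference comparison.

#' Detector validation over seeded phantom replicates
#'
#' For each seed, renders a phantom, injects `n_complete` complete-loss and
#' `n_local` local-loss slices on distinct (slice, shell) groups (scattered
#' motion events; two artifacts inside one 25-direction group inflate that
#' group's SD and can mask each other — a genuine limitation of the
#' mean - 3 SD rule that this experiment does not conflate with
#' single-event sensitivity), runs the QC, and tallies detections against
#' the injected truth labels.
#'
#' @param config a [phantom_config()].
#' @param seeds integer vector of replicate seeds.
#' @param n_complete,n_local events per phantom.
#' @param magnitude_range residual-signal range the event magnitudes are
#'   drawn from (within the complete-loss definition `[0, 0.1]`).
#' @param local_fraction tissue fraction covered by each local-loss region.
#' @param window,nsigma QC parameters.
#' @return list with `by_kind` (tibble: `kind`, `n_injected`, `n_detected`,
#'   `sensitivity`), `false_positive_rate`, and `detail` (per-event tibble).
#' @export
detector_experiment <- function(config, seeds = 1:10, n_complete = 5,
                                n_local = 5, magnitude_range = c(0, 0.1),
                                local_fraction = 0.3,
                                window = 8, nsigma = 3) {
  detail <- list(); n_clean <- 0; n_fp <- 0
  for (s in seeds) {
    cfg <- config; cfg$seed <- as.integer(s)
    ph <- render_phantom(cfg)
    old <- .Random.seed_get()
    set.seed(s + 17L)
    n_ev <- n_complete + n_local
    shells <- unique(ph$grad$shell[ph$grad$shell > 0])
    groups <- tidyr::expand_grid(slice = seq_len(dim(ph$data)[3]),
                                 shell = shells)
    pick <- groups[sample.int(nrow(groups), n_ev), ]
    vols <- vapply(pick$shell, function(sh) {
      sample(ph$grad$volume[ph$grad$shell == sh], 1)
    }, numeric(1))
    mags <- runif(n_ev, magnitude_range[1], magnitude_range[2])
    .Random.seed_set(old)
    ev <- purrr::map(seq_len(n_ev), function(k) {
      artifact_event(if (k <= n_complete) "complete_loss" else "local_loss",
                     volume_index = vols[k], slice_index = pick$slice[k],
                     magnitude = mags[k],
                     geometry = if (k <= n_complete) NULL else local_fraction)
    })
    ph <- inject_artifacts(ph, ev, seed = s + 31L)
    qc <- run_qc(ph, window = window, nsigma = nsigma)
    sc <- qc$scores
    truth <- ph$truth_labels
    key <- paste(sc$volume, sc$slice)
    tkey <- paste(truth$volume, truth$slice)
    hit <- tkey %in% key[sc$rejected]
    detail[[length(detail) + 1]] <-
      dplyr::mutate(truth, seed = s, detected = hit)
    clean <- !(key %in% tkey)
    n_clean <- n_clean + sum(clean)
    n_fp <- n_fp + sum(sc$rejected[clean])
  }
  detail <- dplyr::bind_rows(detail)
  by_kind <- detail |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(n_injected = dplyr::n(), n_detected = sum(.data$detected),
                     sensitivity = mean(.data$detected), .groups = "drop")
  list(by_kind = by_kind, false_positive_rate = n_fp / n_clean,
       n_clean = n_clean, detail = detail)
}

#' Paired LPCC-versus-NCC relative-difference comparison
#'
#' Reproduces, on synthetic data, the comparison of how strongly the two
#' coefficients react to the same artifact. For each pair a (slice, shell)
#' group is drawn, an artifact is injected into one of its directions, all
#' 25 directions are scored against the b0 reference with both
#' coefficients, scores are normalized per group by their maximum, and the
#' relative difference between the artifact image and its best-scoring
#' artifact-free partner is recorded for each coefficient.
#'
#' @param dataset a clean `dwi_dataset` (rendered phantom).
#' @param n_pairs number of artifact/artifact-free pairs.
#' @param kind artifact kind injected: `"mixed"` (default; equal thirds of
#'   complete loss, local loss and mismatch, matching the taxonomy seen in
#'   motion-corrupted acquisitions) or a single kind.
#' @param seed seed for pair sampling and injection.
#' @param window LPCC sub-window size.
#' @param local_fraction tissue fraction of the local-loss region.
#' @return list with `pairs` (tibble: `pair`, `slice`, `bval`, `kind`,
#'   `rd_lpcc`, `rd_ncc`), and the one-sided paired Wilcoxon signed-rank
#'   test (`p_value`, `statistic`) of `rd_lpcc > rd_ncc`.
#' @export
relative_difference_experiment <- function(dataset, n_pairs = 30,
                                           kind = c("mixed", "local_loss",
                                                    "mismatch", "complete_loss"),
                                           seed = 1L,
                                           window = 8, local_fraction = 0.3) {
  kind <- match.arg(kind)
  ref <- select_b0_reference(dataset, window = window)
  grad <- dataset$grad
  shells <- unique(grad$shell[grad$shell > 0])
  nz <- dim(dataset$data)[3]
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  kinds <- if (kind == "mixed") {
    rep_len(c("complete_loss", "local_loss", "mismatch"), n_pairs)
  } else rep(kind, n_pairs)
  draws <- tibble::tibble(slice = sample.int(nz, n_pairs, replace = TRUE),
                          shell = sample(shells, n_pairs, replace = TRUE),
                          kind = kinds,
                          magnitude = runif(n_pairs, 0, 0.1))
  rows <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    z <- draws$slice[k]; sh <- draws$shell[k]
    grp <- grad[grad$shell == sh, ]
    d_art <- sample.int(nrow(grp), 1)
    msl <- dataset$mask[, , z]
    grid <- classify_tiles(msl, window)
    refsl <- ref$reference[, , z]
    rstats <- tile_ref_stats(refsl, grid)
    idxm <- which(msl > 0, arr.ind = TRUE)
    ri <- range(idxm[, 1]); rj <- range(idxm[, 2])
    lp <- nc <- numeric(nrow(grp))
    for (j in seq_len(nrow(grp))) {
      obj <- dataset$data[, , z, grp$volume[j]]
      if (j == d_art) {
        obj <- switch(draws$kind[k],
          complete_loss = attenuate_region(obj, msl > 0, draws$magnitude[k],
                                           dataset$sigma),
          local_loss = attenuate_region(
            obj, (msl > 0) & local_region(msl > 0, local_fraction),
            draws$magnitude[k], dataset$sigma),
          mismatch = shift_slice(obj, c(6, 0)))
      }
      lp[j] <- lpcc(obj, refsl, msl, grid = grid, ref_stats = rstats)
      nc[j] <- pearson(obj[ri[1]:ri[2], rj[1]:rj[2]],
                       refsl[ri[1]:ri[2], rj[1]:rj[2]])
    }
    lpn <- normalize_scores(lp); ncn <- normalize_scores(nc)
    free <- which.max(replace(lpn, d_art, -Inf))
    tibble::tibble(pair = k, slice = z, bval = grp$bval[1],
                   kind = draws$kind[k],
                   rd_lpcc = relative_difference(lpn[free], lpn[d_art]),
                   rd_ncc = relative_difference(ncn[free], ncn[d_art]))
  })
  wt <- wilcox.test(rows$rd_lpcc, rows$rd_ncc, paired = TRUE,
                    alternative = "greater", exact = FALSE)
  list(pairs = rows, p_value = wt$p.value, statistic = unname(wt$statistic),
       median_rd_lpcc = median(rows$rd_lpcc),
       median_rd_ncc = median(rows$rd_ncc))
}
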