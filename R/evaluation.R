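#' Mean squared error between two parameter maps over a region
#'
#' `(1/n) * sum (estimate - reference)^2` over the region's voxels; voxels
#' where either map is NA/NaN are excluded pairwise.
#'
#' @param estimates,references 3D parameter maps of identical shape.
#' @param roi logical/binary array of the same shape selecting the voxels.
#' @return the MSE.
#' @export
mse <- function(estimates, references, roi) {
  stopifnot(all(dim(estimates) == dim(references)),
            all(dim(estimates) == dim(roi)))
  e <- estimates[roi > 0]; r <- references[roi > 0]
  ok <- is.finite(e) & is.finite(r)
  if (!any(ok)) stop("empty effective ROI: no finite paired voxels")
  mean((e[ok] - r[ok])^2)
}

#' Background variance of a parameter map
#'
#' Variance of the map over the complement of the brain mask (NA/NaN
#' excluded); the noise benchmark the protocol MSEs are judged against.
#'
#' @param map 3D parameter map.
#' @param mask 3D brain mask (background = 0).
#' @return the variance.
#' @export
background_sigma2 <- function(map, mask) {
  stopifnot(all(dim(map) == dim(mask)))
  bg <- map[mask == 0]
  bg <- bg[is.finite(bg)]
  if (length(bg) < 2) stop("background is empty")
  var(bg)
}

#' Lower bound of the noise variance across replicates
#'
#' `sigma2_L = mean(sigma2) - sd(sigma2)` over per-replicate background
#' variances.
#'
#' @param sigma2_values numeric vector of per-replicate variances (>= 2).
#' @return the lower bound.
#' @export
sigma2_lower_bound <- function(sigma2_values) {
  if (length(sigma2_values) < 2) stop("need at least 2 replicates (sample SD undefined)")
  mean(sigma2_values) - sd(sigma2_values)
}

#' Direction subsets by consecutive removal from the end of the scan
#'
#' Emulates motion late in the acquisition: for each requested count, the
#' first `n_keep` directions of every shell (acquisition order) are kept and
#' the trailing consecutive block is dropped.
#'
#' @param n_keep vector of direction counts to keep (each within 15..25 for
#'   the default 25-direction scheme).
#' @param n_total acquired directions per shell (default 25).
#' @return tibble with `label`, `n_dirs` and a `keep_dirs` list-column of
#'   kept direction indices.
#' @export
direction_subsets <- function(n_keep = 15:25, n_total = 25) {
  stopifnot(all(n_keep >= 6), all(n_keep <= n_total))
  tibble::tibble(label = paste0("dirs_", n_keep), n_dirs = as.integer(n_keep),
                 keep_dirs = purrr::map(n_keep, seq_len))
}

#' The 26 nonzero b-value combinations of the reduced-protocol analysis
#'
#' Fixed enumeration of every subset of size 2..5 of the five nonzero
#' shells {500, 1000, 1500, 2000, 2500} s/mm^2, with the conventional
#' labels (`"5"`, `"4_#1"` .. `"2_#10"`).
#'
#' @return tibble with `label`, `n_b` and a `bvals` list-column.
#' @export
bvalue_combinations <- function() {
  combos <- list(
    "5"     = c(500, 1000, 1500, 2000, 2500),
    "4_#1"  = c(500, 1000, 1500, 2500),
    "4_#2"  = c(500, 1000, 2000, 2500),
    "4_#3"  = c(500, 1500, 2000, 2500),
    "4_#4"  = c(1000, 1500, 2000, 2500),
    "4_#5"  = c(500, 1000, 1500, 2000),
    "3_#1"  = c(500, 1000, 2500),
    "3_#2"  = c(500, 1500, 2500),
    "3_#3"  = c(500, 2000, 2500),
    "3_#4"  = c(1000, 1500, 2500),
    "3_#5"  = c(1000, 2000, 2500),
    "3_#6"  = c(1500, 2000, 2500),
    "3_#7"  = c(500, 1000, 2000),
    "3_#8"  = c(500, 1500, 2000),
    "3_#9"  = c(1000, 1500, 2000),
    "3_#10" = c(500, 1000, 1500),
    "2_#1"  = c(500, 2500),
    "2_#2"  = c(1000, 2500),
    "2_#3"  = c(1500, 2500),
    "2_#4"  = c(2000, 2500),
    "2_#5"  = c(500, 2000),
    "2_#6"  = c(1000, 2000),
    "2_#7"  = c(1500, 2000),
    "2_#8"  = c(500, 1500),
    "2_#9"  = c(1000, 1500),
    "2_#10" = c(500, 1000)
  )
  tibble::tibble(label = names(combos),
                 n_b = lengths(combos),
                 bvals = unname(combos))
}

# Translate a protocol subset into a keep mask over measurement volumes.
subset_keep <- function(grad, keep_dirs = NULL, keep_bvals = NULL) {
  use <- rep(TRUE, nrow(grad))
  nz <- grad$bval > 0
  if (!is.null(keep_dirs)) use[nz & !(grad$dir_index %in% keep_dirs)] <- FALSE
  if (!is.null(keep_bvals)) use[nz & !(grad$bval %in% keep_bvals)] <- FALSE
  use
}

#' Protocol-subset MSE experiment on clean phantoms
#'
#' For each replicate seed: renders an artifact-free phantom, fits the full
#' protocol as the reference, fits every requested protocol subset, and
#' computes per-parameter MSEs against the reference over brain voxels. The
#' per-replicate noise variance sigma^2 of each parameter is measured on the
#' background of the full-protocol maps (a subsample of background voxels is
#' fitted for this purpose), and the feasibility criterion
#' `MSE < sigma2_L = mean(sigma2) - sd(sigma2)` is evaluated on the
#' across-replicate mean MSE.
#'
#' @param config a [phantom_config()]; one phantom per seed is rendered with
#'   its `seed` replaced.
#' @param subsets tibble of subsets: rows from [direction_subsets()] and/or
#'   [bvalue_combinations()].
#' @param seeds integer vector of replicate seeds (>= 2).
#' @param fwhm smoothing FWHM in mm applied before every fit (the workflow
#'   default).
#' @param n_background background voxels to fit per replicate for sigma^2.
#' @param progress print one line per replicate.
#' @return an `mse_report`: list with `per_replicate` (tibble: `seed`,
#'   `label`, `parameter`, `mse`), `sigma2` (tibble: `seed`, `parameter`,
#'   `sigma2`), and `summary` (tibble: `label`, `parameter`, `mse_mean`,
#'   `mse_sd`, `sigma2_mean`, `sigma2_sd`, `sigma2_L`, `pass`).
#' @export
protocol_experiment <- function(config, subsets, seeds = 1:5, fwhm = 2.5,
                                n_background = 1000, progress = FALSE) {
  stopifnot(length(seeds) >= 2)
  per_rep <- list(); sig <- list()
  for (s in seeds) {
    cfg <- config; cfg$seed <- as.integer(s)
    ph <- render_phantom(cfg)
    ph <- smooth_dataset(ph, fwhm)
    ref <- fit_dataset(ph, qc = NULL, mode = "conventional")
    # background sigma^2 on full-protocol maps
    bg_idx <- which(ph$mask == 0, arr.ind = TRUE)
    old <- .Random.seed_get()
    set.seed(s)
    take <- sample.int(nrow(bg_idx), min(n_background, nrow(bg_idx)))
    .Random.seed_set(old)
    bgfit <- fit_dataset(ph, qc = NULL, mode = "conventional",
                         voxels = bg_idx[take, , drop = FALSE])
    bmask <- array(1L, dim(ph$mask)); bmask[ph$mask == 0] <- 0L
    for (p in c("mk", "md", "fa")) {
      s2 <- tryCatch(background_sigma2(bgfit$maps[[p]], bmask),
                     error = function(e) NA_real_)
      sig[[length(sig) + 1]] <- tibble::tibble(seed = s, parameter = p,
                                               sigma2 = s2)
    }
    for (i in seq_len(nrow(subsets))) {
      keep <- subset_keep(ph$grad,
                          keep_dirs = if ("keep_dirs" %in% names(subsets)) subsets$keep_dirs[[i]] else NULL,
                          keep_bvals = if ("bvals" %in% names(subsets)) subsets$bvals[[i]] else NULL)
      fit <- if (all(keep)) ref else fit_dataset(ph, qc = NULL, mode = "conventional",
                                                 keep_override = keep)
      for (p in c("mk", "md", "fa")) {
        per_rep[[length(per_rep) + 1]] <- tibble::tibble(
          seed = s, label = subsets$label[i], parameter = p,
          mse = mse(fit$maps[[p]], ref$maps[[p]], ph$mask))
      }
      if (progress) message(sprintf("seed %d: subset %s done", s, subsets$label[i]))
    }
  }
  per_rep <- dplyr::bind_rows(per_rep)
  sig <- dplyr::bind_rows(sig)
  sigL <- sig |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(sigma2_mean = mean(.data$sigma2),
                     sigma2_sd = sd(.data$sigma2),
                     sigma2_L = if (sum(is.finite(.data$sigma2)) >= 2) {
                       sigma2_lower_bound(.data$sigma2[is.finite(.data$sigma2)])
                     } else NA_real_,
                     .groups = "drop")
  summary <- per_rep |>
    dplyr::group_by(.data$label, .data$parameter) |>
    dplyr::summarise(mse_mean = mean(.data$mse), mse_sd = sd(.data$mse),
                     mse_median = median(.data$mse), .groups = "drop") |>
    dplyr::left_join(sigL, by = "parameter") |>
    dplyr::mutate(pass = .data$mse_mean < .data$sigma2_L)
  structure(list(per_replicate = per_rep, sigma2 = sig, summary = summary,
                 seeds = seeds, fwhm = fwhm),
            class = "mse_report")
}

#' @export
print.mse_report <- function(x, ...) {
  cat(sprintf("<mse_report> %d subsets x %d parameters, %d replicates\n",
              dplyr::n_distinct(x$summary$label), 3, length(x$seeds)))
  cat(sprintf("  passing MSE < sigma2_L: %d / %d\n",
              sum(x$summary$pass), nrow(x$summary)))
  invisible(x)
}

#' Tidy an MSE report
#' @param x an `mse_report`.
#' @param ... unused.
#' @return the summary tibble.
#' @export
tidy.mse_report <- function(x, ...) x$summary

#' One-row summary of an MSE report
#' @param x an `mse_report`.
#' @param ... unused.
#' @return tibble with subset/pass counts.
#' @export
glance.mse_report <- function(x, ...) {
  tibble::tibble(n_subsets = dplyr::n_distinct(x$summary$label),
                 n_replicates = length(x$seeds),
                 n_pass = sum(x$summary$pass),
                 n_eval = nrow(x$summary))
}

#' White-matter region of interest from an FA map
#'
#' Either every voxel with FA at or above a lower threshold (default 0.3,
#' the upper end of the conventional 0.15..0.3 range), or a band
#' `lower <= FA <= upper`.
#'
#' @param fa_map 3D FA map.
#' @param lower,upper FA thresholds, `0 <= lower < upper <= 1`.
#' @param mode `"lower"` (FA >= lower) or `"band"` (lower <= FA <= upper).
#' @return logical array of the same shape (the ROI); errors if empty.
#' @export
white_matter_roi <- function(fa_map, lower = 0.3, upper = 1, mode = c("lower", "band")) {
  mode <- match.arg(mode)
  stopifnot(lower >= 0, lower < upper, upper <= 1)
  roi <- if (mode == "lower") !is.na(fa_map) & fa_map >= lower
         else !is.na(fa_map) & fa_map >= lower & fa_map <= upper
  if (!any(roi)) stop("empty ROI: no voxels in the FA range")
  roi
}

#' Paired ROI comparison between two workflows
#'
#' Computes per-replicate ROI means of MK, MD and FA for two matched map
#' sets and compares them with the paired Wilcoxon signed-rank test.
#'
#' @param maps_a,maps_b lists of map lists (one element per replicate, each
#'   with `mk`, `md`, `fa` arrays), matched by position.
#' @param rois list of logical ROI arrays, one per replicate (or a single
#'   array recycled).
#' @return tibble: `parameter`, `mean_a`, `mean_b`, `statistic`, `p_value`,
#'   `significant`, `n`.
#' @export
roi_compare <- function(maps_a, maps_b, rois) {
  n <- length(maps_a)
  stopifnot(length(maps_b) == n, n >= 6)
  if (is.array(rois)) rois <- rep(list(rois), n)
  purrr::map_dfr(c("mk", "md", "fa"), function(p) {
    a <- purrr::map_dbl(seq_len(n), ~ mean(maps_a[[.x]][[p]][rois[[.x]]], na.rm = TRUE))
    b <- purrr::map_dbl(seq_len(n), ~ mean(maps_b[[.x]][[p]][rois[[.x]]], na.rm = TRUE))
    if (all(a == b)) {
      tibble::tibble(parameter = p, mean_a = mean(a), mean_b = mean(b),
                     statistic = NA_real_, p_value = 1, significant = FALSE, n = n)
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE))
      tibble::tibble(parameter = p, mean_a = mean(a), mean_b = mean(b),
                     statistic = unname(wt$statistic), p_value = wt$p.value,
                     significant = wt$p.value < 0.05, n = n)
    }
  })
}
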