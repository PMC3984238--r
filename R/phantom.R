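#' Tissue specification for the DKI phantom
#'
#' Bundles the forward-model parameters of one tissue class: baseline signal
#' `s0`, a symmetric positive semi-definite diffusion tensor (um^2/ms) and a
#' fully symmetric rank-4 kurtosis tensor (15 unique elements, unitless).
#'
#' @param label tissue class name.
#' @param s0 baseline (b = 0) signal, > 0.
#' @param dtensor symmetric 3x3 diffusion tensor in um^2/ms.
#' @param wtensor 15 unique kurtosis-tensor elements (canonical order,
#'   see [kt_isotropic()]).
#' @return a `tissue_spec` object.
#' @export
tissue_spec <- function(label, s0, dtensor, wtensor) {
  stopifnot(s0 > 0, length(wtensor) == 15)
  d6 <- dt_from_matrix(dtensor)
  ev <- eigen(dtensor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) stop("diffusion tensor must be positive semi-definite")
  structure(list(label = label, s0 = s0, dtensor = dtensor, d6 = d6,
                 wtensor = wtensor, md = mean(diag(dtensor))),
            class = "tissue_spec")
}

#' Default gray-matter tissue (isotropic, MD 1.1 um^2/ms, MK 0.7)
#' @param s0 baseline signal.
#' @return a `tissue_spec`.
#' @export
tissue_gray <- function(s0 = 1000) {
  tissue_spec("gray", s0, diag(1.1, 3), kt_isotropic(0.7))
}

#' Default CSF-like tissue (fast isotropic diffusion, low kurtosis)
#' @param s0 baseline signal (CSF is bright at b = 0).
#' @return a `tissue_spec`.
#' @export
tissue_csf <- function(s0 = 1400) {
  tissue_spec("csf", s0, diag(2.9, 3), kt_isotropic(0.2))
}

#' Default white-matter tissue (axially symmetric along x)
#'
#' Diffusion eigenvalues (1.7, 0.4, 0.4) um^2/ms; kurtosis is axially
#' symmetric with apparent kurtosis 0.6 along the fiber and 1.8 across it,
#' in the range reported for human white matter.
#'
#' @param s0 baseline signal.
#' @return a `tissue_spec`.
#' @export
tissue_white <- function(s0 = 900) {
  d <- diag(c(1.7, 0.4, 0.4))
  md <- mean(diag(d))
  k_ax <- 0.6; k_rad <- 1.8
  w <- numeric(15)
  w[1] <- k_ax * d[1, 1]^2 / md^2          # xxxx
  w[2] <- w[3] <- k_rad * d[2, 2]^2 / md^2 # yyyy, zzzz
  w[12] <- w[2] / 3                        # yyzz: isotropy in the radial plane
  w[10] <- w[11] <- (w[1] + w[2]) / 6      # xxyy, xxzz: smooth interpolation
  tissue_spec("white", s0, d, w)
}

#' Noise-free DKI signal for a tissue along one gradient
#'
#' Evaluates the standard kurtosis signal model
#' `ln S = ln S0 - b D_app(g) + (b^2/6) MD^2 W_app(g)`
#' with b converted to ms/um^2 so that units cancel (b in s/mm^2, D in
#' um^2/ms).
#'
#' @param tissue a [tissue_spec()].
#' @param b b-value in s/mm^2 (scalar or vector).
#' @param g unit gradient direction (vector, or matrix of one row per `b`).
#' @return noise-free signal(s), strictly positive.
#' @export
forward_signal <- function(tissue, b, g) {
  g <- rbind(g)
  if (length(b) == 1 && nrow(g) > 1) b <- rep(b, nrow(g))
  if (nrow(g) == 1 && length(b) > 1) g <- g[rep(1, length(b)), , drop = FALSE]
  nrm <- sqrt(rowSums(g^2))
  bad <- b > 0 & abs(nrm - 1) > 1e-8
  if (any(bad)) stop("gradient directions must be unit vectors when b > 0")
  bb <- b / 1000  # ms/um^2
  da <- d_app(g, tissue$d6)
  wa <- w_app(g, tissue$wtensor)
  lns <- log(tissue$s0) - bb * da + (bb^2 / 6) * tissue$md^2 * wa
  as.vector(exp(lns))
}

#' Phantom configuration
#'
#' Describes the synthetic acquisition: geometry, gradient scheme, noise
#' level and tissue layout. Defaults reproduce the acquisition the package
#' is designed around: b = 500..2500 s/mm^2 in steps of 500 with 25
#' directions per shell, 5 b0 volumes, 10 axial slices of a 128 x 128 matrix.
#'
#' @param matrix_size in-plane matrix size (square).
#' @param n_slices number of axial slices.
#' @param voxel_size voxel dimensions in mm, length 3.
#' @param bvals nonzero b-values (s/mm^2).
#' @param n_dirs directions per nonzero shell.
#' @param n_b0 number of b0 volumes.
#' @param snr_b0 b0 signal-to-noise ratio, defined as the b0 tissue mean
#'   over the background noise standard deviation of the magnitude images;
#'   `Inf` disables noise.
#' @param seed random seed used for directions, texture and noise.
#' @param gray,white,csf tissue specifications for the isotropic background
#'   tissue, the anisotropic band and the ventricle-like core.
#' @param wm_half_width half-width of the white-matter band as a fraction of
#'   the matrix size.
#' @param csf_half_width half-width of the CSF stripe carved out of the
#'   middle of the band (a ventricle flanked by periventricular white
#'   matter); 0 removes it.
#' @param wm_bend total in-plane fiber-orientation sweep (radians) across
#'   the white-matter band, emulating a bending tract; 0 gives a single
#'   coherent orientation everywhere (unrealistically so: real slices mix
#'   orientations, which damps the direction-to-direction signal spread
#'   within a shell).
#' @param texture_amp amplitude of the fine anatomy-like multiplicative
#'   baseline-signal texture (sd as a fraction of the tissue signal; 0
#'   disables it). Without it the phantom is piecewise constant and carries
#'   no within-tissue structure for correlation-based QC to lock onto.
#' @param texture_scale in-plane correlation length of the fine texture in
#'   pixels (Gaussian sd).
#' @param shading_amp amplitude of the coarse multiplicative shading field
#'   (slow anatomical/coil-profile intensity variation spanning many
#'   sub-windows). Real brain images carry structure at both scales; the
#'   coarse component is what lets a global correlation coefficient ride
#'   out a local artifact.
#' @param shading_scale correlation length of the shading field in pixels.
#' @return a `phantom_config` object.
#' @export
phantom_config <- function(matrix_size = 128, n_slices = 10,
                           voxel_size = c(1.4, 1.4, 5),
                           bvals = c(500, 1000, 1500, 2000, 2500),
                           n_dirs = 25, n_b0 = 5, snr_b0 = 20, seed = 1L,
                           gray = tissue_gray(), white = tissue_white(),
                           csf = tissue_csf(),
                           wm_half_width = 0.10, csf_half_width = 0.03,
                           wm_bend = pi / 2,
                           texture_amp = 0.25, texture_scale = 2,
                           shading_amp = 0.25, shading_scale = 12) {
  stopifnot(matrix_size >= 16, n_slices >= 1, snr_b0 > 0, all(bvals > 0))
  structure(list(matrix_size = matrix_size, n_slices = n_slices,
                 voxel_size = voxel_size, bvals = bvals, n_dirs = n_dirs,
                 n_b0 = n_b0, snr_b0 = snr_b0, seed = as.integer(seed),
                 gray = gray, white = white, csf = csf,
                 wm_half_width = wm_half_width,
                 csf_half_width = csf_half_width, wm_bend = wm_bend,
                 texture_amp = texture_amp, texture_scale = texture_scale,
                 shading_amp = shading_amp, shading_scale = shading_scale),
            class = "phantom_config")
}

#' Render a synthetic DKI dataset from a phantom configuration
#'
#' Builds a layered brain-like object (an elliptical "brain" per slice with
#' an anisotropic white-matter band inside an isotropic gray-matter
#' background, zero signal outside), modulates the baseline signal by a
#' smooth anatomy-like texture field (identical across volumes, so it
#' correlates between a DWI and the b0 reference the way anatomy does),
#' evaluates the noise-free kurtosis signal model per tissue and volume, and
#' applies Rician noise channel-wise at the requested b0 SNR.
#'
#' @param config a [phantom_config()].
#' @return a `dwi_dataset`: list with elements `data` (4D array x,y,z,volume),
#'   `grad` (gradient table tibble), `mask` (3D binary array), `voxel_size`,
#'   `sigma` (noise sd actually applied), and `truth` (ground-truth maps:
#'   `tissue` label array and `md`, `fa`, `mk`, `s0` arrays plus the tissue
#'   specs themselves).
#' @export
render_phantom <- function(config) {
  n <- config$matrix_size
  nz <- config$n_slices
  grad <- make_gradient_table(config$n_dirs, config$bvals, config$n_b0,
                              seed = config$seed)
  nv <- nrow(grad)

  # tissue layout: 1 = background, 2 = gray, 3 = white, 4 = csf
  xs <- (seq_len(n) - (n + 1) / 2) / n
  ys <- (seq_len(n) - (n + 1) / 2) / n
  X <- matrix(xs, n, n)
  Y <- matrix(ys, n, n, byrow = TRUE)
  brain <- (X / 0.42)^2 + (Y / 0.36)^2 <= 1
  if (!any(brain)) stop("degenerate phantom geometry: empty brain mask")
  wm <- brain & abs(Y) <= config$wm_half_width
  csf <- brain & abs(Y) <= config$csf_half_width & abs(X) <= 0.25
  layout_slice <- matrix(1L, n, n)
  layout_slice[brain] <- 2L
  layout_slice[wm] <- 3L
  layout_slice[csf] <- 4L
  tissue <- array(rep(layout_slice, nz), c(n, n, nz))
  mask <- array(as.integer(tissue > 1L), c(n, n, nz))

  g <- as.matrix(grad[, c("gx", "gy", "gz")])
  dirs_nz <- unique(g[grad$bval > 0, , drop = FALSE])

  # per-tissue parameter LUT in the fitter's (ln S0, D, V = MD^2 W)
  # parameterization; white matter gets one column per in-plane position so
  # its fiber orientation can bend along the band
  th_gray <- c(log(config$gray$s0), config$gray$d6,
               config$gray$md^2 * config$gray$wtensor)
  th_csf <- c(log(config$csf$s0), config$csf$d6,
              config$csf$md^2 * config$csf$wtensor)
  wm_cols <- vector("list", n)
  wm_mk <- numeric(n)
  for (cx in seq_len(n)) {
    ang <- config$wm_bend * (xs[cx])  # xs in (-0.5, 0.5): sweep over the band
    rt <- rotate_tensors(config$white$d6, config$white$wtensor, rot_z(ang))
    wm_cols[[cx]] <- c(log(config$white$s0), rt$d6, config$white$md^2 * rt$w15)
    da <- d_app(dirs_nz, rt$d6)
    wm_mk[cx] <- mean(config$white$md^2 * w_app(dirs_nz, rt$w15) / da^2)
  }

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$seed + 1L)

  # smooth multiplicative baseline modulation, shared by all volumes:
  # fine texture + coarse shading, mimicking multi-scale anatomy
  field <- array(1, c(n, n, nz))
  for (comp in list(c(config$texture_amp, config$texture_scale),
                    c(config$shading_amp, config$shading_scale))) {
    if (comp[1] <= 0) next
    K <- gaussian_conv_matrix(n, comp[2])
    for (z in seq_len(nz)) {
      t2 <- K %*% matrix(rnorm(n * n), n, n) %*% t(K)
      t2 <- (t2 - mean(t2)) / sd(t2)
      field[, , z] <- field[, , z] + comp[1] * t2
    }
  }
  field <- pmax(field, 0.2)  # field first: pmax keeps its dim attributes

  idx <- as.vector(tissue)
  fvec <- as.vector(field)
  s0_map <- fvec * c(0, config$gray$s0, config$white$s0, config$csf$s0)[idx]
  b0_tissue_mean <- mean(s0_map[idx > 1])
  # Rician background (pure noise) is Rayleigh with sd sigma*sqrt(2 - pi/2):
  # scale the channel noise so the measured tissue-mean / background-sd
  # ratio equals snr_b0.
  sigma <- if (is.finite(config$snr_b0)) {
    b0_tissue_mean / config$snr_b0 / sqrt(2 - pi / 2)
  } else 0

  # noise-free log-signals for all tissue voxels via the shared design
  # matrix: generator and fitter use the same model by construction
  tis <- which(idx > 1L)
  Theta <- matrix(th_gray, 22, length(tis))
  is_wm <- idx[tis] == 3L
  is_csf <- idx[tis] == 4L
  # orientation varies along the band (the x axis indexes array rows)
  row_of <- as.vector(array(rep(matrix(seq_len(n), n, n), nz), c(n, n, nz)))
  if (any(is_wm)) {
    Theta[, is_wm] <- do.call(cbind, wm_cols[row_of[tis[is_wm]]])
  }
  if (any(is_csf)) Theta[, is_csf] <- th_csf
  A <- design_matrix(grad)
  lnS <- A %*% Theta                      # nv x n_tissue
  data <- array(0, c(n, n, nz, nv))
  for (v in seq_len(nv)) {
    s <- numeric(n * n * nz)
    s[tis] <- fvec[tis] * exp(lnS[v, ])
    if (sigma > 0) s <- rician(s, sigma)
    data[, , , v] <- s
  }

  mk_map <- rep(NA_real_, n * n * nz)
  dirs_all <- g[grad$bval > 0, , drop = FALSE]
  mk_map[tis] <- truth_mk(config$gray, dirs_all)
  if (any(is_wm)) {
    mk_map[tis[is_wm]] <- wm_mk[row_of[tis[is_wm]]]
  }
  if (any(is_csf)) mk_map[tis[is_csf]] <- truth_mk(config$csf, dirs_all)
  truth <- list(
    tissue = tissue,
    gray = config$gray, white = config$white, csf = config$csf,
    md = array(c(NA, truth_md(config$gray), truth_md(config$white),
                 truth_md(config$csf))[idx], c(n, n, nz)),
    fa = array(c(NA, truth_fa(config$gray), truth_fa(config$white),
                 truth_fa(config$csf))[idx], c(n, n, nz)),
    mk = array(mk_map, c(n, n, nz)),
    s0 = array(s0_map, c(n, n, nz)),
    field = field
  )
  new_dwi_dataset(data, grad, mask, config$voxel_size, sigma, truth, config)
}

truth_md <- function(tissue) mean(diag(tissue$dtensor))
truth_fa <- function(tissue) derive_fa(tissue$d6)
truth_mk <- function(tissue, dirs) {
  dirs <- unique(dirs)
  da <- d_app(dirs, tissue$d6)
  mean(tissue$md^2 * w_app(dirs, tissue$wtensor) / da^2)
}

# Rician sample: magnitude of a complex Gaussian centered on the true signal.
rician <- function(s, sigma) {
  sqrt((s + rnorm(length(s), 0, sigma))^2 + rnorm(length(s), 0, sigma)^2)
}

new_dwi_dataset <- function(data, grad, mask, voxel_size, sigma, truth = NULL,
                            config = NULL) {
  structure(list(data = data, grad = grad, mask = mask,
                 voxel_size = voxel_size, sigma = sigma,
                 truth = truth, config = config),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_dataset> %d x %d x %d voxels, %d volumes (%d b0 + %d shells x %d dirs)\n",
              d[1], d[2], d[3], d[4], sum(x$grad$bval == 0),
              length(unique(x$grad$bval[x$grad$bval > 0])),
              max(table(x$grad$shell[x$grad$shell > 0]), 0)))
  cat(sprintf("  voxel %.2g x %.2g x %.2g mm, noise sd %.3g, %d mask voxels\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$sigma, sum(x$mask)))
  invisible(x)
}
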