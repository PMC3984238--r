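# Constrained linear least-squares (CLLS) estimation of the DKI model.
# Parameter vector theta (length 22, per voxel):
#   theta[1]     = ln S0
#   theta[2:7]   = D (6 unique elements, um^2/ms)
#   theta[8:22]  = V = MD^2 * W (15 unique elements, um^4/ms^2)
# so that  A theta = ln S  with  ln S = ln S0 - b D_app + (b^2/6) V_app,
# b internally in ms/um^2 (s/mm^2 divided by 1000).

#' One design-matrix row of the log-linear DKI model
#'
#' @param b b-value in s/mm^2.
#' @param g unit gradient direction (ignored for b = 0).
#' @return numeric vector of 22 coefficients (intercept, 6 diffusion
#'   monomials, 15 kurtosis monomials, symmetry multiplicities included).
#' @export
design_row <- function(b, g) {
  if (b == 0) return(c(1, rep(0, 21)))
  if (abs(sqrt(sum(g^2)) - 1) > 1e-8) stop("gradient direction must be a unit vector when b > 0")
  bb <- b / 1000
  c(1, -bb * dt_monomials(g), (bb^2 / 6) * kt_monomials(g))
}

#' Design matrix for a set of measurements
#'
#' @param grad gradient-table tibble (rows = measurements to include).
#' @return matrix with one 22-column row per measurement.
#' @export
design_matrix <- function(grad) {
  g <- as.matrix(grad[, c("gx", "gy", "gz")])
  bb <- grad$bval / 1000
  cbind(1, -bb * dt_monomials(g), (bb^2 / 6) * kt_monomials(g))
}

# Linear inequality constraints of the CLLS scheme, evaluated at a set of
# constraint directions g (typically the acquisition's direction set):
#   D_app(g) >= 0
#   V_app(g) >= 0                       (K_app >= 0)
#   (C / b_max) D_app(g) - V_app(g) >= 0  (K_app <= C / (b_max D_app))
# Each block is linear in theta; rows are stacked into G with G theta >= 0.
clls_constraints <- function(dirs, C = 3, b_max = 2500) {
  bbmax <- b_max / 1000
  P_d <- dt_monomials(dirs)
  P_v <- kt_monomials(dirs)
  z6 <- matrix(0, nrow(P_d), 6)
  z15 <- matrix(0, nrow(P_d), 15)
  G1 <- cbind(0, P_d, z15)
  G2 <- cbind(0, z6, P_v)
  G3 <- cbind(0, (C / bbmax) * P_d, -P_v)
  rbind(G1, G2, G3)
}

#' Fit one voxel by constrained linear least squares
#'
#' Minimizes `||A theta - ln S||^2` subject to, at every constraint
#' direction: nonnegative apparent diffusivity, nonnegative apparent
#' kurtosis, and apparent kurtosis at most `C / (b_max * D_app)`. Solved as
#' a quadratic program; if the QP fails the unconstrained least-squares
#' solution is returned with `status = "unconstrained_fallback"`.
#'
#' @param signals positive measurement signals (same order as `A` rows).
#' @param A design matrix from [design_matrix()].
#' @param constraint_dirs matrix of unit directions (one per row) at which
#'   the constraints are imposed.
#' @param C kurtosis bound constant (default 3).
#' @param b_max largest b-value of the protocol in s/mm^2.
#' @param G optional precomputed constraint matrix (overrides
#'   `constraint_dirs`).
#' @return list with `theta` (length 22), `status` (`"ok"`, `"ols"` if no
#'   constraint was active, `"unconstrained_fallback"`, or `"unfittable"`).
#' @export
fit_voxel_clls <- function(signals, A, constraint_dirs = NULL, C = 3,
                           b_max = max_bval_of(A), G = NULL) {
  if (any(signals <= 0)) stop("signals must be positive (clamp before fitting)")
  if (nrow(A) < ncol(A)) return(list(theta = rep(NA_real_, 22), status = "unfittable"))
  if (is.null(G)) G <- clls_constraints(constraint_dirs, C, b_max)
  y <- log(signals)
  AtA <- crossprod(A)
  Aty <- crossprod(A, y)
  theta <- tryCatch(solve(AtA, Aty), error = function(e) NULL)
  if (is.null(theta)) return(list(theta = rep(NA_real_, 22), status = "unfittable"))
  theta <- as.vector(theta)
  if (all(G %*% theta >= -1e-10)) return(list(theta = theta, status = "ols"))
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = AtA + diag(1e-10, 22), dvec = Aty,
                       Amat = t(G), bvec = rep(0, nrow(G))),
    error = function(e) NULL)
  if (is.null(sol)) return(list(theta = theta, status = "unconstrained_fallback"))
  list(theta = sol$solution, status = "ok")
}

max_bval_of <- function(A) stop("b_max must be supplied when G is not precomputed")

#' Mean diffusivity of a diffusion tensor
#' @param d 6 unique elements (or symmetric 3x3 matrix).
#' @return `trace(D) / 3`.
#' @export
derive_md <- function(d) {
  if (is.matrix(d)) d <- dt_from_matrix(d)
  (d[1] + d[2] + d[3]) / 3
}

#' Fractional anisotropy of a diffusion tensor
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||` from the
#' eigenvalues, clipped to `[0, 1]`.
#'
#' @param d 6 unique elements (or symmetric 3x3 matrix).
#' @return FA in `[0, 1]` (NaN for a zero tensor).
#' @export
derive_fa <- function(d) {
  if (is.matrix(d)) d <- dt_from_matrix(d)
  ev <- eigen(dt_to_matrix(d), symmetric = TRUE, only.values = TRUE)$values
  nrm <- sqrt(sum(ev^2))
  if (nrm == 0) return(NaN)
  min(1, max(0, sqrt(1.5) * sqrt(sum((ev - mean(ev))^2)) / nrm))
}

#' Mean kurtosis of a fitted voxel
#'
#' Directional average of the apparent kurtosis
#' `K_app(g) = V_app(g) / D_app(g)^2` over a set of directions (by default
#' the acquisition's sampled directions). Directions whose apparent
#' diffusivity falls below `min_diffusivity` are skipped.
#'
#' @param theta length-22 parameter vector (see [fit_voxel_clls()]), or a
#'   list with elements `d` (6) and `v` (15).
#' @param dirs matrix of unit directions, one per row.
#' @param min_diffusivity smallest usable apparent diffusivity in um^2/ms.
#' @param min_kurtosis,max_kurtosis clipping range for the result. Near-flat
#'   log-signals (background, CSF at high b) give `D_app -> 0` and an
#'   unbounded kurtosis ratio; derived maps are conventionally clipped to a
#'   physiological range.
#' @return mean kurtosis (NaN if no direction is usable).
#' @export
derive_mk <- function(theta, dirs, min_diffusivity = 1e-4,
                      min_kurtosis = 0, max_kurtosis = 10) {
  if (is.list(theta)) theta <- c(0, theta$d, theta$v)
  da <- d_app(dirs, theta[2:7])
  va <- w_app(dirs, theta[8:22])
  ok <- da > min_diffusivity
  if (!any(ok)) return(NaN)
  min(max_kurtosis, max(min_kurtosis, mean(va[ok] / da[ok]^2)))
}

#' Enforce the minimum-protocol rule after artifact rejection
#'
#' On each slice, a nonzero shell that retains fewer than `min_dirs`
#' directions is dropped entirely (all its measurements rejected for that
#' slice); if fewer than 2 nonzero shells remain the slice is unfittable.
#'
#' @param keep tibble with columns `slice`, `shell`, `direction_index`,
#'   `volume`, `rejected` (the QC scores tibble works as-is).
#' @param min_dirs minimum surviving directions per shell (default 15).
#' @param min_shells minimum nonzero shells per slice (default 2).
#' @return list with `keep` (the tibble with an updated `rejected` column
#'   and a logical `shell_dropped`) and `slice_status` (tibble: `slice`,
#'   `n_shells`, `fittable`).
#' @export
enforce_minimum_protocol <- function(keep, min_dirs = 15, min_shells = 2) {
  keep <- keep |>
    dplyr::group_by(.data$slice, .data$shell) |>
    dplyr::mutate(shell_dropped = sum(!.data$rejected) < min_dirs,
                  rejected = .data$rejected | .data$shell_dropped) |>
    dplyr::ungroup()
  slice_status <- keep |>
    dplyr::group_by(.data$slice) |>
    dplyr::summarise(n_shells = dplyr::n_distinct(.data$shell[!.data$rejected]),
                     .groups = "drop") |>
    dplyr::mutate(fittable = .data$n_shells >= min_shells)
  list(keep = keep, slice_status = slice_status)
}

#' In-plane Gaussian smoothing of every slice of every volume
#'
#' 2D Gaussian kernel of the stated full width at half maximum (mm),
#' separable convolution with zero padding. `fwhm = 0` is the identity.
#'
#' @param dataset a `dwi_dataset`.
#' @param fwhm kernel FWHM in mm (default 2.5).
#' @return the smoothed dataset.
#' @export
smooth_dataset <- function(dataset, fwhm = 2.5) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(dataset)
  d <- dim(dataset$data)
  K1 <- gaussian_conv_matrix(d[1], fwhm / 2.3548200450309493 / dataset$voxel_size[1])
  K2 <- gaussian_conv_matrix(d[2], fwhm / 2.3548200450309493 / dataset$voxel_size[2])
  for (v in seq_len(d[4])) for (z in seq_len(d[3])) {
    dataset$data[, , z, v] <- K1 %*% dataset$data[, , z, v] %*% t(K2)
  }
  dataset
}

# Dense 1D convolution matrix for a normalized Gaussian kernel (sd in
# pixels), zero padding at the edges.
gaussian_conv_matrix <- function(n, sd_px) {
  if (sd_px <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sd_px))
  k <- exp(-((-r):r)^2 / (2 * sd_px^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (o in (-r):r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- k[o + r + 1]
  }
  M
}

#' Fit diffusion and kurtosis tensors for a whole dataset
#'
#' Per slice, builds the design matrix from the measurements that survive QC
#' (proposed mode) or from all measurements (conventional mode), applies the
#' minimum-protocol rule, and solves the constrained least-squares problem
#' at every voxel inside the mask. The unconstrained solution is computed
#' for all voxels in one linear solve; the quadratic program is run only at
#' voxels violating a constraint.
#'
#' @param dataset a `dwi_dataset` (smooth first with [smooth_dataset()] to
#'   follow the full workflow).
#' @param qc a `qc_report` from [run_qc()], or NULL.
#' @param mode `"proposed"` (apply QC rejections) or `"conventional"`
#'   (ignore them).
#' @param C kurtosis-bound constant (default 3).
#' @param min_dirs,min_shells minimum-protocol rule parameters.
#' @param keep_override optional logical vector over measurement volumes
#'   (TRUE = use), applied uniformly to all slices (used for protocol-subset
#'   experiments); overrides `qc`.
#' @param exclude optional tibble with columns `slice` and `volume`: manual
#'   per-slice exclusions applied on top of `qc`/`keep_override` (used to
#'   replay one dataset's rejections on another).
#' @param voxels optional integer matrix (columns x, y, z) restricting the
#'   fit to specific voxels regardless of the mask (used for background
#'   noise estimation).
#' @param constrained apply the CLLS inequality constraints (default TRUE);
#'   FALSE gives the plain log-linear least-squares fit.
#' @return a `dki_fit`: list with `theta` (4D array x,y,z,22), `status`
#'   (integer array; 0 ok/ols, 1 fallback, 2 unfittable), `maps` (list of 3D
#'   arrays `mk`, `md`, `fa`, `s0`), `protocol` (per-slice surviving-shell
#'   log) and the settings used.
#' @export
fit_dataset <- function(dataset, qc = NULL, mode = c("proposed", "conventional"),
                        C = 3, min_dirs = 15, min_shells = 2,
                        keep_override = NULL, voxels = NULL, exclude = NULL,
                        constrained = TRUE) {
  mode <- match.arg(mode)
  grad <- dataset$grad
  d <- dim(dataset$data)
  nvox_floor <- if (dataset$sigma > 0) 0.5 * dataset$sigma * sqrt(pi / 2) else 1e-6

  # per-slice keep table over all measurement volumes
  keep_tbl <- slice_keep_table(dataset, qc, mode, min_dirs, min_shells,
                               keep_override, exclude)
  dirs_all <- unique(as.matrix(grad[grad$bval > 0, c("gx", "gy", "gz")]))

  theta <- array(NA_real_, c(d[1:3], 22))
  status <- array(2L, d[1:3])
  proto <- list()
  for (z in seq_len(d[3])) {
    kt <- keep_tbl[[z]]
    vox <- if (is.null(voxels)) {
      idx <- which(dataset$mask[, , z] > 0, arr.ind = TRUE)
      if (nrow(idx) == 0) next else cbind(idx, z)
    } else {
      vz <- voxels[voxels[, 3] == z, , drop = FALSE]
      if (nrow(vz) == 0) next else vz
    }
    proto[[z]] <- tibble::tibble(slice = z,
                                 shells = paste(sort(unique(grad$bval[kt$use][grad$bval[kt$use] > 0])), collapse = ","),
                                 n_kept = sum(kt$use), fittable = kt$fittable)
    if (!kt$fittable) next
    sub <- grad[kt$use, ]
    A <- design_matrix(sub)
    b_max <- max(sub$bval)
    G <- clls_constraints(dirs_all, C, b_max)

    Y <- matrix(dataset$data[cbind(rep(vox[, 1], each = nrow(sub)),
                                   rep(vox[, 2], each = nrow(sub)),
                                   z,
                                   rep(sub$volume, nrow(vox)))],
                nrow = nrow(sub))
    Y <- pmax(Y, nvox_floor)
    L <- log(Y)
    AtA <- crossprod(A)
    Th <- tryCatch(solve(AtA, crossprod(A, L)), error = function(e) NULL)
    if (is.null(Th)) next
    viol <- constrained & colSums((G %*% Th) < -1e-10) > 0
    st <- integer(nrow(vox))
    if (any(viol)) {
      AtAr <- AtA + diag(1e-10, 22)
      for (k in which(viol)) {
        sol <- tryCatch(
          quadprog::solve.QP(AtAr, crossprod(A, L[, k]), t(G), rep(0, nrow(G))),
          error = function(e) NULL)
        if (is.null(sol)) st[k] <- 1L else Th[, k] <- sol$solution
      }
    }
    for (p in seq_len(22)) {
      theta[cbind(vox[, 1], vox[, 2], z, p)] <- Th[p, ]
    }
    status[cbind(vox[, 1], vox[, 2], z)] <- st
  }
  maps <- derive_maps(theta, status, dirs_all)
  structure(list(theta = theta, status = status, maps = maps,
                 protocol = if (length(proto)) dplyr::bind_rows(proto) else NULL,
                 mode = mode, C = C, min_dirs = min_dirs,
                 constraint_dirs = dirs_all),
            class = "dki_fit")
}

# Decide, per slice, which measurement volumes enter the fit.
slice_keep_table <- function(dataset, qc, mode, min_dirs, min_shells,
                             keep_override, exclude = NULL) {
  grad <- dataset$grad
  d <- dim(dataset$data)
  out <- vector("list", d[3])
  base_use <- rep(TRUE, nrow(grad))
  if (!is.null(keep_override)) base_use <- keep_override
  for (z in seq_len(d[3])) {
    use <- base_use
    if (is.null(keep_override) && mode == "proposed" && !is.null(qc)) {
      sc <- qc$scores[qc$scores$slice == z, ]
      use[sc$volume[sc$rejected]] <- FALSE
      b0z <- qc$b0[qc$b0$slice == z, ]
      if (nrow(b0z)) use[b0z$volume[!b0z$kept]] <- FALSE
    }
    if (!is.null(exclude)) {
      use[exclude$volume[exclude$slice == z]] <- FALSE
    }
    # minimum-protocol rule on nonzero shells
    tab <- grad |>
      dplyr::filter(.data$bval > 0) |>
      dplyr::mutate(used = use[.data$volume]) |>
      dplyr::group_by(.data$shell) |>
      dplyr::summarise(n = sum(.data$used), .groups = "drop")
    bad_shells <- tab$shell[tab$n < min_dirs]
    use[grad$shell %in% bad_shells] <- FALSE
    n_shells <- sum(tab$n >= min_dirs)
    fittable <- n_shells >= min_shells && any(use & grad$bval == 0)
    out[[z]] <- list(use = use, fittable = fittable)
  }
  out
}

# Scalar maps from the fitted parameter array. MK is clipped to the same
# physiological range as derive_mk().
derive_maps <- function(theta, status, dirs, min_diffusivity = 1e-4,
                        min_kurtosis = 0, max_kurtosis = 10) {
  d <- dim(theta)[1:3]
  nv <- prod(d)
  Tm <- matrix(theta, nrow = nv)      # voxels x 22
  D <- Tm[, 2:7, drop = FALSE]
  V <- Tm[, 8:22, drop = FALSE]
  md <- rowMeans(D[, 1:3, drop = FALSE])
  s0 <- exp(Tm[, 1])
  # FA via eigenvalues: loop voxels with finite D only
  fa <- rep(NA_real_, nv)
  ok <- which(complete.cases(D))
  for (k in ok) fa[k] <- derive_fa(D[k, ])
  # MK: directional average, vectorized over voxels
  PD <- dt_monomials(dirs)            # m x 6
  PV <- kt_monomials(dirs)            # m x 15
  mk <- rep(NA_real_, nv)
  if (length(ok)) {
    DA <- PD %*% t(D[ok, , drop = FALSE])   # m x nok
    VA <- PV %*% t(V[ok, , drop = FALSE])
    Kv <- VA / DA^2
    good <- DA > min_diffusivity
    Kv[!good] <- NA
    mk[ok] <- pmin(max_kurtosis, pmax(min_kurtosis, colMeans(Kv, na.rm = TRUE)))
    mk[ok][colSums(good) == 0] <- NaN
  }
  list(mk = array(mk, d), md = array(md, d), fa = array(fa, d),
       s0 = array(s0, d))
}

#' @export
print.dki_fit <- function(x, ...) {
  n_fit <- sum(x$status == 0L | x$status == 1L)
  cat(sprintf("<dki_fit> mode %s, %d voxels fitted (%d fallback), C = %g\n",
              x$mode, n_fit, sum(x$status == 1L), x$C))
  invisible(x)
}

#' Tidy a tensor fit into one row per fitted voxel
#' @param x a `dki_fit`.
#' @param ... unused.
#' @return tibble with voxel coordinates, `mk`, `md`, `fa`, `s0`, `status`.
#' @export
tidy.dki_fit <- function(x, ...) {
  idx <- which(x$status < 2L, arr.ind = TRUE)
  out <- tibble::tibble(x = idx[, 1], y = idx[, 2], z = idx[, 3])
  out$mk <- x$maps$mk[idx]; out$md <- x$maps$md[idx]
  out$fa <- x$maps$fa[idx]; out$s0 <- x$maps$s0[idx]
  out$status <- x$status[idx]
  out
}

#' One-row summary of a tensor fit
#' @param x a `dki_fit`.
#' @param ... unused.
#' @return tibble with voxel counts and map medians.
#' @export
glance.dki_fit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n_fitted = nrow(td), n_fallback = sum(td$status == 1L),
                 median_mk = median(td$mk, na.rm = TRUE),
                 median_md = median(td$md, na.rm = TRUE),
                 median_fa = median(td$fa, na.rm = TRUE),
                 mode = x$mode)
}
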