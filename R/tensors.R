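# Symmetric-tensor bookkeeping shared by the phantom forward model and the
# tensor fitter. Both sides use the same canonical element orders so that a
# noise-free signal rendered by the generator is fitted back exactly.

# Canonical order of the 6 unique elements of a symmetric rank-2 tensor.
DT_ELEMENTS <- c("xx", "yy", "zz", "xy", "xz", "yz")
DT_MULT <- c(1, 1, 1, 2, 2, 2)
# index pairs (i, j) for each unique element
DT_IDX <- cbind(i = c(1, 2, 3, 1, 1, 2), j = c(1, 2, 3, 2, 3, 3))

# Canonical order of the 15 unique elements of a fully symmetric rank-4
# tensor, with permutation multiplicities.
KT_ELEMENTS <- c("xxxx", "yyyy", "zzzz",
                 "xxxy", "xxxz", "xyyy", "yyyz", "xzzz", "yzzz",
                 "xxyy", "xxzz", "yyzz",
                 "xxyz", "xyyz", "xyzz")
KT_MULT <- c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)
KT_IDX <- rbind(
  c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
  c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 2, 2, 2), c(2, 2, 2, 3),
  c(1, 3, 3, 3), c(2, 3, 3, 3),
  c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
  c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 2, 3, 3)
)

#' Convert a symmetric 3x3 matrix to its 6 unique elements
#'
#' Elements are ordered `xx, yy, zz, xy, xz, yz`.
#'
#' @param m symmetric 3x3 matrix.
#' @return numeric vector of length 6.
#' @export
dt_from_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(3, 3)))
  if (max(abs(m - t(m))) > 1e-10 * max(1, max(abs(m)))) {
    stop("diffusion tensor must be symmetric")
  }
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

#' Convert 6 unique diffusion-tensor elements back to a 3x3 matrix
#'
#' @param d numeric vector of length 6 in `xx, yy, zz, xy, xz, yz` order.
#' @return symmetric 3x3 matrix.
#' @export
dt_to_matrix <- function(d) {
  stopifnot(length(d) == 6)
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

# Monomials g_i g_j (with symmetry multiplicity) for the 6 unique
# diffusion-tensor elements, one row per direction.
dt_monomials <- function(g) {
  g <- rbind(g)
  cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

# Monomials g_i g_j g_k g_l (with multiplicity) for the 15 unique rank-4
# elements, one row per direction.
kt_monomials <- function(g) {
  g <- rbind(g)
  out <- matrix(0, nrow(g), 15)
  for (k in seq_len(15)) {
    idx <- KT_IDX[k, ]
    out[, k] <- KT_MULT[k] * g[, idx[1]] * g[, idx[2]] * g[, idx[3]] * g[, idx[4]]
  }
  out
}

#' Apparent diffusivity along a direction
#'
#' `d_app(g, d) = g' D g` for the symmetric tensor with unique elements `d`.
#'
#' @param g unit direction vector (or matrix with one direction per row).
#' @param d 6 unique diffusion-tensor elements.
#' @return apparent diffusivity (one value per direction).
#' @export
d_app <- function(g, d) as.vector(dt_monomials(g) %*% d)

#' Apparent rank-4 contraction along a direction
#'
#' `w_app(g, w) = sum_ijkl g_i g_j g_k g_l W_ijkl` for the fully symmetric
#' tensor with 15 unique elements `w`.
#'
#' @param g unit direction vector (or matrix with one direction per row).
#' @param w 15 unique rank-4 tensor elements (canonical order).
#' @return contraction value (one per direction).
#' @export
w_app <- function(g, w) as.vector(kt_monomials(g) %*% w)

# Full 81-element contraction by explicit summation; brute-force oracle for
# kt_monomials used in tests.
w_app_bruteforce <- function(g, w) {
  W <- array(0, c(3, 3, 3, 3))
  for (k in seq_len(15)) {
    idx <- KT_IDX[k, ]
    for (p in unique(asplit(perms4(idx), 1))) {
      W[p[1], p[2], p[3], p[4]] <- w[k]
    }
  }
  s <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    s <- s + g[i] * g[j] * g[k] * g[l] * W[i, j, k, l]
  }
  s
}

perms4 <- function(x) {
  # all 24 index permutations of a length-4 vector
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4), ]
  t(apply(as.matrix(p), 1, function(r) x[r]))
}

# Rotate a symmetric rank-2 (6 unique elements) and a fully symmetric
# rank-4 tensor (15 unique elements) by a 3x3 rotation matrix.
rotate_tensors <- function(d6, w15, R) {
  D2 <- R %*% dt_to_matrix(d6) %*% t(R)
  W <- array(0, c(3, 3, 3, 3))
  for (k in seq_len(15)) {
    idx <- KT_IDX[k, ]
    for (p in unique(asplit(perms4(idx), 1))) {
      W[p[1], p[2], p[3], p[4]] <- w15[k]
    }
  }
  # W'_ijkl = R_ia R_jb R_kc R_ld W_abcd, contracted one index at a time
  Wr <- W
  for (ax in 1:4) {
    Wr <- aperm(apply(Wr, setdiff(1:4, 1), function(v) R %*% v), c(2, 3, 4, 1))
  }
  w_out <- vapply(seq_len(15), function(k) {
    Wr[KT_IDX[k, 1], KT_IDX[k, 2], KT_IDX[k, 3], KT_IDX[k, 4]]
  }, numeric(1))
  list(d6 = dt_from_matrix((D2 + t(D2)) / 2), w15 = w_out)
}

# In-plane (about-z) rotation matrix.
rot_z <- function(theta) {
  matrix(c(cos(theta), sin(theta), 0,
           -sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3)
}

#' Isotropic rank-4 kurtosis tensor with a given kurtosis
#'
#' Returns the 15 unique elements of the fully symmetric isotropic tensor for
#' which the apparent kurtosis equals `k` along every direction (given an
#' isotropic diffusion tensor).
#'
#' @param k target kurtosis (unitless).
#' @return numeric vector of length 15.
#' @export
kt_isotropic <- function(k) {
  w <- numeric(15)
  w[1:3] <- k          # xxxx, yyyy, zzzz
  w[10:12] <- k / 3    # xxyy, xxzz, yyzz
  w
}
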