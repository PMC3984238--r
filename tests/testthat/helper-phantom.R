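# Small phantom configurations shared across tests. Noise-free variants are
# used for exactness checks; SNR-20 variants for statistical properties.

tiny_config <- function(seed = 1L, snr = Inf, n = 32, nz = 2, ...) {
  phantom_config(matrix_size = n, n_slices = nz, snr_b0 = snr,
                 seed = seed, ...)
}

desk_config <- function(seed = 1L, n = 64, nz = 4, ...) {
  phantom_config(matrix_size = n, n_slices = nz, seed = seed, ...)
}

# random symmetric positive-definite diffusion tensor (um^2/ms scale)
random_spd <- function() {
  m <- matrix(rnorm(9, sd = 0.4), 3, 3)
  s <- crossprod(m) + diag(0.3, 3)
  s / mean(diag(s)) * 1.0
}

# random fully-symmetric kurtosis tensor via random rotation of an
# axially symmetric one
random_w15 <- function() {
  w <- kt_isotropic(runif(1, 0.3, 1.2))
  w[1] <- w[1] * runif(1, 0.5, 1.5)
  rt <- dkimoco:::rotate_tensors(c(1, 1, 1, 0, 0, 0), w,
                                 dkimoco:::rot_z(runif(1, 0, pi)))
  rt$w15
}

# brute-force LPCC straight from the definitions, using stats::cor per tile
lpcc_bruteforce <- function(obj, ref, mask, window) {
  n1 <- nrow(obj); n2 <- ncol(obj)
  starts1 <- seq(1, n1, window); starts2 <- seq(1, n2, window)
  rs <- c(); classes <- c()
  for (j0 in starts2) for (i0 in starts1) {
    ii <- i0:min(i0 + window - 1, n1); jj <- j0:min(j0 + window - 1, n2)
    a <- obj[ii, jj]; b <- ref[ii, jj]; m <- mask[ii, jj]
    classes <- c(classes, if (all(m == 0)) "S_b" else if (all(m > 0)) "S_t" else "S_bt")
    r <- if (length(a) < 2 || sd(a) == 0 || sd(b) == 0) 0 else
      cor(as.vector(a), as.vector(b))
    rs <- c(rs, r)
  }
  nb <- sum(classes == "S_b"); L <- length(rs)
  w <- ifelse(classes == "S_b", 0, 1 / (L - nb))
  sum(w * rs)
}

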