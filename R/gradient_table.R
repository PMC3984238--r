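#' Build a multi-shell gradient table
#'
#' Generates the acquisition scheme used throughout the package: `n_b0`
#' zero-weighting entries followed by, for each nonzero b-value, the same set
#' of `n_dirs` unit gradient directions. Directions are laid out on a
#' spherical Fibonacci spiral over the half-sphere (antipodal directions are
#' equivalent for diffusion weighting), then rotated by a random rotation
#' drawn from `seed` so different seeds give different but equally well-spread
#' schemes.
#'
#' @param n_dirs number of gradient directions per nonzero shell (>= 6).
#' @param bvals numeric vector of nonzero b-values in s/mm^2.
#' @param n_b0 number of b = 0 volumes.
#' @param seed integer seed for the random rotation of the direction set.
#' @return a tibble with one row per measurement volume and columns
#'   `volume`, `bval`, `gx`, `gy`, `gz`, `shell` (0 for b0) and `dir_index`
#'   (1..n_dirs within each shell, NA for b0).
#' @examples
#' gt <- make_gradient_table(25, c(500, 1000, 1500, 2000, 2500), 5, seed = 1)
#' nrow(gt)  # 5 + 125
#' @export
make_gradient_table <- function(n_dirs, bvals, n_b0 = 5, seed = 1L) {
  if (n_dirs < 6) stop("n_dirs must be >= 6: fewer directions leave the diffusion tensor under-determined")
  if (length(bvals) == 0) stop("bvals must be nonempty")
  if (any(bvals <= 0)) stop("bvals must be positive (b0 volumes are added via n_b0)")
  dirs <- fibonacci_hemisphere(n_dirs)
  rot <- random_rotation(seed)
  dirs <- dirs %*% t(rot)
  dirs <- dirs / sqrt(rowSums(dirs^2))

  b0 <- tibble::tibble(volume = seq_len(n_b0), bval = 0,
                       gx = 0, gy = 0, gz = 0, shell = 0L, dir_index = NA_integer_)
  shells <- purrr::map_dfr(seq_along(bvals), function(s) {
    tibble::tibble(bval = bvals[s],
                   gx = dirs[, 1], gy = dirs[, 2], gz = dirs[, 3],
                   shell = s, dir_index = seq_len(n_dirs))
  })
  shells$volume <- n_b0 + seq_len(nrow(shells))
  dplyr::bind_rows(b0, shells[, names(b0)])
}

# Evenly spread points on the upper hemisphere via the Fibonacci lattice.
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- (1 + sqrt(5)) / 2
  z <- i / n                       # cos(theta) in (0, 1): upper hemisphere
  theta <- acos(z)
  lon <- 2 * pi * i / phi
  cbind(sin(theta) * cos(lon), sin(theta) * sin(lon), z)
}

# Uniform random 3D rotation (QR of a Gaussian matrix, det corrected).
random_rotation <- function(seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q %*% diag(sign(diag(qr.R(qr_))))
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read an FSL-style bval/bvec pair into a gradient table
#'
#' @param bval_file path to a text file with one row of b-values.
#' @param bvec_file path to a text file with three rows (x, y, z components).
#' @param b0_threshold b-values at or below this are treated as b = 0.
#' @return gradient-table tibble (see [make_gradient_table()]).
#' @export
read_gradient_table <- function(bval_file, bvec_file, b0_threshold = 10) {
  bvals <- scan(bval_file, quiet = TRUE)
  bvec <- as.matrix(read.table(bvec_file))
  if (nrow(bvec) != 3) stop("bvec file must have three rows")
  if (ncol(bvec) != length(bvals)) stop("bval/bvec length mismatch")
  is_b0 <- bvals <= b0_threshold
  ub <- sort(unique(bvals[!is_b0]))
  shell <- integer(length(bvals))
  shell[!is_b0] <- match(bvals[!is_b0], ub)
  dir_index <- rep(NA_integer_, length(bvals))
  for (s in seq_along(ub)) dir_index[shell == s] <- seq_len(sum(shell == s))
  tibble::tibble(volume = seq_along(bvals), bval = ifelse(is_b0, 0, bvals),
                 gx = bvec[1, ], gy = bvec[2, ], gz = bvec[3, ],
                 shell = shell, dir_index = dir_index)
}

#' Write a gradient table as FSL-style bval/bvec files
#'
#' @param grad gradient-table tibble.
#' @param bval_file,bvec_file output paths.
#' @return invisibly, the two paths.
#' @export
write_gradient_table <- function(grad, bval_file, bvec_file) {
  writeLines(paste(format(grad$bval, trim = TRUE), collapse = " "), bval_file)
  m <- rbind(grad$gx, grad$gy, grad$gz)
  writeLines(apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = " ")),
             bvec_file)
  invisible(c(bval_file, bvec_file))
}
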