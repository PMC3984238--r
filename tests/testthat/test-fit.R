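test_that("design rows expand the log-linear kurtosis model", {
  expect_equal(design_row(0, c(0, 0, 0)), c(1, rep(0, 21)))
  r <- design_row(1000, c(1, 0, 0))
  expect_equal(r[1], 1)
  expect_equal(r[2], -1)            # -b Dxx with b = 1 ms/um^2
  expect_equal(r[8], 1 / 6)         # (b^2/6) Vxxxx
  expect_equal(sum(r != 0), 3)
  expect_error(design_row(1000, c(1, 1, 0)), "unit")

  # row . theta reproduces ln(forward_signal) for random tensors
  set.seed(20)
  for (i in 1:5) {
    D <- random_spd(); w <- random_w15()
    tis <- tissue_spec("t", 800, D, w)
    g <- rnorm(3); g <- g / sqrt(sum(g^2))
    b <- sample(c(500, 1000, 2500), 1)
    theta <- c(log(800), tis$d6, tis$md^2 * w)
    expect_equal(sum(design_row(b, g) * theta),
                 log(forward_signal(tis, b, g)), tolerance = 1e-10)
  }
})

test_that("noise-free phantom signals are recovered exactly by the CLLS fit", {
  ph <- render_phantom(tiny_config(seed = 21, snr = Inf))
  fit <- fit_dataset(ph, qc = NULL, mode = "conventional")
  tw <- tissue_white()
  # relative error per parameter block at a white-matter voxel
  wm <- which(ph$truth$tissue == 3L & ph$truth$field > 0.5, arr.ind = TRUE)[1, ]
  th <- fit$theta[wm[1], wm[2], wm[3], ]
  expect_equal(exp(th[1]), ph$truth$s0[wm[1], wm[2], wm[3]], tolerance = 1e-8)
  # maps equal the analytic truth everywhere in the brain
  expect_lt(max(abs(fit$maps$md - ph$truth$md), na.rm = TRUE), 1e-8)
  expect_lt(max(abs(fit$maps$fa - ph$truth$fa), na.rm = TRUE), 1e-7)
  expect_lt(max(abs(fit$maps$mk - ph$truth$mk), na.rm = TRUE), 1e-7)
})

test_that("a pure-DTI voxel yields a vanishing kurtosis block", {
  dti <- tissue_spec("dti", 700, diag(c(1.2, 0.6, 0.6)), rep(0, 15))
  gt <- make_gradient_table(25, c(500, 1000, 1500, 2000, 2500), 5, seed = 1)
  g <- as.matrix(gt[, c("gx", "gy", "gz")])
  s <- forward_signal(dti, gt$bval, g)
  dirs <- unique(g[gt$bval > 0, ])
  f <- fit_voxel_clls(s, design_matrix(gt), constraint_dirs = dirs, b_max = 2500)
  expect_equal(f$theta[2:7], dti$d6, tolerance = 1e-8)
  expect_lt(max(abs(f$theta[8:22])), 1e-8)
})

test_that("single-shell data is unfittable and flagged", {
  gt <- make_gradient_table(25, 1000, 5, seed = 1)
  tg <- tissue_gray()
  g <- as.matrix(gt[, c("gx", "gy", "gz")])
  s <- forward_signal(tg, gt$bval, g)
  # 30 rows >= 22 columns, but one shell cannot separate D from V
  f <- fit_voxel_clls(s, design_matrix(gt),
                      constraint_dirs = unique(g[gt$bval > 0, ]), b_max = 1000)
  expect_equal(f$status, "unfittable")
})

test_that("unconstrained mode equals the pseudo-inverse least-squares oracle", {
  ph <- render_phantom(tiny_config(seed = 22, snr = 20, n = 24, nz = 1))
  fit <- fit_dataset(ph, qc = NULL, mode = "conventional", constrained = FALSE)
  A <- design_matrix(ph$grad)
  vox <- which(ph$mask[, , 1] > 0, arr.ind = TRUE)[c(1, 50, 100), ]
  floor_ <- 0.5 * ph$sigma * sqrt(pi / 2)
  for (k in 1:3) {
    y <- log(pmax(ph$data[vox[k, 1], vox[k, 2], 1, ], floor_))
    oracle <- as.vector(MASS::ginv(A) %*% y)
    expect_equal(fit$theta[vox[k, 1], vox[k, 2], 1, ], oracle, tolerance = 1e-10)
  }
})

test_that("constrained fits satisfy the directional kurtosis bounds", {
  ph <- render_phantom(tiny_config(seed = 23, snr = 20, n = 24, nz = 1))
  fit <- fit_dataset(ph, qc = NULL, mode = "conventional", C = 3)
  dirs <- fit$constraint_dirs
  PD <- dkimoco:::dt_monomials(dirs)
  PV <- dkimoco:::kt_monomials(dirs)
  idx <- which(fit$status < 2L, arr.ind = TRUE)
  Tm <- apply(idx, 1, function(v) fit$theta[v[1], v[2], v[3], ])
  DA <- PD %*% Tm[2:7, ]
  VA <- PV %*% Tm[8:22, ]
  tol <- 1e-6
  expect_gt(min(DA), -tol)
  expect_gt(min(VA), -tol)
  expect_gt(min((3 / 2.5) * DA - VA), -tol)
})

test_that("scalar map derivations match their closed forms", {
  expect_equal(derive_md(c(3, 0, 0, 0, 0, 0)), 1)
  expect_equal(derive_md(diag(c(1, 2, 3))), 2)
  set.seed(24)
  D <- random_spd()
  expect_equal(derive_md(D), mean(eigen(D)$values), tolerance = 1e-12)
  expect_equal(derive_fa(diag(0.9, 3)), 0)
  expect_equal(derive_fa(diag(c(2, 0, 0))), 1)
  expect_equal(derive_fa(diag(c(1.7, 0.4, 0.4))), 0.7255890, tolerance = 1e-6)

  # MK: directional average equals a brute-force loop over directions
  w <- random_w15(); d6 <- dt_from_matrix(random_spd())
  md <- derive_md(d6)
  theta <- c(0, d6, md^2 * w)
  dirs <- dkimoco:::fibonacci_hemisphere(25)
  manual <- mean(vapply(seq_len(25), function(i) {
    g <- dirs[i, ]
    md^2 * w_app(g, w) / d_app(g, d6)^2
  }, numeric(1)))
  expect_equal(derive_mk(theta, dirs), manual, tolerance = 1e-12)
  # isotropic case returns the configured kurtosis for any direction set
  expect_equal(derive_mk(c(0, rep(1.1, 3), rep(0, 3), 1.1^2 * kt_isotropic(0.7)),
                         dirs), 0.7, tolerance = 1e-12)
  expect_equal(derive_mk(c(0, rep(1, 3), rep(0, 3), rep(0, 15)), dirs), 0)
})

test_that("Gaussian smoothing conserves mass and has the stated kernel", {
  ph <- render_phantom(tiny_config(seed = 25, snr = Inf, n = 24, nz = 1))
  expect_identical(smooth_dataset(ph, 0)$data, ph$data)
  # impulse response matches the separable kernel with sd fwhm/2.355/pixel
  imp <- ph
  imp$data <- array(0, dim(ph$data)[c(1, 2, 3)] |> c(1))
  dim(imp$data) <- c(24, 24, 1, 1)
  imp$data[12, 12, 1, 1] <- 1
  sm <- smooth_dataset(imp, 2.5)
  sd_px <- 2.5 / 2.3548200450309493 / 1.4
  K <- dkimoco:::gaussian_conv_matrix(24, sd_px)
  expect_equal(sm$data[, , 1, 1], outer(K[, 12], K[, 12]), tolerance = 1e-12)
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)  # away from boundary
})

test_that("the minimum-protocol rule drops thin shells and flags thin slices", {
  keep <- tidyr::expand_grid(slice = 1:2, shell = 1:3, direction_index = 1:25)
  keep$volume <- seq_len(nrow(keep))
  keep$rejected <- FALSE
  # slice 1 shell 2: reject 11 directions -> only 14 left -> whole shell drops
  keep$rejected[keep$slice == 1 & keep$shell == 2 & keep$direction_index <= 11] <- TRUE
  out <- enforce_minimum_protocol(keep)
  k1 <- out$keep[out$keep$slice == 1 & out$keep$shell == 2, ]
  expect_true(all(k1$rejected))
  expect_true(all(k1$shell_dropped))
  expect_true(out$slice_status$fittable[out$slice_status$slice == 1])  # 2 shells left
  expect_equal(out$slice_status$n_shells[out$slice_status$slice == 1], 2)
  # untouched slice is unchanged
  k2 <- out$keep[out$keep$slice == 2, ]
  expect_false(any(k2$rejected))
  # one surviving shell -> unfittable
  keep2 <- keep[keep$shell <= 2 & keep$slice == 1, ]
  keep2$rejected[keep2$shell == 2] <- TRUE
  out2 <- enforce_minimum_protocol(keep2)
  expect_false(out2$slice_status$fittable[1])
})

test_that("rejections on one slice never change the fit of another", {
  ph <- render_phantom(tiny_config(seed = 26, snr = 20, n = 24, nz = 2))
  full <- fit_dataset(ph, qc = NULL, mode = "conventional")
  excl <- tibble::tibble(slice = 1, volume = c(10, 40, 80))
  part <- fit_dataset(ph, qc = NULL, mode = "proposed", exclude = excl)
  expect_identical(part$theta[, , 2, ], full$theta[, , 2, ])
  expect_false(identical(part$theta[, , 1, ], full$theta[, , 1, ]))
})

test_that("an all-background slice yields an all-NA map row", {
  ph <- render_phantom(tiny_config(seed = 27, snr = Inf, n = 24, nz = 2))
  ph$mask[, , 2] <- 0L
  fit <- fit_dataset(ph, qc = NULL, mode = "conventional")
  expect_true(all(is.na(fit$maps$md[, , 2])))
  expect_true(all(is.finite(fit$maps$md[, , 1][ph$mask[, , 1] > 0])))
})
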