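test_that("forward signal reduces to its closed forms", {
  tg <- tissue_gray()
  g <- c(1, 0, 0)
  # b = 0 returns S0 exactly
  expect_equal(forward_signal(tg, 0, g), 1000)
  # isotropic D and W: S0 exp(-b d + b^2 d^2 K / 6) for any direction
  set.seed(5)
  for (i in 1:4) {
    gg <- rnorm(3); gg <- gg / sqrt(sum(gg^2))
    bb <- 2  # 2000 s/mm^2 in ms/um^2
    expect_equal(forward_signal(tg, 2000, gg),
                 1000 * exp(-bb * 1.1 + bb^2 * 1.1^2 * 0.7 / 6),
                 tolerance = 1e-12)
  }
  # W = 0 gives the monoexponential DTI limit
  dti <- tissue_spec("dti", 500, diag(0.8, 3), rep(0, 15))
  expect_equal(forward_signal(dti, 1500, g), 500 * exp(-1.5 * 0.8),
               tolerance = 1e-12)
  expect_error(forward_signal(tg, 1000, c(1, 1, 0)), "unit")
})

test_that("noise-free phantom equals the forward model and zero background", {
  ph <- render_phantom(tiny_config(seed = 3, snr = Inf))
  # background voxels carry no signal in any volume
  bg <- which(ph$mask == 0)
  expect_equal(max(abs(ph$data[, , , 10][bg])), 0)
  # a gray-matter voxel's signal across volumes matches forward_signal times
  # its local texture field
  gm <- which(ph$truth$tissue == 2L, arr.ind = TRUE)[1, ]
  g <- as.matrix(ph$grad[, c("gx", "gy", "gz")])
  expected <- forward_signal(tissue_gray(), ph$grad$bval, g) *
    ph$truth$field[gm[1], gm[2], gm[3]]
  expect_equal(ph$data[gm[1], gm[2], gm[3], ], expected, tolerance = 1e-10)
})

test_that("Rician noise calibrates the b0 SNR and Rayleigh background", {
  ph <- render_phantom(phantom_config(matrix_size = 128, n_slices = 6,
                                      snr_b0 = 20, seed = 11))
  b0 <- ph$data[, , , 1]
  bg <- b0[ph$mask == 0]
  expect_gt(length(bg), 1e4)
  snr <- mean(b0[ph$mask > 0]) / sd(bg)
  expect_lt(abs(snr / 20 - 1), 0.1)
  # background mean follows the Rayleigh closed form sigma * sqrt(pi/2)
  expect_lt(abs(mean(bg) / (ph$sigma * sqrt(pi / 2)) - 1), 0.05)
})

test_that("artifact injection honours its contracts", {
  ph <- render_phantom(tiny_config(seed = 4, snr = 20))
  # empty event list leaves the data untouched and labels clean
  out <- inject_artifacts(ph, list(), seed = 1)
  expect_identical(out$data, ph$data)
  expect_equal(nrow(out$truth_labels), 0)

  # complete loss at magnitude 0 leaves only the noise floor
  ev <- list(artifact_event("complete_loss", volume_index = 20,
                            slice_index = 1, magnitude = 0))
  out <- inject_artifacts(ph, ev, seed = 2)
  m <- ph$mask[, , 1] > 0
  lvl <- mean(out$data[, , 1, 20][m]) / (ph$sigma * sqrt(pi / 2))
  expect_lt(abs(lvl - 1), 0.1)
  expect_equal(out$truth_labels$volume, 20L)

  # mismatch is a pure integer translation with zero fill
  ev <- list(artifact_event("mismatch", volume_index = 30, slice_index = 2,
                            geometry = c(3, 0)))
  out <- inject_artifacts(ph, ev, seed = 3)
  orig <- ph$data[, , 2, 30]
  shifted <- out$data[, , 2, 30]
  expect_equal(shifted[4:32, ], orig[1:29, ])
  expect_equal(shifted[1:3, ], matrix(0, 3, 32))

  # misalignment labels every slice of the volume
  ev <- list(artifact_event("volume_misalignment", volume_index = 40,
                            magnitude = 5, geometry = c(2, 2)))
  out <- inject_artifacts(ph, ev, seed = 4)
  expect_equal(nrow(out$truth_labels), dim(ph$data)[3])

  # guard rails
  expect_error(inject_artifacts(ph, list(
    artifact_event("complete_loss", volume_index = 1, slice_index = 1))),
    "b0")
  expect_error(inject_artifacts(ph, list(
    artifact_event("complete_loss", volume_index = 20, slice_index = 1),
    artifact_event("local_loss", volume_index = 20, slice_index = 1))),
    "overlapping")
  expect_error(artifact_event("complete_loss", 10, 1, magnitude = 0.5),
               "magnitude")
})

test_that("phantom truth maps carry the configured tissue values", {
  cfg <- tiny_config(seed = 6, snr = Inf)
  ph <- render_phantom(cfg)
  wm <- ph$truth$tissue == 3L
  gm <- ph$truth$tissue == 2L
  expect_equal(unique(ph$truth$md[wm]), mean(c(1.7, 0.4, 0.4)))
  expect_equal(unique(ph$truth$md[gm]), 1.1)
  expect_equal(unique(ph$truth$fa[wm]), 0.7255890, tolerance = 1e-6)
  expect_equal(unique(ph$truth$fa[gm]), 0)
  expect_equal(unique(ph$truth$mk[gm]), 0.7, tolerance = 1e-12)
  if (any(ph$truth$tissue == 4L)) {
    expect_equal(unique(ph$truth$md[ph$truth$tissue == 4L]), 2.9)
  }
})
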