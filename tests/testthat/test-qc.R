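test_that("pearson matches the definition and handles degenerate regions", {
  a <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 10), 3, 3)
  b <- matrix(c(2, 1, 4, 4, 6, 5, 8, 9, 9), 3, 3)
  expect_equal(pearson(a, b), cor(as.vector(a), as.vector(b)), tolerance = 1e-14)
  expect_equal(pearson(a, a), 1)
  expect_equal(pearson(a, 2 * mean(a) - a), -1)  # negation about the mean
  expect_equal(pearson(a, matrix(5, 3, 3)), 0)   # flat region -> 0 by contract
  expect_error(pearson(a, 1:5), "shape")
})

test_that("tile classification covers the three region classes", {
  z <- matrix(0, 16, 16)
  g <- classify_tiles(z, 8)
  expect_equal(g$class, rep("S_b", 4))
  expect_equal(g$N_b, g$L)
  o <- classify_tiles(matrix(1, 16, 16), 8)
  expect_equal(o$class, rep("S_t", 4))
  expect_equal(o$N_b, 0)
  half <- matrix(0, 16, 16); half[1:4, 1:8] <- 1  # covers half of tile 1
  h <- classify_tiles(half, 8)
  expect_equal(h$class[1], "S_bt")
  # edge tiles smaller than the window are kept as partial tiles
  e <- classify_tiles(matrix(1, 20, 20), 8)
  expect_equal(e$L, 9)
})

test_that("tile weights are equal on tissue tiles and sum to one", {
  half <- matrix(0, 16, 16)
  half[, 9:16] <- 1; half[1:8, 1:8] <- 0  # tiles: S_b, S_b, S_t, S_t
  g <- classify_tiles(half, 8)
  w <- tile_weights(g)
  expect_equal(sum(w), 1)
  expect_equal(w[g$class == "S_b"], rep(0, g$N_b))
  expect_equal(unique(w[g$class != "S_b"]), 1 / (g$L - g$N_b))
  allbg <- classify_tiles(matrix(0, 16, 16), 8)
  expect_error(tile_weights(allbg), "no tissue")
})

test_that("lpcc equals the brute-force weighted sum of tile correlations", {
  set.seed(10)
  for (i in 1:20) {
    n1 <- sample(16:40, 1); n2 <- sample(16:40, 1)
    w <- sample(c(5, 8), 1)
    obj <- matrix(rnorm(n1 * n2), n1, n2)
    ref <- matrix(rnorm(n1 * n2), n1, n2)
    mask <- matrix(rbinom(n1 * n2, 1, 0.6), n1, n2)
    if (all(mask == 0)) mask[1, 1] <- 1
    expect_equal(lpcc(obj, ref, mask, window = w),
                 lpcc_bruteforce(obj, ref, mask, w), tolerance = 1e-12)
  }
})

test_that("lpcc is 1 on identical slices and invariant to affine rescaling", {
  set.seed(12)
  img <- matrix(rnorm(32 * 32), 32, 32)
  mask <- matrix(1, 32, 32)
  expect_equal(lpcc(img, img, mask), 1, tolerance = 1e-12)
  expect_equal(lpcc(3.2 * img + 7, img, mask), 1, tolerance = 1e-12)
  ref <- matrix(rnorm(32 * 32), 32, 32)
  base <- lpcc(img, ref, mask)
  expect_equal(lpcc(0.5 * img + 100, 2 * ref - 3, mask), base, tolerance = 1e-9)
})

test_that("ncc is a single global coefficient over the brain bounding box", {
  set.seed(13)
  img <- matrix(rnorm(24 * 24), 24, 24)
  mask <- matrix(0, 24, 24); mask[5:20, 7:18] <- 1
  expect_equal(ncc(img, img, mask), 1)
  ref <- matrix(rnorm(24 * 24), 24, 24)
  expect_equal(ncc(img, ref, mask),
               cor(as.vector(img[5:20, 7:18]), as.vector(ref[5:20, 7:18])),
               tolerance = 1e-14)
  # independent images decorrelate at the 3/sqrt(n) scale
  expect_lt(abs(ncc(img, ref, mask)), 3 / sqrt(16 * 12))
})

test_that("score normalization and the mean - 3 sd threshold behave as specified", {
  expect_equal(normalize_scores(c(0.9, 0.6, 0.3)), c(1, 2 / 3, 1 / 3))
  expect_equal(normalize_scores(rep(0.4, 5)), rep(1, 5))
  x <- runif(10, 0.1, 1)
  expect_equal(normalize_scores(normalize_scores(x)), normalize_scores(x))
  expect_error(normalize_scores(c(-1, -2)), "not positive")

  s <- rep(0.98, 25)
  expect_equal(rejection_threshold(s), 0.98)
  expect_equal(sum(s < rejection_threshold(s)), 0)  # ties are kept
  set.seed(14)
  grp <- c(rnorm(24, 1, 0.005), 0.5)
  thr <- rejection_threshold(grp)
  expect_true(grp[25] < thr)
  expect_equal(sum(grp[1:24] < thr), 0)
  expect_equal(rejection_threshold(sample(grp)), thr)
})

test_that("relative difference follows the published definition", {
  expect_equal(relative_difference(1.0, 0.5), 0.5)
  expect_equal(relative_difference(0.7, 0.7), 0)
  expect_equal(relative_difference(0.94, 0.68), 0.2766, tolerance = 1e-4)
  expect_error(relative_difference(0, 0.5), "nonzero")
})

test_that("b0 screening excludes a corrupted b0 and averages the survivors", {
  ph <- render_phantom(tiny_config(seed = 15, snr = 20))
  ev <- list(artifact_event("complete_loss", volume_index = 2,
                            slice_index = 1, magnitude = 0))
  pha <- inject_artifacts(ph, ev, seed = 1, allow_b0 = TRUE)
  ref <- select_b0_reference(pha)
  k1 <- ref$kept[ref$kept$slice == 1, ]
  expect_false(k1$kept[k1$volume == 2])
  expect_true(all(k1$kept[k1$volume != 2]))
  # untouched slice keeps all five
  expect_true(all(ref$kept$kept[ref$kept$slice == 2]))
  # averaging five clean b0s shrinks the background variance ~ 5x
  bg <- ph$mask[, , 2] == 0
  v_single <- var(ph$data[, , 2, 1][bg])
  v_ref <- var(ref$reference[, , 2][bg])
  expect_lt(abs(v_ref / (v_single / 5) - 1), 0.25)
})

test_that("run_qc flags exactly the scores strictly below their threshold", {
  ph <- render_phantom(tiny_config(seed = 16, snr = 20))
  ev <- list(artifact_event("complete_loss", volume_index = 10,
                            slice_index = 1, magnitude = 0))
  pha <- inject_artifacts(ph, ev, seed = 2)
  qc <- run_qc(pha)
  expect_s3_class(qc$scores, "tbl_df")
  expect_equal(nrow(qc$scores), 2 * 5 * 25)
  expect_identical(qc$scores$rejected, qc$scores$lpcc_norm < qc$scores$threshold)
  hit <- qc$scores[qc$scores$volume == 10 & qc$scores$slice == 1, ]
  expect_true(hit$rejected)
  # normalized scores peak at exactly 1 within every (slice, shell) group
  mx <- tapply(qc$scores$lpcc_norm, paste(qc$scores$slice, qc$scores$shell), max)
  expect_equal(as.vector(mx), rep(1, length(mx)))
})
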