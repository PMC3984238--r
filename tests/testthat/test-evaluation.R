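test_that("mse follows its definition on exact fixtures", {
  a <- array(rnorm(27), c(3, 3, 3))
  roi <- array(1, c(3, 3, 3))
  expect_equal(mse(a, a, roi), 0)
  expect_equal(mse(a + 0.3, a, roi), 0.09, tolerance = 1e-12)
  # 10-voxel fixture against a hand summation, with NaN excluded pairwise
  set.seed(30)
  est <- array(rnorm(27), c(3, 3, 3)); ref <- array(rnorm(27), c(3, 3, 3))
  roi2 <- array(0, c(3, 3, 3)); roi2[sample(27, 10)] <- 1
  est[which(roi2 == 1)[1]] <- NaN
  sel <- roi2 == 1 & is.finite(est)
  expect_equal(mse(est, ref, roi2), sum((est[sel] - ref[sel])^2) / sum(sel))
  expect_error(mse(est * NaN, ref, roi2), "empty")
})

test_that("background variance ignores the mask interior", {
  set.seed(31)
  map <- array(rnorm(40^3, 0, 2), c(40, 40, 40))
  mask <- array(0L, c(40, 40, 40)); mask[10:30, 10:30, 10:30] <- 1L
  s2 <- background_sigma2(map, mask)
  expect_lt(abs(s2 / 4 - 1), 0.05)
  map2 <- map; map2[mask == 1] <- 1e6
  expect_equal(background_sigma2(map2, mask), s2)
  expect_equal(background_sigma2(array(3, c(4, 4, 1)), array(0, c(4, 4, 1))), 0)
})

test_that("sigma2 lower bound is mean minus sample sd", {
  expect_equal(sigma2_lower_bound(c(4, 4, 4)), 4)
  expect_equal(sigma2_lower_bound(c(3, 5)), 4 - sqrt(2))
  expect_error(sigma2_lower_bound(4), "2 replicates")
})

test_that("direction subsets drop a trailing consecutive block", {
  ds <- direction_subsets(15:25)
  expect_equal(nrow(ds), 11)
  expect_equal(ds$keep_dirs[[which(ds$n_dirs == 25)]], 1:25)
  expect_equal(ds$keep_dirs[[which(ds$n_dirs == 15)]], 1:15)
  for (k in ds$keep_dirs) expect_equal(k, seq_len(length(k)))
  expect_error(direction_subsets(5), ">= 6")
})

test_that("the b-value combination table is the fixed 26-row enumeration", {
  bc <- bvalue_combinations()
  expect_equal(nrow(bc), 26)
  expect_equal(unname(table(bc$n_b)), c(10L, 10L, 5L, 1L), ignore_attr = TRUE)
  expect_equal(bc$bvals[[which(bc$label == "2_#2")]], c(1000, 2500))
  expect_equal(bc$bvals[[which(bc$label == "5")]], c(500, 1000, 1500, 2000, 2500))
  expect_equal(bc$bvals[[which(bc$label == "3_#10")]], c(500, 1000, 1500))
  # every subset of sizes 2..5 appears exactly once
  key <- vapply(bc$bvals, paste, character(1), collapse = ",")
  expect_equal(anyDuplicated(key), 0)
  expect_identical(bvalue_combinations(), bc)  # stable enumeration
})

test_that("white-matter ROI selection is threshold-monotone", {
  ph <- render_phantom(tiny_config(seed = 32, snr = Inf))
  roi <- white_matter_roi(ph$truth$fa, lower = 0.3)
  wm <- ph$truth$tissue == 3L
  expect_true(all(roi[wm]))           # the band (FA 0.73) is inside the ROI
  expect_false(any(roi[ph$truth$tissue == 2L]))
  roi2 <- white_matter_roi(ph$truth$fa, lower = 0.5)
  expect_true(all(roi[roi2]))         # raising the cut shrinks the ROI
  band <- white_matter_roi(ph$truth$fa, lower = 0.15, upper = 0.9, mode = "band")
  expect_identical(band, !is.na(ph$truth$fa) & ph$truth$fa >= 0.15 &
                     ph$truth$fa <= 0.9)
  expect_error(white_matter_roi(array(0, c(2, 2, 2))), "empty ROI")
})

test_that("roi_compare degenerates gracefully on identical map pairs", {
  maps <- replicate(6, list(mk = array(runif(8), c(2, 2, 2)),
                            md = array(runif(8), c(2, 2, 2)),
                            fa = array(runif(8), c(2, 2, 2))),
                    simplify = FALSE)
  out <- roi_compare(maps, maps, array(TRUE, c(2, 2, 2)))
  expect_equal(out$p_value, rep(1, 3))
  expect_false(any(out$significant))
})

test_that("protocol subsets reproduce the reference exactly on noise-free data", {
  cfg <- tiny_config(seed = 33, snr = Inf, n = 24, nz = 1)
  subs <- dplyr::bind_rows(
    direction_subsets(c(20, 25))[, c("label", "keep_dirs")],
    bvalue_combinations()[bvalue_combinations()$label == "2_#2",
                          c("label", "bvals")])
  rep <- protocol_experiment(cfg, subs, seeds = 1:2, fwhm = 0,
                             n_background = 50)
  s <- rep$summary
  expect_equal(s$mse_mean[s$label == "dirs_25"], rep(0, 3))
  expect_lt(max(s$mse_mean), 1e-12)   # exact model, any determinate subset
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(glance(rep)$n_subsets, 3)
})
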