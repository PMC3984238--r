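test_that("gradient table has the expected layout for the reference scheme", {
  gt <- make_gradient_table(25, c(500, 1000, 1500, 2000, 2500), 5, seed = 1)
  expect_equal(nrow(gt), 130)
  expect_equal(sum(gt$bval == 0), 5)
  expect_equal(unname(table(gt$bval[gt$bval > 0])), rep(25L, 5),
               ignore_attr = TRUE)
  nrm <- with(gt[gt$bval > 0, ], sqrt(gx^2 + gy^2 + gz^2))
  expect_equal(nrm, rep(1, 125), tolerance = 1e-12)
  # the same direction set is reused across shells
  d1 <- as.matrix(gt[gt$shell == 1, c("gx", "gy", "gz")])
  d5 <- as.matrix(gt[gt$shell == 5, c("gx", "gy", "gz")])
  expect_equal(d1, d5)
})

test_that("gradient table is deterministic in the seed and errors below 6 directions", {
  a <- make_gradient_table(25, c(500, 1000), 5, seed = 7)
  b <- make_gradient_table(25, c(500, 1000), 5, seed = 7)
  expect_identical(a, b)
  c <- make_gradient_table(25, c(500, 1000), 5, seed = 8)
  expect_false(isTRUE(all.equal(a$gx, c$gx)))
  expect_error(make_gradient_table(5, 1000, 5), "under-determined")
})

test_that("bval/bvec files round-trip through the FSL format", {
  gt <- make_gradient_table(12, c(1000, 2500), 3, seed = 2)
  bval <- tempfile(fileext = ".bval"); bvec <- tempfile(fileext = ".bvec")
  write_gradient_table(gt, bval, bvec)
  back <- read_gradient_table(bval, bvec)
  expect_equal(back$bval, gt$bval)
  expect_equal(back$shell, gt$shell)
  expect_equal(cbind(back$gx, back$gy, back$gz),
               cbind(gt$gx, gt$gy, gt$gz), tolerance = 1e-9,
               ignore_attr = TRUE)
  unlink(c(bval, bvec))
})
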