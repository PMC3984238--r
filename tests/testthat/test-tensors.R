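test_that("diffusion-tensor element packing round-trips and validates", {
  m <- matrix(c(1.7, 0.1, 0.2, 0.1, 0.4, 0.05, 0.2, 0.05, 0.4), 3, 3)
  expect_equal(dt_to_matrix(dt_from_matrix(m)), m)
  expect_error(dt_from_matrix(matrix(rnorm(9), 3, 3)), "symmetric")
})

test_that("rank-4 contraction with multiplicities matches brute-force summation", {
  set.seed(41)
  for (i in 1:5) {
    w <- rnorm(15)
    g <- rnorm(3); g <- g / sqrt(sum(g^2))
    expect_equal(w_app(g, w), dkimoco:::w_app_bruteforce(g, w), tolerance = 1e-12)
  }
})

test_that("isotropic kurtosis tensor gives the same W_app along every direction", {
  w <- kt_isotropic(0.7)
  set.seed(42)
  g <- matrix(rnorm(30), 10, 3)
  g <- g / sqrt(rowSums(g^2))
  expect_equal(w_app(g, w), rep(0.7, 10), tolerance = 1e-12)
})

test_that("tensor rotation is a similarity transform for both ranks", {
  set.seed(43)
  d6 <- dt_from_matrix(random_spd())
  w15 <- rnorm(15)
  R <- dkimoco:::rot_z(0.7)
  rt <- dkimoco:::rotate_tensors(d6, w15, R)
  for (i in 1:4) {
    g <- rnorm(3); g <- g / sqrt(sum(g^2))
    gb <- as.vector(t(R) %*% g)
    expect_equal(d_app(g, rt$d6), d_app(gb, d6), tolerance = 1e-12)
    expect_equal(w_app(g, rt$w15), w_app(gb, w15), tolerance = 1e-12)
  }
  # rotation preserves the isotropic invariants
  expect_equal(derive_md(rt$d6), derive_md(d6), tolerance = 1e-12)
  expect_equal(derive_fa(rt$d6), derive_fa(d6), tolerance = 1e-10)
})
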