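test_that("MR-informed Gaussian weights obey the closed form and symmetry", {
  # uniform MR: every in-grid neighbour weight is 1
  w <- gaussian_mr_weights(matrix(5, 6, 6), sigma_mr = 1)
  ing <- fbsem:::uniform_weights(c(6, 6))
  for (k in seq_along(w)) expect_equal(w[[k]], ing[[k]])

  # intensity step of exactly sigma gives exp(-1/2) across the edge
  mr <- matrix(0, 6, 6); mr[, 4:6] <- 2
  w <- gaussian_mr_weights(mr, sigma_mr = 2)
  st <- fbsem:::default_stencil()
  k_right <- which(st$di == 0 & st$dj == 1)
  expect_equal(w[[k_right]][3, 3], exp(-1 / 2), tolerance = 1e-12)
  expect_equal(w[[k_right]][3, 2], 1, tolerance = 1e-12)

  # symmetry w_jb = w_bj on a random toy image
  set.seed(4)
  w <- gaussian_mr_weights(matrix(runif(16), 4, 4), sigma_mr = 0.3)
  opp <- fbsem:::opposite_index(st)
  for (k in seq_along(w)) {
    w_bj <- fbsem:::shift_image(w[[opp[k]]], -st$di[k], -st$dj[k])
    ok <- fbsem:::uniform_weights(c(4, 4))[[k]] > 0
    expect_equal(w[[k]][ok], w_bj[ok], tolerance = 1e-12)
  }

  # constant MR with auto sigma falls back to uniform weights
  w <- gaussian_mr_weights(matrix(1, 5, 5), sigma_mr = "auto")
  for (k in seq_along(w)) expect_equal(w[[k]], fbsem:::uniform_weights(c(5, 5))[[k]])
})

test_that("quadratic prior value matches hand evaluations and scales quadratically", {
  w2 <- fbsem:::uniform_weights(c(1, 2))
  expect_equal(tikhonov_value(matrix(c(0, 1), 1, 2), w2), 1)
  w <- fbsem:::uniform_weights(c(5, 5))
  expect_equal(tikhonov_value(matrix(3, 5, 5), w), 0)
  set.seed(1)
  x <- matrix(runif(25), 5)
  expect_equal(tikhonov_value(3 * x, w), 9 * tikhonov_value(x, w),
               tolerance = 1e-12)
})

test_that("prior gradient is exact for the pair-once penalty", {
  w2 <- fbsem:::uniform_weights(c(1, 2))
  expect_equal(as.vector(tikhonov_gradient(matrix(c(0, 1), 1, 2), w2)), c(-1, 1))
  w <- fbsem:::uniform_weights(c(8, 8))
  expect_equal(max(abs(tikhonov_gradient(matrix(2, 8, 8), w))), 0)

  # central differences of the pair-once penalty P = value / 2
  set.seed(2)
  x <- matrix(runif(64), 8)
  wg <- gaussian_mr_weights(matrix(runif(64), 8), sigma_mr = 0.5)
  g <- tikhonov_gradient(x, wg)
  h <- 1e-5
  num <- matrix(0, 8, 8)
  for (i in seq_len(64)) {
    e <- matrix(0, 8, 8); e[i] <- h
    num[i] <- (tikhonov_value(x + e, wg) - tikhonov_value(x - e, wg)) / (4 * h)
  }
  expect_lt(max(abs(num - g)) / max(abs(g)), 1e-5)
})

test_that("De Pierro regularization image equals the generic step and hand values", {
  w2 <- fbsem:::uniform_weights(c(1, 2))
  expect_equal(as.vector(depierro_reg_image(matrix(c(0, 1), 1, 2), w2)),
               c(0.5, 0.5))
  w <- fbsem:::uniform_weights(c(6, 6))
  xu <- matrix(4, 6, 6)
  expect_equal(depierro_reg_image(xu, w), xu)
  # isolated voxel (no neighbours) is returned unchanged
  expect_equal(depierro_reg_image(matrix(3, 1, 1), fbsem:::uniform_weights(c(1, 1))),
               matrix(3, 1, 1))

  set.seed(3)
  for (rep in 1:5) {
    x <- matrix(runif(64), 8)
    wg <- gaussian_mr_weights(matrix(runif(64), 8), sigma_mr = 0.4)
    wsum <- Reduce(`+`, wg)
    generic <- x - (1 / wsum) * 0.5 * tikhonov_gradient(x, wg)
    expect_lt(max(abs(generic - depierro_reg_image(x, wg))), 1e-12)
  }
})

test_that("the quadratic penalty is convex on random pairs", {
  set.seed(5)
  w <- gaussian_mr_weights(matrix(runif(36), 6), sigma_mr = 0.5)
  for (rep in 1:10) {
    x <- matrix(rnorm(36), 6); z <- matrix(rnorm(36), 6)
    lam <- runif(1)
    lhs <- tikhonov_value(lam * x + (1 - lam) * z, w)
    rhs <- lam * tikhonov_value(x, w) + (1 - lam) * tikhonov_value(z, w)
    expect_lte(lhs, rhs + 1e-10)
  }
})

test_that("prior model bundles weights with distance scaling", {
  mr <- fix_phantom32()$mr
  pr <- tikhonov_prior(gaussian_mr_weights(mr), distance_weighting = TRUE)
  st <- pr$stencil
  diag_k <- which(st$di == 1 & st$dj == 1)
  straight_k <- which(st$di == 1 & st$dj == 0)
  # diagonal neighbours are down-weighted by sqrt(2)
  pru <- tikhonov_prior(dim2 = c(4, 4), distance_weighting = TRUE)
  expect_equal(pru$weights[[diag_k]][2, 2] * sqrt(2),
               pru$weights[[straight_k]][2, 2])
  x <- fix_phantom32()$activity
  expect_equal(pr$penalty(x), pr$value(x) / 2)
  expect_equal(pr$gradient(x), tikhonov_gradient(x, pr$weights))
})
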