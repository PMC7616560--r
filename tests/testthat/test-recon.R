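test_that("log-posterior matches the Poisson closed forms", {
  tiny <- fix_tiny8()
  model <- tiny$model
  x <- tiny$act
  lam <- forward_project(model, x) + tiny$sino$randoms
  y <- tiny$sino$counts
  pos <- y > 0
  manual <- sum(y[pos] * log(lam[pos]) - lam[pos]) - sum(lam[!pos])
  expect_equal(log_posterior(model, tiny$sino, x), manual, tolerance = 1e-12)

  # beta = 0 equals the pure log-likelihood even with a prior attached
  pr <- tikhonov_prior(dim2 = c(8, 8))
  expect_equal(log_posterior(model, tiny$sino, x, pr, beta = 0),
               log_posterior(model, tiny$sino, x))
  expect_equal(log_posterior(model, tiny$sino, x, pr, beta = 2),
               manual - 2 * pr$penalty(x), tolerance = 1e-12)

  # y > 0 with zero mean is -Inf
  sino0 <- sinogram(y, 0, model$geometry)
  expect_identical(log_posterior(model, sino0, matrix(0, 8, 8)), -Inf)
})

test_that("EM update matches a dense-matrix oracle and is homogeneous in counts", {
  tiny <- fix_tiny8()
  model <- tiny$model
  H <- tiny$H
  x <- matrix(1, 8, 8)
  for (m in 1:2) {
    rows <- model$subset_rows[[m]]
    ybar <- H[rows, ] %*% as.vector(x) + tiny$sino$randoms[rows]
    ratio <- tiny$sino$counts[rows] / as.vector(ybar)
    s <- colSums(H[rows, ])
    oracle <- as.vector(x) * as.vector(crossprod(H[rows, ], ratio)) / s
    upd <- em_update(model, tiny$sino, x, m)
    expect_lt(max(abs(as.vector(upd) - oracle)), 1e-10)
    expect_true(all(upd >= 0))
  }

  # with no randoms, doubling the counts doubles the update
  y2 <- sinogram(2 * tiny$sino$counts, 0, model$geometry)
  y1 <- sinogram(tiny$sino$counts, 0, model$geometry)
  set.seed(8)
  x <- matrix(runif(64, 0.5, 2), 8)
  expect_equal(em_update(model, y2, x, 1), 2 * em_update(model, y1, x, 1),
               tolerance = 1e-10)
})

test_that("fusion returns the exact non-negative quadratic root", {
  set.seed(6)
  n <- 1e4
  de <- 10^runif(n, -3, 1)
  xe <- runif(n, 0, 5)
  xr <- runif(n, -2, 5)
  out <- fuse_images(xe, xr, de)
  expect_true(all(out >= 0))
  expect_lt(max(abs(de * out^2 + (1 - de * xr) * out - xe)), 1e-10)

  # against a numeric root finder on a subsample
  for (i in sample.int(n, 50)) {
    root <- uniroot(function(z) de[i] * z^2 + (1 - de[i] * xr[i]) * z - xe[i],
                    c(0, xe[i] + abs(xr[i]) + 10), tol = 1e-14)$root
    expect_equal(out[i], root, tolerance = 1e-8)
  }

  # delta -> 0 recovers the EM image; consistent fixed point
  expect_equal(fuse_images(xe, xr, 0), xe)
  expect_equal(fuse_images(rep(2, 5), rep(2, 5), runif(5, 0.01, 1)), rep(2, 5),
               tolerance = 1e-12)
})

test_that("no-prior splitting reconstruction is exactly OSEM", {
  model <- fix_model32()
  sino <- fix_sino32()$sino
  a <- fbsem_reconstruct(model, sino, recon_config(n_iterations = 10))
  b <- osem_reconstruct(model, sino, n_iterations = 10)
  expect_lt(max(abs(a$image - b$image)) / max(b$image), 1e-12)
  expect_identical(a$method, "OSEM")

  # gamma = Inf with a prior attached is the same degenerate limit
  pr <- tikhonov_prior(gaussian_mr_weights(fix_phantom32()$mr))
  cfg <- recon_config(n_iterations = 10, prior = pr, beta = 1, gamma = Inf)
  c_ <- fbsem_reconstruct(model, sino, cfg)
  expect_lt(max(abs(c_$image - b$image)) / max(b$image), 1e-12)
})

test_that("MLEM and De Pierro MAPEM increase their objectives monotonically", {
  toy <- fix_toy16()
  r_ml <- fbsem_reconstruct(toy$model, toy$sino,
                            recon_config(n_iterations = 30, record_objective = TRUE))
  d <- diff(r_ml$trace)
  expect_true(all(d >= -1e-8 * abs(r_ml$trace[-1])))

  pr <- tikhonov_prior(gaussian_mr_weights(toy$mr))
  cfg <- recon_config(n_iterations = 30, prior = pr, beta = 2,
                      mode = "depierro", record_objective = TRUE)
  r_map <- fbsem_reconstruct(toy$model, toy$sino, cfg)
  d <- diff(r_map$trace)
  expect_true(all(d >= -1e-8 * abs(r_map$trace[-1])))
  expect_true(all(r_map$image >= 0))
})

test_that("MLEM conserves sensitivity-weighted total counts after one iteration", {
  toy <- fix_toy16()
  # counts drawn with no randoms so every event comes from the forward model
  sino0 <- sample_poisson(toy$model, toy$reference, 0, seed = 13)
  x1 <- em_update(toy$model, sino0, matrix(1, 16, 16), 1)
  expect_equal(sum(toy$model$sens[, 1] * as.vector(x1)), sum(sino0$counts),
               tolerance = 1e-8)
})

test_that("gamma tuning selects by NRMSE and respects its contract", {
  toy <- fix_toy16()
  pr <- tikhonov_prior(gaussian_mr_weights(toy$mr))
  samples <- list(list(sino = toy$sino, reference = toy$reference, prior = pr))
  single <- tune_gamma(toy$model, samples, gamma_grid = 0.37, n_iterations = 5)
  expect_equal(single$gamma, 0.37)
  expect_error(tune_gamma(toy$model, samples, numeric(0)), "non-empty")

  # very-low-count ordered-subset study: regularization clearly helps, so the
  # regularized grid point beats the near-OSEM one (100 gamma*)
  geom <- toy$model$geometry
  model6 <- build_system(geom, NULL, n_subsets = 6)
  sc <- scale_to_counts(model6, toy$reference, 3e3, randoms_fraction = 0.2)
  noisy <- sample_poisson(model6, sc$x, sc$randoms, seed = 17)
  g0 <- 1 / (2 * mean(pr$wsum))
  res <- tune_gamma(model6, list(list(sino = noisy, reference = sc$x, prior = pr)),
                    gamma_grid = c(g0, 100 * g0), n_iterations = 10)
  expect_true(res$gamma %in% c(g0, 100 * g0))
  expect_equal(res$gamma, g0)
})

test_that("reconstruction objects print and expose residual sinograms", {
  toy <- fix_toy16()
  fit <- fbsem_reconstruct(toy$model, toy$sino, recon_config(n_iterations = 3))
  expect_output(print(fit), "OSEM")
  r <- residuals(fit)
  expect_length(r, toy$model$geometry$n_lor)
  expect_equal(r, toy$sino$counts - forward_project(toy$model, fit$image) -
                 toy$sino$randoms)
})
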