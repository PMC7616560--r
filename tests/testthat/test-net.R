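test_that("unit parameter counts match the architecture arithmetic", {
  p <- build_unit("pet", seed = 1)
  expect_identical(count_params(p), 320L + 3L * 9248L + 289L + 4L * 64L + 2L + 1L)
  # layer-wise: conv weights + biases + affine BN
  sizes <- vapply(p$layers, function(L) length(L$W) + length(L$b), numeric(1))
  expect_equal(sizes, c(288 + 32, 9216 + 32, 9216 + 32, 9216 + 32, 288 + 1))

  pm <- build_unit("petmr", seed = 1)
  expect_identical(nrow(pm$layers[[1]]$W), 9L * 2L)   # 2-channel first layer
  expect_identical(count_params(pm), count_params(p) + 288L)
})

test_that("zero final-layer unit acts as the identity and clamps negatives", {
  p <- build_unit("pet", seed = 3)
  p$layers[[5]]$W[] <- 0
  x <- fix_phantom32()$activity
  expect_equal(reg_step_net(p, x), x, tolerance = 1e-12)

  # arbitrary weights: output is never negative, shape is preserved
  q <- build_unit("pet", seed = 4)
  set.seed(5)
  for (n in c(32L, 48L)) {
    xr <- matrix(rnorm(n * n), n)
    out <- reg_step_net(q, xr)
    expect_identical(dim(out), c(n, n))
    expect_true(all(out >= 0))
  }
  expect_error(reg_step_net(q, x, mr = NULL), NA)
  qm <- build_unit("petmr", seed = 4)
  expect_error(reg_step_net(qm, x), "MR")
})

test_that("backpropagated gradients match finite differences when EM is frozen", {
  tiny <- fix_tiny8()
  model <- tiny$model
  Y <- matrix(tiny$sino$counts, ncol = 1)
  Rb <- matrix(tiny$sino$randoms, ncol = 1)
  sens <- lapply(1:2, function(m) matrix(model$sens[, m], ncol = 1))
  ref <- as.vector(tiny$act)
  p <- build_unit("pet", seed = 1)

  loss_of <- function(params, frozen = NULL) {
    fw <- fbsem:::unrolled_pass(params, model, Y, Rb, NULL, NULL, sens,
                                n_it = 2, n_sub = 2, keep_cache = TRUE,
                                frozen_em = frozen)
    mean((fw$x - ref)^2)
  }
  fw <- fbsem:::unrolled_pass(p, model, Y, Rb, NULL, NULL, sens,
                              n_it = 2, n_sub = 2, keep_cache = TRUE)
  frozen <- lapply(fw$caches, function(cc) cc$x_em)
  d <- matrix(2 * (fw$x - ref) / length(fw$x), 64, 1)
  bw <- fbsem:::unrolled_bwd(p, fw$caches, d, 8, 1)

  h <- 1e-5
  set.seed(2)
  full_diffs <- numeric(0)
  for (trial in 1:10) {
    l <- sample(1:5, 1)
    wi <- sample(length(p$layers[[l]]$W), 1)
    pp <- p; pp$layers[[l]]$W[wi] <- pp$layers[[l]]$W[wi] + h
    pm <- p; pm$layers[[l]]$W[wi] <- pm$layers[[l]]$W[wi] - h
    num <- (loss_of(pp, frozen) - loss_of(pm, frozen)) / (2 * h)
    ana <- bw$grads[[l]]$dW[wi]
    expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-8), 0.05)
    # unfrozen forward re-runs the EM chain: its sensitivity differs
    num_live <- (loss_of(pp) - loss_of(pm)) / (2 * h)
    full_diffs <- c(full_diffs, abs(num_live - ana) /
                      max(abs(num_live) + abs(ana), 1e-12))
  }
  # gradients are NOT those of the fully differentiated chain: the EM path
  # is detached by construction
  expect_gt(max(full_diffs), 0.1)

  # gamma gradient (exact single-state check)
  fw1 <- fbsem:::unrolled_pass(p, model, Y, Rb, NULL, NULL, sens,
                               n_it = 1, n_sub = 1, keep_cache = TRUE)
  d1 <- matrix(2 * (fw1$x - ref) / length(fw1$x), 64, 1)
  bw1 <- fbsem:::unrolled_bwd(p, fw1$caches, d1, 8, 1)
  loss1 <- function(params) {
    fw <- fbsem:::unrolled_pass(params, model, Y, Rb, NULL, NULL, sens,
                                n_it = 1, n_sub = 1)
    mean((fw$x - ref)^2)
  }
  pp <- p; pp$rho <- p$rho + h
  pm <- p; pm$rho <- p$rho - h
  num <- (loss1(pp) - loss1(pm)) / (2 * h)
  expect_lt(abs(num - bw1$drho) / max(abs(num), 1e-10), 1e-4)
})

test_that("with an identity unit and large gamma the unrolled net matches OSEM", {
  tiny <- fix_tiny8()
  p <- build_unit("pet", seed = 2)
  p$rho <- 20
  p$layers[[5]]$W[] <- 0
  out <- unrolled_forward(p, tiny$model, tiny$sino, n_it = 10)
  os <- osem_reconstruct(tiny$model, tiny$sino, n_iterations = 10)$image
  expect_lt(max(abs(out - os)) / max(os), 1e-8)
  # the state count is n_it * n_sub by construction
  expect_identical(tiny$model$n_subsets * 10L, 20L)
})

test_that("training on a tiny problem reduces the loss and is seed-reproducible", {
  tiny <- fix_tiny8()
  samples <- lapply(1:5, function(s) {
    lam <- forward_project(tiny$model, tiny$act) + 0.5
    y <- with_seed_test(100 + s, rpois(length(lam), lam))
    list(counts = y, randoms = 0.5, reference = tiny$act)
  })
  fit <- fbsem_net(tiny$model, samples, input_mode = "pet", n_iterations = 2,
                   epochs = 10, n_minibatches = 2, lr = 0.01, seed = 6)
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  expect_gt(fit$gamma, 0)
  expect_identical(fit$n_params, 28612L)

  fit2 <- fbsem_net(tiny$model, samples, input_mode = "pet", n_iterations = 2,
                    epochs = 10, n_minibatches = 2, lr = 0.01, seed = 6)
  expect_identical(fit$loss_history, fit2$loss_history)
  expect_identical(coef(fit), coef(fit2))

  img <- predict(fit, tiny$model, tiny$sino)
  expect_identical(dim(img), c(8L, 8L))
  expect_true(all(img >= 0))
  expect_output(print(fit), "28612")
})

test_that("PET+MR mode trains and uses the MR channel", {
  tiny <- fix_tiny8()
  mr <- tiny$act[, 8:1]  # co-registered structural channel
  samples <- lapply(1:3, function(s) {
    lam <- forward_project(tiny$model, tiny$act) + 0.5
    y <- with_seed_test(200 + s, rpois(length(lam), lam))
    list(counts = y, randoms = 0.5, reference = tiny$act, mr = mr)
  })
  fit <- fbsem_net(tiny$model, samples, input_mode = "petmr", n_iterations = 1,
                   epochs = 4, n_minibatches = 1, lr = 0.01, seed = 2)
  expect_lt(tail(fit$loss_history, 1), fit$loss_history[1])
  img1 <- predict(fit, tiny$model, tiny$sino, mr = mr)
  img2 <- predict(fit, tiny$model, tiny$sino, mr = mr * 0)
  expect_false(identical(img1, img2))
  expect_error(predict(fit, tiny$model, tiny$sino), "MR")
})
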