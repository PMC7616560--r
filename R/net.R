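# The unrolled reconstruction network: a recurrent chain of
# N = N_it x N_sub states. Each state replaces the gradient regularization
# step by a residual convolutional learning unit, keeps the (non-trainable)
# ordered-subset EM update, and fuses the two images with the closed-form
# quadratic root whose coupling weight delta = 1 / (gamma s^(m)) carries the
# single trainable regularization scalar gamma. All states share one
# parameter set. Convolutions, batch normalization, backpropagation and the
# Adam optimizer are implemented here directly on BLAS-backed matrices.
#
# Layout: activations are channels x pixels matrices (pixels of a batch of
# vectorized n x n images, sample-major). A 3x3 convolution is an im2col
# gather plus a single BLAS product, implemented in C++ (src/conv.cpp).

NET_CHANNELS <- c(32L, 32L, 32L, 32L, 1L)

# ---- convolution (compiled kernels) ----------------------------------------

# 3x3 convolution as im2col + one BLAS product, in C++ (src/conv.cpp).
# Kernels are stored stacked: W is a (9 * Cin) x Cout matrix whose k-th
# Cin-row block is the kernel tap for the k-th neighbourhood offset.
conv_fwd <- function(A, W, b, n, batch) {
  .conv_fwd_cpp(A, W, b, n, batch)
}

conv_bwd <- function(dY, A, W, n, batch) {
  .conv_bwd_cpp(dY, A, W, n, batch)
}

# Feature normalization over the pixels of the current pass (per channel),
# with trainable affine scale/shift. The same statistics are used in
# training and inference.
bn_fwd <- function(A, g, b, eps = 1e-5) {
  mu <- rowMeans(A)
  v <- rowMeans(A^2) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- (A - mu) * invstd
  list(Y = xhat * g + b, xhat = xhat, invstd = invstd)
}

bn_bwd <- function(dY, cache, g) {
  dxhat <- dY * g
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dA <- cache$invstd * (dxhat - m1 - cache$xhat * m2)
  list(dA = dA, dg = rowSums(dY * cache$xhat), db = rowSums(dY))
}

# ---- residual learning unit ------------------------------------------------

#' Build the residual learning unit
#'
#' A 5-layer convolutional unit: 3x3 kernels, layers 1-4 with 32 output
#' channels, layer 5 with 1 output channel; every convolution carries a bias
#' and is followed by affine batch normalization; hidden layers use a ReLU
#' nonlinearity after the normalization. The unit output is added residually
#' to the input PET channel and clamped non-negative by a ReLU, so the unit
#' learns a correction rather than a mapping. PET-only mode takes 1 input
#' channel; PET+MR mode takes 2. Together with the trainable fusion scalar
#' gamma, PET-only mode has 28612 trainable parameters.
#'
#' Hidden-layer weights use He initialization; the final layer is
#' initialized near zero so the untrained unit is close to the identity, and
#' gamma is trained on a log scale (initial value 1) to keep it positive.
#'
#' @param input_mode `"pet"` (1 channel) or `"petmr"` (2 channels)
#' @param seed integer seed for the random initialization
#' @return an object of class `net_params`: per-layer stacked kernel
#'   matrices `W` (`9 * in_channels` by `out_channels`), biases, and affine
#'   batch normalization parameters, plus the log-scale fusion parameter
#'   `rho` (`gamma = exp(rho)`)
#' @export
build_unit <- function(input_mode = c("pet", "petmr"), seed = 1L) {
  input_mode <- match.arg(input_mode)
  cin <- c(if (input_mode == "pet") 1L else 2L, NET_CHANNELS[-5])
  cout <- NET_CHANNELS
  with_seed(seed, {
    layers <- lapply(1:5, function(l) {
      sc <- if (l == 5) 0.01 else sqrt(2 / (9 * cin[l]))
      list(W = matrix(rnorm(9 * cin[l] * cout[l], sd = sc),
                      9 * cin[l], cout[l]),
           b = numeric(cout[l]),
           bn_g = rep(1, cout[l]), bn_b = numeric(cout[l]))
    })
    structure(list(layers = layers, rho = 0, input_mode = input_mode,
                   seed = as.integer(seed)),
              class = "net_params")
  })
}

#' Count trainable parameters of the unit
#'
#' Convolution weights and biases, affine batch-normalization parameters,
#' and the fusion scalar gamma.
#'
#' @param params a `net_params`
#' @return integer parameter count
#' @export
count_params <- function(params) {
  as.integer(sum(vapply(params$layers, function(L) {
    length(L$W) + length(L$b) + length(L$bn_g) + length(L$bn_b)
  }, numeric(1))) + 1L)  # + gamma
}

#' @export
print.net_params <- function(x, ...) {
  cat(sprintf("Residual learning unit (%s input): %d trainable parameters, gamma = %.4g\n",
              x$input_mode, count_params(x), exp(x$rho)))
  invisible(x)
}

# Forward pass of the unit on stacked activations Xin (Cin x N); x_row is
# the PET channel (the residual path). Returns the regularized image row
# plus caches when requested.
unit_fwd <- function(params, Xin, x_row, n, batch, keep_cache = FALSE) {
  h <- Xin
  caches <- if (keep_cache) vector("list", 5) else NULL
  for (l in 1:5) {
    L <- params$layers[[l]]
    z <- conv_fwd(h, L$W, L$b, n, batch)
    bn <- bn_fwd(z, L$bn_g, L$bn_b)
    if (l < 5) {
      mask <- bn$Y > 0
      y <- bn$Y * mask
    } else {
      mask <- NULL
      y <- bn$Y
    }
    if (keep_cache) caches[[l]] <- list(A = h, xhat = bn$xhat,
                                        invstd = bn$invstd, mask = mask)
    h <- y
  }
  zres <- x_row + h[1, ]
  list(xreg = pmax(zres, 0), res_mask = zres > 0, caches = caches)
}

# Backward pass through the unit and the residual/clamp path; d_xreg is a
# vector over pixels. Returns per-layer gradients and the gradient wrt the
# input PET channel (residual identity path included).
unit_bwd <- function(params, caches, res_mask, d_xreg, n, batch) {
  dz <- d_xreg * res_mask
  grads <- vector("list", 5)
  dh <- matrix(dz, nrow = 1)
  for (l in 5:1) {
    L <- params$layers[[l]]
    cc <- caches[[l]]
    dy <- if (l < 5) dh * cc$mask else dh
    bn <- bn_bwd(dy, cc, L$bn_g)
    cv <- conv_bwd(bn$dA, cc$A, L$W, n, batch)
    grads[[l]] <- list(dW = cv$dW, db = cv$db, dg = bn$dg, dbeta = bn$db)
    dh <- cv$dA
  }
  list(grads = grads, d_input = dh, d_x = dz + dh[1, ])
}

#' Network regularization step
#'
#' Applies the residual learning unit to the current image (optionally with
#' a co-registered MR channel): `x_Reg = ReLU(x + unit(x [, mr]))`. This is
#' the learned replacement for the gradient regularization step of the
#' classical algorithm.
#'
#' @param params a `net_params`
#' @param x current image matrix
#' @param mr MR image matrix (required in `"petmr"` mode)
#' @return the regularized image matrix (non-negative)
#' @export
reg_step_net <- function(params, x, mr = NULL) {
  stopifnot(inherits(params, "net_params"))
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) != n) stop("square image expected", call. = FALSE)
  if (params$input_mode == "petmr") {
    if (is.null(mr)) stop("petmr mode requires an MR image", call. = FALSE)
    if (!all(dim(mr) == dim(x))) stop("MR grid mismatch", call. = FALSE)
  }
  Xin <- if (params$input_mode == "petmr") {
    rbind(as.vector(x), as.vector(mr))
  } else matrix(as.vector(x), nrow = 1)
  out <- unit_fwd(params, Xin, as.vector(x), n, 1L)
  matrix(out$xreg, n, n)
}

# ---- unrolled network ------------------------------------------------------

# Internal batched unrolled pass. Y, Rb: n_lor x B; mr: HW x B or NULL;
# att: n_lor x B or NULL; sens: list over subsets of HW x B matrices.
# Gradients are not propagated through the EM update: each state's EM image
# is computed from the previous state and treated as a constant, so
# backpropagation passes only through the regularization and fusion
# computations (including their dependence on the previous image).
unrolled_pass <- function(params, model, Y, Rb, mr, att, sens, n_it, n_sub,
                          keep_cache = FALSE, frozen_em = NULL) {
  n <- model$geometry$image_size_px
  hw <- n * n
  B <- ncol(Y)
  gamma <- exp(params$rho)
  mr_row <- if (is.null(mr)) NULL else as.vector(mr)
  x <- matrix(1, hw, B)
  n_states <- n_it * n_sub
  caches <- if (keep_cache) vector("list", n_states) else NULL
  for (t in seq_len(n_states)) {
    m <- ((t - 1L) %% n_sub) + 1L
    s <- sens[[m]]
    mask <- s > 0
    x_row <- as.vector(x)
    Xin <- if (is.null(mr_row)) matrix(x_row, nrow = 1) else rbind(x_row, mr_row)
    uf <- unit_fwd(params, Xin, x_row, n, B, keep_cache = keep_cache)
    x_reg <- matrix(uf$xreg, hw, B)
    x_em <- if (!is.null(frozen_em)) frozen_em[[t]] else {
      em_update_core(model, Y, Rb, x, m, att = att, sens = s)
    }
    delta <- matrix(0, hw, B)
    delta[mask] <- 1 / (gamma * s[mask])
    bq <- 1 - delta * x_reg
    Sq <- sqrt(bq^2 + 4 * delta * x_em)
    x_new <- fuse_images(x_em, x_reg, delta)
    x_new[!mask] <- 0
    if (any(!is.finite(x_new))) stop("non-finite image in unrolled state ", t, call. = FALSE)
    if (keep_cache) {
      caches[[t]] <- list(unit = uf$caches, res_mask = uf$res_mask,
                          x_reg = x_reg, x_em = x_em, delta = delta,
                          Sq = Sq, x_out = x_new, mask = mask)
    }
    x <- x_new
  }
  list(x = x, caches = caches)
}

unrolled_bwd <- function(params, caches, d_x, n, B) {
  hw <- n * n
  acc <- lapply(params$layers, function(L) {
    list(dW = matrix(0, nrow(L$W), ncol(L$W)), db = numeric(length(L$b)),
         dg = numeric(length(L$bn_g)), dbeta = numeric(length(L$bn_b)))
  })
  drho <- 0
  for (t in length(caches):1) {
    cc <- caches[[t]]
    dx <- d_x
    dx[!cc$mask] <- 0
    Sg <- pmax(cc$Sq, 1e-9)
    d_xreg <- dx * cc$delta * cc$x_out / Sg
    d_delta <- dx * cc$x_out * (cc$x_reg - cc$x_out) / Sg
    drho <- drho - sum(d_delta * cc$delta)
    ub <- unit_bwd(params, cc$unit, cc$res_mask, as.vector(d_xreg), n, B)
    for (l in 1:5) {
      acc[[l]]$dW <- acc[[l]]$dW + ub$grads[[l]]$dW
      acc[[l]]$db <- acc[[l]]$db + ub$grads[[l]]$db
      acc[[l]]$dg <- acc[[l]]$dg + ub$grads[[l]]$dg
      acc[[l]]$dbeta <- acc[[l]]$dbeta + ub$grads[[l]]$dbeta
    }
    d_x <- matrix(ub$d_x, hw, B)
  }
  list(grads = acc, drho = drho)
}

#' Unrolled network forward pass
#'
#' Runs the recurrent chain of `N_it x N_sub` reconstruction states from a
#' uniform initial image: learned regularization step, ordered-subset EM
#' update (non-trainable), closed-form fusion with the trainable gamma.
#'
#' @param params a `net_params`
#' @param model a `system_model` (provides the subset schedule and
#'   sensitivity images)
#' @param sino a `sinogram`
#' @param mr optional MR image matrix (required in `"petmr"` mode)
#' @param n_it number of outer iterations (states = `n_it` times the model's
#'   subset count)
#' @param mumap optional attenuation map overriding the model's attenuation
#' @return the reconstructed image matrix
#' @export
unrolled_forward <- function(params, model, sino, mr = NULL, n_it = 10L,
                             mumap = NULL) {
  stopifnot(inherits(params, "net_params"), inherits(model, "system_model"),
            inherits(sino, "sinogram"))
  n <- model$geometry$image_size_px
  if (params$input_mode == "petmr" && is.null(mr)) {
    stop("petmr mode requires an MR image", call. = FALSE)
  }
  att <- if (is.null(mumap)) NULL else
    matrix(attenuation_factors(model, mumap), ncol = 1)
  sens <- lapply(seq_len(model$n_subsets), function(m) {
    if (is.null(att)) matrix(model$sens[, m], ncol = 1) else
      sensitivity_for(model, att, m)
  })
  out <- unrolled_pass(params, model,
                       Y = matrix(sino$counts, ncol = 1),
                       Rb = matrix(sino$randoms, ncol = 1),
                       mr = if (is.null(mr)) NULL else matrix(as.vector(mr), ncol = 1),
                       att = att, sens = sens,
                       n_it = n_it, n_sub = model$n_subsets)
  matrix(out$x, n, n)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  st <- lapply(params$layers, function(L) {
    list(mW = matrix(0, nrow(L$W), ncol(L$W)),
         vW = matrix(0, nrow(L$W), ncol(L$W)),
         mb = numeric(length(L$b)), vb = numeric(length(L$b)),
         mg = numeric(length(L$bn_g)), vg = numeric(length(L$bn_g)),
         mbeta = numeric(length(L$bn_b)), vbeta = numeric(length(L$bn_b)))
  })
  list(layers = st, mrho = 0, vrho = 0, t = 0L)
}

adam_step <- function(params, grads, drho, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - b1^state$t
  corr2 <- 1 - b2^state$t
  upd <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    list(p = p - lr * (m / corr1) / (sqrt(v / corr2) + eps), m = m, v = v)
  }
  for (l in 1:5) {
    L <- params$layers[[l]]; S <- state$layers[[l]]; G <- grads[[l]]
    u <- upd(L$W, G$dW, S$mW, S$vW)
    L$W <- u$p; S$mW <- u$m; S$vW <- u$v
    u <- upd(L$b, G$db, S$mb, S$vb); L$b <- u$p; S$mb <- u$m; S$vb <- u$v
    u <- upd(L$bn_g, G$dg, S$mg, S$vg); L$bn_g <- u$p; S$mg <- u$m; S$vg <- u$v
    u <- upd(L$bn_b, G$dbeta, S$mbeta, S$vbeta); L$bn_b <- u$p; S$mbeta <- u$m; S$vbeta <- u$v
    params$layers[[l]] <- L; state$layers[[l]] <- S
  }
  u <- upd(params$rho, drho, state$mrho, state$vrho)
  params$rho <- u$p; state$mrho <- u$m; state$vrho <- u$v
  list(params = params, state = state)
}

# ---- training --------------------------------------------------------------

#' Fit the unrolled reconstruction network
#'
#' Trains the residual learning unit and the fusion weight gamma end-to-end
#' by minimizing the mean squared error between the unrolled network's
#' output and reference high-count images, using the Adam optimizer over
#' seeded minibatches. Gradients flow through the regularization and fusion
#' computations only; the EM updates are treated as fixed operations.
#'
#' All samples must share the model's geometry; per-sample attenuation is
#' supplied through each sample's `mumap` (or precomputed `att`).
#'
#' @param model a `system_model` built without attenuation (per-sample
#'   attenuation comes from the samples)
#' @param samples list of training samples; each a list with `counts`
#'   (sinogram vector), `randoms` (vector or scalar), `reference` (image
#'   matrix), and optionally `mr` (image matrix) and `mumap` or `att`
#' @param input_mode `"pet"` or `"petmr"`
#' @param n_iterations unrolled outer iterations (states = `n_iterations`
#'   times the model's subset count)
#' @param epochs training epochs
#' @param n_minibatches minibatches per epoch (batch size about
#'   `length(samples) / n_minibatches`)
#' @param lr Adam learning rate
#' @param seed integer seed controlling initialization and batching
#' @param verbose print per-epoch loss
#' @return an object of class `fbsem_net`: trained `params`, per-epoch
#'   `loss_history`, the fitted `gamma`, and the training configuration.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @export
fbsem_net <- function(model, samples, input_mode = c("pet", "petmr"),
                      n_iterations = 10L, epochs = 50L, n_minibatches = 10L,
                      lr = 0.05, seed = 1L, verbose = FALSE) {
  input_mode <- match.arg(input_mode)
  stopifnot(inherits(model, "system_model"))
  ns <- length(samples)
  if (ns < 1) stop("no training samples", call. = FALSE)
  n <- model$geometry$image_size_px
  hw <- n * n
  n_minibatches <- min(n_minibatches, ns)

  Y <- vapply(samples, function(s) as.numeric(s$counts), numeric(model$geometry$n_lor))
  Rb <- vapply(samples, function(s) {
    r <- s$randoms
    if (length(r) == 1) rep(r, model$geometry$n_lor) else as.numeric(r)
  }, numeric(model$geometry$n_lor))
  Ref <- vapply(samples, function(s) as.vector(as.matrix(s$reference)), numeric(hw))
  MR <- if (input_mode == "petmr") {
    vapply(samples, function(s) {
      if (is.null(s$mr)) stop("petmr mode requires MR images", call. = FALSE)
      as.vector(as.matrix(s$mr))
    }, numeric(hw))
  } else NULL
  Att <- vapply(samples, function(s) {
    if (!is.null(s$att)) as.numeric(s$att)
    else if (!is.null(s$mumap)) attenuation_factors(model, s$mumap)
    else rep(1, model$geometry$n_lor)
  }, numeric(model$geometry$n_lor))
  sens_all <- lapply(seq_len(model$n_subsets), function(m) {
    sensitivity_for(model, Att, m)
  })

  params <- build_unit(input_mode, seed = seed)
  opt <- adam_init(params)
  loss_history <- numeric(epochs)
  gamma_history <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(ns)
      groups <- split(perm, rep_len(seq_len(n_minibatches), ns))
      ep_loss <- 0
      for (grp in groups) {
        B <- length(grp)
        fw <- unrolled_pass(params, model,
                            Y = Y[, grp, drop = FALSE],
                            Rb = Rb[, grp, drop = FALSE],
                            mr = if (is.null(MR)) NULL else MR[, grp, drop = FALSE],
                            att = Att[, grp, drop = FALSE],
                            sens = lapply(sens_all, function(s) s[, grp, drop = FALSE]),
                            n_it = n_iterations, n_sub = model$n_subsets,
                            keep_cache = TRUE)
        resid <- fw$x - Ref[, grp, drop = FALSE]
        loss <- mean(resid^2)
        if (!is.finite(loss)) stop("training diverged: non-finite loss", call. = FALSE)
        d_x <- 2 * resid / length(resid)
        bw <- unrolled_bwd(params, fw$caches, d_x, n, B)
        st <- adam_step(params, bw$grads, bw$drho, opt, lr)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + loss * B
      }
      loss_history[ep] <- ep_loss / ns
      gamma_history[ep] <- exp(params$rho)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.6g  gamma %.4g", ep,
                        loss_history[ep], gamma_history[ep]))
      }
    }
  })

  structure(list(params = params, loss_history = loss_history,
                 gamma_history = gamma_history,
                 gamma = exp(params$rho),
                 input_mode = input_mode,
                 n_iterations = as.integer(n_iterations),
                 n_subsets = model$n_subsets,
                 n_params = count_params(params),
                 config = list(epochs = epochs, n_minibatches = n_minibatches,
                               lr = lr, seed = seed, n_samples = ns,
                               image_size_px = n),
                 geometry = model$geometry),
            class = "fbsem_net")
}

#' @export
print.fbsem_net <- function(x, ...) {
  cat(sprintf("Unrolled reconstruction network (%s input)\n", x$input_mode))
  cat(sprintf("  %d states (%d iterations x %d subsets), %d shared trainable parameters\n",
              x$n_iterations * x$n_subsets, x$n_iterations, x$n_subsets,
              x$n_params))
  cat(sprintf("  trained %d epochs on %d samples; final loss %.6g; gamma = %.4g\n",
              x$config$epochs, x$config$n_samples,
              tail(x$loss_history, 1), x$gamma))
  invisible(x)
}

#' @export
summary.fbsem_net <- function(object, ...) {
  print(object)
  counts <- vapply(object$params$layers, function(L) {
    length(L$W) + length(L$b) + length(L$bn_g) + length(L$bn_b)
  }, numeric(1))
  cat("  parameters per layer (conv + bias + BN):",
      paste(counts, collapse = ", "), "+ 1 (gamma)\n")
  cat(sprintf("  loss: initial %.6g -> final %.6g\n",
              object$loss_history[1], tail(object$loss_history, 1)))
  invisible(object)
}

#' @export
coef.fbsem_net <- function(object, ...) {
  c(gamma = object$gamma, log_gamma = object$params$rho)
}

#' @export
plot.fbsem_net <- function(x, ...) {
  plot(seq_along(x$loss_history), x$loss_history, type = "b",
       xlab = "epoch", ylab = "training MSE", main = "training loss", log = "y")
  invisible(x)
}

#' Reconstruct with a trained network
#'
#' @param object a fitted `fbsem_net`
#' @param model a `system_model` on the training geometry
#' @param sino a `sinogram`
#' @param mr MR image (required for `"petmr"` fits)
#' @param mumap optional attenuation map for this acquisition
#' @param ... unused
#' @return the reconstructed image matrix
#' @export
predict.fbsem_net <- function(object, model, sino, mr = NULL, mumap = NULL, ...) {
  unrolled_forward(object$params, model, sino, mr = mr,
                   n_it = object$n_iterations, mumap = mumap)
}
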