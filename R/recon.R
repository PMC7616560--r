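#' Emission sinogram container
#'
#' @param counts non-negative integer counts per LOR
#' @param randoms non-negative expected accidental-coincidence (randoms) rate
#'   per LOR; scalar or per-LOR vector
#' @param geometry the `scanner_geometry` the counts were simulated or
#'   measured under
#' @param seed seed used for sampling, if any
#' @return an object of class `sinogram`
#' @export
sinogram <- function(counts, randoms = 0, geometry, seed = NA_integer_) {
  stopifnot(inherits(geometry, "scanner_geometry"))
  counts <- as.numeric(counts)
  if (length(counts) != geometry$n_lor) stop("counts length must equal n_lor", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(randoms) == 1) randoms <- rep(as.numeric(randoms), geometry$n_lor)
  if (any(randoms < 0)) stop("randoms must be non-negative", call. = FALSE)
  structure(list(counts = counts, randoms = randoms, geometry = geometry,
                 total_prompts = sum(counts), seed = seed),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("Sinogram: %d angles x %d bins, %.4g prompts (%.3g expected randoms)\n",
              x$geometry$n_angles, x$geometry$n_radial_bins,
              x$total_prompts, sum(x$randoms)))
  invisible(x)
}

#' Convert a sinogram to a radial-bins by angles matrix
#' @param x a `sinogram`
#' @param what `"counts"` or `"randoms"`
#' @return a matrix with `n_radial_bins` rows and `n_angles` columns
#' @export
as.matrix.sinogram <- function(x, what = c("counts", "randoms"), ...) {
  what <- match.arg(what)
  matrix(x[[what]], x$geometry$n_radial_bins, x$geometry$n_angles)
}

#' MAP objective (log-posterior)
#'
#' The Poisson log-likelihood
#' `L(y | x) = sum_i y_i log([Hx]_i + rbar_i) - ([Hx]_i + rbar_i)` minus
#' `beta` times the prior penalty. Bins with `y_i = 0` contribute
#' `-([Hx]_i + rbar_i)`; a bin with `y_i > 0` and zero mean yields `-Inf`
#' (a legal return).
#'
#' @param model a `system_model`
#' @param sino a `sinogram`
#' @param x image estimate (non-negative matrix on the model grid)
#' @param prior a `prior_model` or `NULL`
#' @param beta regularization weight (multiplies the prior's pair-once
#'   penalty `P(x) = value(x) / 2`)
#' @return a scalar (possibly `-Inf`)
#' @export
log_posterior <- function(model, sino, x, prior = NULL, beta = 0) {
  ybar <- forward_project(model, x) + sino$randoms
  y <- sino$counts
  pos <- y > 0
  ll <- -sum(ybar[!pos])
  if (any(pos)) {
    if (any(ybar[pos] == 0)) return(-Inf)
    ll <- ll + sum(y[pos] * log(ybar[pos]) - ybar[pos])
  }
  if (!is.null(prior) && beta > 0) ll <- ll - beta * prior$penalty(x)
  ll
}

# One ordered-subset EM update (batched over columns when X, att, sens are
# matrices). Voxels with zero sensitivity are frozen at 0; EM denominators
# are guarded with a small epsilon.
em_update_core <- function(model, Y, R, X, m, att = NULL, sens = NULL,
                           eps = 1e-12) {
  rows <- model$subset_rows[[m]]
  ybar <- forward_project(model, X, subset = m, att_factors = att)
  ybar <- ybar + (if (is.matrix(Y)) R[rows, , drop = FALSE] else R[rows])
  ym <- if (is.matrix(Y)) Y[rows, , drop = FALSE] else Y[rows]
  ratio <- ym / pmax(ybar, eps)
  bp <- back_project(model, ratio, subset = m, att_factors = att)
  s <- if (is.null(sens)) model$sens[, m] else sens
  nvox <- model$geometry$image_size_px^2
  bp <- matrix(as.vector(as.matrix(bp)), nrow = nvox)
  Xm <- matrix(as.vector(X), nrow = nvox)
  sm <- matrix(as.vector(s), nrow = nvox)
  if (ncol(sm) == 1L && ncol(Xm) > 1L) sm <- sm[, rep(1L, ncol(Xm)), drop = FALSE]
  out <- bp * Xm / pmax(sm, eps)
  out[sm <= 0] <- 0
  out
}

#' Ordered-subset EM update
#'
#' One EM update of the current estimate using the data of subset `m`, with
#' expected randoms in the denominator:
#' `x_EM,j = (x_j / s_j^(m)) * sum_{i in subset m} h_ij y_i / ([Hx]_i + rbar_i)`.
#'
#' @inheritParams log_posterior
#' @param m subset index
#' @return the updated image matrix (non-negative)
#' @export
em_update <- function(model, sino, x, m) {
  stopifnot(inherits(model, "system_model"), inherits(sino, "sinogram"))
  n <- model$geometry$image_size_px
  matrix(em_update_core(model, sino$counts, sino$randoms, as.matrix(x), m),
         n, n)
}

#' Fusion of EM and regularization images
#'
#' The closed-form non-negative root of the per-voxel quadratic
#' `delta x^2 + (1 - delta x_Reg) x - x_EM = 0`, computed in the rationalized
#' form `2 x_EM / ((1 - delta x_Reg) + sqrt((1 - delta x_Reg)^2 + 4 delta
#' x_EM))` with a fallback to the `(-b + sqrt(...)) / (2 delta)` form when
#' the rationalized denominator underflows. `delta = 0` returns `x_EM`
#' exactly (the OSEM limit); the output is non-negative even when
#' `x_Reg < 0`.
#'
#' @param x_em EM-updated image (non-negative)
#' @param x_reg regularization image (may be negative)
#' @param delta per-voxel positive coupling weight `1 / (gamma s_j^(m))`
#'   (0 allowed, giving the OSEM limit)
#' @return the fused image, same shape as the inputs
#' @export
fuse_images <- function(x_em, x_reg, delta) {
  b <- 1 - delta * x_reg
  s <- sqrt(b^2 + 4 * delta * x_em)
  d <- b + s
  out <- 2 * x_em / d
  bad <- !(d > 1e-12)
  if (any(bad)) {
    dd <- pmax(delta, 1e-300)
    out[bad] <- ((s - b) / (2 * dd))[bad]
  }
  out[x_em == 0 & b >= 0] <- 0
  # one Newton polish of the quadratic (f' at the root equals s)
  resid <- delta * out^2 + b * out - x_em
  out <- pmax(out - resid / pmax(s, 1e-12), 0)
  out
}

#' Reconstruction configuration
#'
#' @param n_iterations number of outer iterations `N_it`
#' @param prior a `prior_model` or `NULL` (no prior: the algorithm reduces
#'   to OSEM)
#' @param beta regularization weight (>= 0)
#' @param gamma regularization step size / fusion weight; a positive scalar
#'   or `Inf` (OSEM limit). Ignored in De Pierro mode, which uses the
#'   per-voxel value `gamma_j = 1 / (2 beta sum_b w_jb)`.
#' @param mode `"generic"` (gradient regularization step) or `"depierro"`
#'   (closed-form neighbour-average regularization image; quadratic priors
#'   only)
#' @param record_objective record the MAP objective after every outer
#'   iteration
#' @param initial initial image (default uniform ones)
#' @return an object of class `recon_config`
#' @export
recon_config <- function(n_iterations = 10L, prior = NULL, beta = 1,
                         gamma = 1, mode = c("generic", "depierro"),
                         record_objective = FALSE, initial = NULL) {
  mode <- match.arg(mode)
  stopifnot_scalar(n_iterations, "n_iterations", positive = TRUE, integerish = TRUE)
  if (!is.null(prior)) stopifnot(inherits(prior, "prior_model"))
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (!identical(gamma, Inf)) stopifnot_scalar(gamma, "gamma", positive = TRUE)
  if (mode == "depierro" && !is.null(prior) && is.null(prior$reg_image)) {
    stop("De Pierro mode requires a quadratic prior", call. = FALSE)
  }
  structure(list(n_iterations = as.integer(n_iterations), prior = prior,
                 beta = beta, gamma = gamma, mode = mode,
                 record_objective = isTRUE(record_objective),
                 initial = initial),
            class = "recon_config")
}

#' MAP-EM reconstruction by forward-backward splitting
#'
#' Runs `N_it` outer iterations of `N_sub` ordered-subset states (the subset
#' count comes from the system model). Each state performs a regularization
#' step, an EM update of the previous image, and a closed-form fusion of the
#' two, weighted by `gamma` and the subset sensitivity image. With no prior
#' (or `gamma = Inf`) the algorithm is exactly OSEM; in De Pierro mode with
#' the quadratic prior it is De Pierro's MAPEM, which monotonically
#' increases the MAP objective when `N_sub = 1`.
#'
#' @inheritParams log_posterior
#' @param config a `recon_config`
#' @return an object of class `fbsem_recon`: the reconstructed `image`, the
#'   objective `trace` (if recorded), and the configuration
#' @examples
#' \donttest{
#' ph <- make_base_phantom(32, 2.08, seed = 1)
#' geom <- scanner_geometry(32)
#' model <- build_system(geom, ph$mumap, n_subsets = 6)
#' sc <- scale_to_counts(model, ph$activity, 1e5, randoms_fraction = 0.2)
#' sino <- sample_poisson(model, sc$x, sc$randoms, seed = 1)
#' fit <- fbsem_reconstruct(model, sino, recon_config(n_iterations = 10))
#' fit
#' }
#' @export
fbsem_reconstruct <- function(model, sino, config = recon_config()) {
  stopifnot(inherits(model, "system_model"), inherits(sino, "sinogram"),
            inherits(config, "recon_config"))
  n <- model$geometry$image_size_px
  x <- if (is.null(config$initial)) matrix(1, n, n) else as.matrix(config$initial)
  prior <- config$prior
  no_prior <- is.null(prior) || identical(config$gamma, Inf) || config$beta == 0
  trace <- if (config$record_objective) numeric(config$n_iterations) else NULL
  # per-voxel inverse step size used in De Pierro mode
  inv_gamma_px <- if (!no_prior && config$mode == "depierro") {
    2 * config$beta * prior$wsum
  } else NULL
  for (it in seq_len(config$n_iterations)) {
    for (m in seq_len(model$n_subsets)) {
      s <- matrix(model$sens[, m], n, n)
      if (no_prior) {
        x_reg <- x
        delta <- matrix(0, n, n)
      } else if (config$mode == "depierro") {
        x_reg <- prior$reg_image(x)
        delta <- inv_gamma_px / pmax(s, 1e-12)
      } else {
        x_reg <- x - config$gamma * config$beta * prior$gradient(x)
        delta <- 1 / (config$gamma * pmax(s, 1e-12))
      }
      x_em <- em_update(model, sino, x, m)
      x <- fuse_images(x_em, x_reg, delta)
      x[s <= 0] <- 0
      if (any(!is.finite(x))) {
        stop(sprintf("non-finite image at iteration %d, subset %d", it, m),
             call. = FALSE)
      }
    }
    if (config$record_objective) {
      trace[it] <- log_posterior(model, sino, x,
                                 prior = if (no_prior) NULL else prior,
                                 beta = config$beta)
    }
  }
  structure(list(image = x, trace = trace, config = config,
                 model = model, sino = sino,
                 method = if (no_prior) "OSEM" else
                   if (config$mode == "depierro") "MAPEM (De Pierro)" else "FBSEM"),
            class = "fbsem_recon")
}

#' Ordered-subsets EM (OSEM) reconstruction
#'
#' Plain OSEM: sequential subset EM updates from a uniform initial image.
#' Kept as an independent loop (no regularization or fusion machinery) so the
#' no-prior limit of [fbsem_reconstruct()] can be validated against it.
#'
#' @inheritParams log_posterior
#' @param n_iterations number of outer iterations
#' @param initial initial image (default uniform ones)
#' @return an object of class `fbsem_recon`
#' @export
osem_reconstruct <- function(model, sino, n_iterations = 10L, initial = NULL) {
  n <- model$geometry$image_size_px
  x <- if (is.null(initial)) matrix(1, n, n) else as.matrix(initial)
  for (it in seq_len(n_iterations)) {
    for (m in seq_len(model$n_subsets)) {
      x <- em_update(model, sino, x, m)
    }
  }
  structure(list(image = x, trace = NULL,
                 config = list(n_iterations = n_iterations),
                 model = model, sino = sino, method = "OSEM"),
            class = "fbsem_recon")
}

#' @export
print.fbsem_recon <- function(x, ...) {
  cat(sprintf("%s reconstruction: %dx%d image, %d iterations x %d subsets\n",
              x$method, nrow(x$image), ncol(x$image),
              x$config$n_iterations, x$model$n_subsets))
  if (!is.null(x$trace)) {
    cat(sprintf("  final MAP objective: %.6g\n", tail(x$trace, 1)))
  }
  invisible(x)
}

#' @export
plot.fbsem_recon <- function(x, ...) {
  if (!is.null(x$trace)) {
    op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(par(op))
  }
  image(t(x$image)[, nrow(x$image):1], col = gray.colors(128, 0, 1),
        axes = FALSE, main = x$method, useRaster = TRUE)
  if (!is.null(x$trace)) {
    plot(seq_along(x$trace), x$trace, type = "b", xlab = "iteration",
         ylab = "MAP objective", main = "objective trace")
  }
  invisible(x)
}

#' @export
residuals.fbsem_recon <- function(object, ...) {
  object$sino$counts - (forward_project(object$model, object$image) +
                          object$sino$randoms)
}

#' NRMSE-based selection of the regularization weight gamma
#'
#' Reconstructs every sample for every gamma in the grid and returns the
#' gamma minimizing the mean global NRMSE against the reference images —
#' the selection criterion used for the classical MAPEM baseline.
#'
#' @param model a `system_model`
#' @param samples a list; each element has `sino` (a `sinogram`), `reference`
#'   (image matrix) and `prior` (a `prior_model`, e.g. MR-guided)
#' @param gamma_grid non-empty vector of candidate gamma values
#' @param n_iterations,beta passed to the reconstruction
#' @return a list with `gamma` (the selected value), and `nrmse` (mean NRMSE
#'   per grid point)
#' @export
tune_gamma <- function(model, samples, gamma_grid, n_iterations = 10L,
                       beta = 1) {
  if (length(gamma_grid) == 0) stop("gamma_grid must be non-empty", call. = FALSE)
  scores <- vapply(gamma_grid, function(g) {
    errs <- vapply(samples, function(smp) {
      cfg <- recon_config(n_iterations = n_iterations, prior = smp$prior,
                          beta = beta, gamma = g)
      rec <- fbsem_reconstruct(model, smp$sino, cfg)
      nrmse(rec$image, smp$reference)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  list(gamma = gamma_grid[which.min(scores)],
       nrmse = setNames(scores, signif(gamma_grid, 4)))
}
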