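# Differentiable prior models for MAP reconstruction.
#
# The quadratic (Tikhonov) prior is written as the ordered double sum
#   R(x) = 1/2 * sum_j sum_{b in N_j} w_jb (x_j - x_b)^2,
# in which every unordered neighbour pair contributes twice. The penalty that
# enters the MAP objective is P(x) = R(x) / 2 (each pair counted once); its
# exact gradient is the conventional per-voxel form
#   (grad P)_j = sum_{b in N_j} w_jb (x_j - x_b)
# for symmetric weights, and it is this pairing that makes the De Pierro
# reduction (see depierro_reg_image) an exact identity.

# 8-connected 2D neighbourhood stencil: offsets (di, dj) and distances.
default_stencil <- function() {
  off <- expand.grid(di = -1:1, dj = -1:1)
  off <- off[!(off$di == 0 & off$dj == 0), ]
  off$dist <- sqrt(off$di^2 + off$dj^2)
  off
}

#' Uniform neighbourhood weights
#'
#' Weight lists are stored as one matrix per stencil offset: `W[[k]][j]` is
#' `w_{j, j+off_k}`, zero where the neighbour falls outside the grid.
#' Uniform weights are 1 for every in-grid neighbour pair.
#'
#' @param dim2 image dimensions (length-2 integer)
#' @param stencil neighbourhood offsets (default 8-connected)
#' @return a list of weight matrices, one per stencil offset
#' @export
uniform_weights <- function(dim2, stencil = default_stencil()) {
  n1 <- dim2[1]; n2 <- dim2[2]
  lapply(seq_len(nrow(stencil)), function(k) {
    di <- stencil$di[k]; dj <- stencil$dj[k]
    w <- matrix(1, n1, n2)
    # zero where neighbour (i+di, j+dj) is out of grid
    if (di == 1) w[n1, ] <- 0 else if (di == -1) w[1, ] <- 0
    if (dj == 1) w[, n2] <- 0 else if (dj == -1) w[, 1] <- 0
    w
  })
}

# Index of the opposite offset for each stencil row.
opposite_index <- function(stencil) {
  vapply(seq_len(nrow(stencil)), function(k) {
    which(stencil$di == -stencil$di[k] & stencil$dj == -stencil$dj[k])
  }, integer(1))
}

#' MR-informed Gaussian neighbourhood weights
#'
#' Anatomical guidance weights for the quadratic prior:
#' `w_jb = exp(-(m_j - m_b)^2 / (2 sigma_mr^2))` for each neighbour `b` of
#' voxel `j` in the stencil, symmetrized by averaging with the transposed
#' weight. A uniform MR image yields weights identically 1. With
#' `sigma_mr = "auto"`, sigma is set to the standard deviation of in-grid
#' neighbour intensity differences (over `mask` if given); if that is zero
#' (constant MR) the weights fall back to uniform.
#'
#' @param mr MR image matrix
#' @param sigma_mr positive bandwidth in MR intensity units, or `"auto"`
#' @param stencil neighbourhood offsets (default 8-connected)
#' @param mask optional logical matrix restricting the auto-sigma estimate
#' @return a list of weight matrices, one per stencil offset
#' @export
gaussian_mr_weights <- function(mr, sigma_mr = "auto",
                                stencil = default_stencil(), mask = NULL) {
  mr <- as.matrix(mr)
  nk <- nrow(stencil)
  diffs <- vector("list", nk)
  ingrid <- uniform_weights(dim(mr), stencil)
  for (k in seq_len(nk)) {
    nb <- shift_image(mr, -stencil$di[k], -stencil$dj[k])  # value at j + off_k
    diffs[[k]] <- (mr - nb) * ingrid[[k]]
  }
  if (identical(sigma_mr, "auto")) {
    sel <- if (is.null(mask)) TRUE else as.vector(mask)
    d_all <- unlist(lapply(seq_len(nk), function(k) {
      v <- as.vector(diffs[[k]]); g <- as.vector(ingrid[[k]]) > 0
      keep <- g & (if (is.null(mask)) TRUE else sel)
      v[keep]
    }))
    sigma_mr <- stats::sd(d_all)
    if (!is.finite(sigma_mr) || sigma_mr <= 0) return(ingrid)
  }
  stopifnot_scalar(sigma_mr, "sigma_mr", positive = TRUE)
  w <- lapply(seq_len(nk), function(k) {
    exp(-diffs[[k]]^2 / (2 * sigma_mr^2)) * ingrid[[k]]
  })
  symmetrize_weights(w, stencil)
}

# Average w_jb with w_bj (the opposite-offset weight shifted to j).
symmetrize_weights <- function(w, stencil = default_stencil()) {
  opp <- opposite_index(stencil)
  out <- w
  for (k in seq_along(w)) {
    w_bj_at_j <- shift_image(w[[opp[k]]], -stencil$di[k], -stencil$dj[k])
    out[[k]] <- (w[[k]] + w_bj_at_j) / 2
  }
  out
}

# Scale weights by inverse Euclidean inter-voxel distance (in pixel units).
distance_scale_weights <- function(w, stencil = default_stencil()) {
  lapply(seq_along(w), function(k) w[[k]] / stencil$dist[k])
}

#' Quadratic (Tikhonov) prior value
#'
#' Evaluates `R(x) = 1/2 * sum_j sum_{b in N_j} w_jb (x_j - x_b)^2` as
#' written, with each unordered pair contributing twice inside the double
#' sum. Boundary voxels use only in-grid neighbours.
#'
#' @param x image matrix
#' @param weights weight list as returned by [gaussian_mr_weights()] or
#'   [uniform_weights()]
#' @param stencil neighbourhood offsets matching `weights`
#' @return a scalar
#' @export
tikhonov_value <- function(x, weights, stencil = default_stencil()) {
  x <- as.matrix(x)
  total <- 0
  for (k in seq_along(weights)) {
    nb <- shift_image(x, -stencil$di[k], -stencil$dj[k])
    total <- total + sum(weights[[k]] * (x - nb)^2)
  }
  total / 2
}

#' Quadratic prior gradient (per-voxel derivative)
#'
#' Computes `(grad)_j = sum_{b in N_j} w_jb (x_j - x_b)`, the exact gradient
#' of the pair-once penalty `P(x) = tikhonov_value(x, w) / 2` for symmetric
#' weights. This is the derivative used in the regularization step of the
#' splitting algorithm.
#'
#' @inheritParams tikhonov_value
#' @return an image matrix
#' @export
tikhonov_gradient <- function(x, weights, stencil = default_stencil()) {
  x <- as.matrix(x)
  g <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(weights)) {
    nb <- shift_image(x, -stencil$di[k], -stencil$dj[k])
    g <- g + weights[[k]] * (x - nb)
  }
  g
}

#' De Pierro regularization image
#'
#' The closed-form regularization image of De Pierro's MAPEM for the
#' quadratic prior:
#' `x_Reg,j = (1 / (2 sum_b w_jb)) * sum_{b in N_j} w_jb (x_j + x_b)`.
#' It equals the generic gradient regularization step evaluated with
#' `beta = 1/2` and per-voxel `gamma_j = 1 / sum_b w_jb`. Voxels with zero
#' total weight (isolated) are returned unchanged.
#'
#' @inheritParams tikhonov_value
#' @return an image matrix
#' @export
depierro_reg_image <- function(x, weights, stencil = default_stencil()) {
  x <- as.matrix(x)
  num <- matrix(0, nrow(x), ncol(x))
  wsum <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(weights)) {
    nb <- shift_image(x, -stencil$di[k], -stencil$dj[k])
    num <- num + weights[[k]] * (x + nb)
    wsum <- wsum + weights[[k]]
  }
  out <- x
  ok <- wsum > 0
  out[ok] <- num[ok] / (2 * wsum[ok])
  out
}

#' Construct a quadratic prior model
#'
#' Bundles neighbourhood weights with the generic differentiable-prior
#' interface consumed by the reconstruction engine: `value(x)` (the double
#' sum), `penalty(x) = value(x)/2` (the term entering the MAP objective),
#' `gradient(x)` (exact gradient of the penalty), the De Pierro
#' regularization image, and the per-voxel weight sums.
#'
#' @param weights weight list; default uniform weights on `dim2`
#' @param dim2 image dimensions, required when `weights` is `NULL`
#' @param distance_weighting divide weights by inter-voxel distance (common
#'   practice for 8-connected stencils)
#' @param stencil neighbourhood offsets
#' @return an object of class `prior_model`
#' @export
tikhonov_prior <- function(weights = NULL, dim2 = NULL,
                           distance_weighting = TRUE,
                           stencil = default_stencil()) {
  if (is.null(weights)) {
    if (is.null(dim2)) stop("either weights or dim2 must be given", call. = FALSE)
    weights <- uniform_weights(dim2, stencil)
  }
  if (distance_weighting) weights <- distance_scale_weights(weights, stencil)
  wsum <- Reduce(`+`, weights)
  structure(list(
    type = "tikhonov",
    weights = weights, stencil = stencil, wsum = wsum,
    value = function(x) tikhonov_value(x, weights, stencil),
    penalty = function(x) tikhonov_value(x, weights, stencil) / 2,
    gradient = function(x) tikhonov_gradient(x, weights, stencil),
    reg_image = function(x) depierro_reg_image(x, weights, stencil)
  ), class = "prior_model")
}

#' @export
print.prior_model <- function(x, ...) {
  cat(sprintf("Quadratic prior (%s), %d-neighbour stencil, mean weight sum %.3g\n",
              x$type, nrow(x$stencil), mean(x$wsum)))
  invisible(x)
}
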