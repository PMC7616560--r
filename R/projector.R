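#' Parallel-beam scanner geometry
#'
#' A generic 2D parallel-beam geometry: `n_angles` projection angles uniformly
#' covering `[0, pi)` and `n_radial_bins` radial bins of width
#' `bin_spacing_mm`. One sinogram bin corresponds to one line of response
#' (LOR). Defaults follow `n_angles = 2 * image size`,
#' `n_radial_bins = 1.5 * image size`, `bin_spacing = pixel spacing`.
#'
#' @param image_size_px reconstructed image size in pixels (square)
#' @param image_spacing_mm pixel spacing in mm
#' @param n_angles number of projection angles
#' @param n_radial_bins number of radial bins per angle
#' @param bin_spacing_mm radial bin spacing in mm
#' @return an object of class `scanner_geometry`
#' @export
scanner_geometry <- function(image_size_px, image_spacing_mm = 2.08,
                             n_angles = 2L * image_size_px,
                             n_radial_bins = round(1.5 * image_size_px),
                             bin_spacing_mm = image_spacing_mm) {
  stopifnot_scalar(image_size_px, "image_size_px", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(n_angles, "n_angles", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(n_radial_bins, "n_radial_bins", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(bin_spacing_mm, "bin_spacing_mm", positive = TRUE)
  structure(list(
    image_size_px = as.integer(image_size_px),
    image_spacing_mm = image_spacing_mm,
    n_angles = as.integer(n_angles),
    n_radial_bins = as.integer(n_radial_bins),
    bin_spacing_mm = bin_spacing_mm,
    n_lor = as.integer(n_angles * n_radial_bins)
  ), class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf("Parallel-beam geometry: %d angles x %d radial bins (%.2f mm), image %dx%d at %.2f mm\n",
              x$n_angles, x$n_radial_bins, x$bin_spacing_mm,
              x$image_size_px, x$image_size_px, x$image_spacing_mm))
  invisible(x)
}

# Sparse projection matrix rows for one angle: ray sampling with bilinear
# interpolation weights, each sample weighted by the step length (mm), which
# approximates the line integral (Joseph-style interpolation coefficients).
angle_triplets <- function(geom, theta, step_mm) {
  n <- geom$image_size_px; sp <- geom$image_spacing_mm
  half_fov <- n * sp / 2
  offs <- (seq_len(geom$n_radial_bins) - (geom$n_radial_bins + 1) / 2) *
    geom$bin_spacing_mm
  tmax <- half_fov * sqrt(2)
  ts <- seq(-tmax, tmax, by = step_mm)
  # point = r * u + t * v, u = (cos, sin), v = (-sin, cos) in (row, col) mm
  ct <- cos(theta); st <- sin(theta)
  r_mm <- outer(offs * ct, ts * -st, `+`)   # n_radial x n_t
  c_mm <- outer(offs * st, ts *  ct, `+`)
  bin <- matrix(seq_len(geom$n_radial_bins), geom$n_radial_bins, length(ts))
  # continuous pixel coordinates (0-based, pixel centres at i + 0.5)
  rp <- (as.vector(r_mm) + half_fov) / sp
  cp <- (as.vector(c_mm) + half_fov) / sp
  bin <- as.vector(bin)
  r0 <- floor(rp - 0.5); c0 <- floor(cp - 0.5)
  fr <- (rp - 0.5) - r0; fc <- (cp - 0.5) - c0
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (q in 1:4) {
    ri <- r0 + (q == 2 | q == 4)
    ci <- c0 + (q == 3 | q == 4)
    w <- switch(q,
                (1 - fr) * (1 - fc),
                fr * (1 - fc),
                (1 - fr) * fc,
                fr * fc) * step_mm
    ok <- ri >= 0 & ri <= (n - 1) & ci >= 0 & ci <= (n - 1) & w > 0
    ii <- c(ii, bin[ok])
    jj <- c(jj, ri[ok] + 1L + ci[ok] * n)  # column-major voxel index
    xx <- c(xx, w[ok])
  }
  list(i = ii, j = jj, x = xx)
}

#' Build the PET system model
#'
#' Computes interpolation-weight intersection coefficients `h_ij` for every
#' LOR as a sparse matrix, folds in attenuation factors
#' `exp(-line integral of mu)` when a mu-map is given, partitions the angles
#' into interleaved ordered subsets, and precomputes the per-subset
#' sensitivity images `s_j^(m) = sum_{i in subset m} h_ij`.
#'
#' @param geometry a `scanner_geometry`
#' @param mumap linear attenuation map in mm^-1 on the image grid, or `NULL`
#'   for no attenuation (all factors 1)
#' @param n_subsets number of ordered subsets (interleaved angles); must not
#'   exceed the number of angles
#' @param step_factor ray sampling step as a fraction of the pixel spacing
#' @return an object of class `system_model` with per-subset sparse matrices
#'   `Hs`, LOR attenuation factors `att`, subset row indices `subset_rows`,
#'   subset angle indices, and the sensitivity image matrix `sens`
#'   (voxels x subsets)
#' @export
build_system <- function(geometry, mumap = NULL, n_subsets = 6L,
                         step_factor = 0.5) {
  stopifnot(inherits(geometry, "scanner_geometry"))
  stopifnot_scalar(n_subsets, "n_subsets", positive = TRUE, integerish = TRUE)
  if (n_subsets > geometry$n_angles) {
    stop("n_subsets must not exceed the number of angles", call. = FALSE)
  }
  n <- geometry$image_size_px
  if (!is.null(mumap)) {
    mumap <- as.matrix(mumap)
    if (!all(dim(mumap) == c(n, n))) stop("mumap grid does not match geometry", call. = FALSE)
    if (any(mumap < 0)) stop("mumap must be non-negative", call. = FALSE)
  }
  step_mm <- step_factor * geometry$image_spacing_mm
  thetas <- (seq_len(geometry$n_angles) - 1L) * pi / geometry$n_angles
  nrad <- geometry$n_radial_bins

  subsets <- lapply(seq_len(n_subsets), function(m) {
    as.integer(seq.int(m, geometry$n_angles, by = n_subsets))
  })
  Hs <- vector("list", n_subsets)
  att <- rep(1, geometry$n_lor)
  subset_rows <- vector("list", n_subsets)
  sens <- matrix(0, n * n, n_subsets)
  mu_vec <- if (is.null(mumap)) NULL else as.vector(mumap)
  for (m in seq_len(n_subsets)) {
    angs <- subsets[[m]]
    tri_i <- vector("list", length(angs))
    tri_j <- vector("list", length(angs))
    tri_x <- vector("list", length(angs))
    for (k in seq_along(angs)) {
      tr <- angle_triplets(geometry, thetas[angs[k]], step_mm)
      tri_i[[k]] <- tr$i + (k - 1L) * nrad   # row within this subset block
      tri_j[[k]] <- tr$j
      tri_x[[k]] <- tr$x
    }
    H <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                              x = unlist(tri_x),
                              dims = c(length(angs) * nrad, n * n))
    rows <- as.integer(outer(seq_len(nrad), (angs - 1L) * nrad, `+`))
    subset_rows[[m]] <- rows
    if (!is.null(mu_vec)) {
      att[rows] <- exp(-as.vector(H %*% mu_vec))
    }
    sens[, m] <- as.vector(Matrix::crossprod(H, att[rows]))
    Hs[[m]] <- H
  }
  structure(list(
    geometry = geometry, Hs = Hs, att = att,
    subsets = subsets, subset_rows = subset_rows,
    sens = sens, n_subsets = as.integer(n_subsets),
    has_attenuation = !is.null(mumap)
  ), class = "system_model")
}

#' @export
print.system_model <- function(x, ...) {
  nnz <- sum(vapply(x$Hs, function(h) length(h@x), numeric(1)))
  cat(sprintf("PET system model: %d LORs, %d subsets, %s attenuation, %.1fM nonzeros\n",
              x$geometry$n_lor, x$n_subsets,
              if (x$has_attenuation) "with" else "no", nnz / 1e6))
  invisible(x)
}

as_image_vector <- function(model, x) {
  n <- model$geometry$image_size_px
  if (is.matrix(x) && all(dim(x) == c(n, n))) return(as.vector(x))
  x <- as.matrix(x)
  if (nrow(x) != n * n) stop("image does not match the model grid", call. = FALSE)
  x   # voxels x batch
}

#' Forward projection
#'
#' Applies the attenuated system matrix: `[H x]_i` for every LOR `i` in the
#' chosen subset (or all LORs). Accepts an image matrix or a voxels-by-batch
#' matrix of vectorized images.
#'
#' @param model a `system_model`
#' @param x image (matrix on the model grid) or voxels-by-batch matrix
#' @param subset subset index in `1..n_subsets`, or `"all"`
#' @param att_factors optional per-LOR attenuation factors overriding the
#'   model's (used for batches of phantoms sharing one geometry); a vector or
#'   an LORs-by-batch matrix
#' @return projection values: a vector for a single image, or a matrix with
#'   one column per batch element
#' @export
forward_project <- function(model, x, subset = "all", att_factors = NULL) {
  stopifnot(inherits(model, "system_model"))
  xv <- as_image_vector(model, x)
  single <- is.null(dim(xv))
  if (single) xv <- matrix(xv, ncol = 1)
  proj_sub <- function(m) {
    p <- as.matrix(model$Hs[[m]] %*% xv)
    a <- if (is.null(att_factors)) model$att[model$subset_rows[[m]]] else att_factors
    if (is.matrix(a) && !is.null(att_factors)) {
      p * a[model$subset_rows[[m]], , drop = FALSE]
    } else if (!is.null(att_factors)) {
      p * a[model$subset_rows[[m]]]
    } else {
      p * a
    }
  }
  if (identical(subset, "all")) {
    out <- matrix(0, model$geometry$n_lor, ncol(xv))
    for (m in seq_len(model$n_subsets)) {
      out[model$subset_rows[[m]], ] <- proj_sub(m)
    }
  } else {
    m <- as.integer(subset)
    if (m < 1 || m > model$n_subsets) stop("invalid subset index", call. = FALSE)
    out <- proj_sub(m)
  }
  if (single) as.vector(out) else out
}

#' Back projection
#'
#' Applies the adjoint of [forward_project()]: `H^T q` restricted to the
#' chosen subset.
#'
#' @inheritParams forward_project
#' @param q projection values over the chosen subset (in LOR order for
#'   `"all"`, in subset-row order for a single subset); vector or matrix with
#'   one column per batch element
#' @return the backprojected image as a matrix on the model grid (single
#'   input) or a voxels-by-batch matrix
#' @export
back_project <- function(model, q, subset = "all", att_factors = NULL) {
  stopifnot(inherits(model, "system_model"))
  n <- model$geometry$image_size_px
  q <- as.matrix(q)
  if (any(!is.finite(q))) stop("projection values must be finite", call. = FALSE)
  single <- ncol(q) == 1L
  get_att <- function(m) {
    a <- if (is.null(att_factors)) model$att else att_factors
    if (is.matrix(a)) a[model$subset_rows[[m]], , drop = FALSE] else a[model$subset_rows[[m]]]
  }
  if (identical(subset, "all")) {
    if (nrow(q) != model$geometry$n_lor) stop("projection length mismatch", call. = FALSE)
    out <- matrix(0, n * n, ncol(q))
    for (m in seq_len(model$n_subsets)) {
      qa <- q[model$subset_rows[[m]], , drop = FALSE] * get_att(m)
      out <- out + as.matrix(Matrix::crossprod(model$Hs[[m]], qa))
    }
  } else {
    m <- as.integer(subset)
    if (m < 1 || m > model$n_subsets) stop("invalid subset index", call. = FALSE)
    if (nrow(q) != length(model$subset_rows[[m]])) stop("projection length mismatch", call. = FALSE)
    out <- as.matrix(Matrix::crossprod(model$Hs[[m]], q * get_att(m)))
  }
  if (single) matrix(out, n, n) else out
}

# Per-subset sensitivity images for given attenuation factors (voxels x
# batch); used when several phantoms share the geometry but differ in mu-map.
sensitivity_for <- function(model, att_factors, subset) {
  m <- as.integer(subset)
  a <- att_factors[model$subset_rows[[m]], , drop = FALSE]
  as.matrix(Matrix::crossprod(model$Hs[[m]], a))
}

#' Attenuation factors for a mu-map under a model's geometry
#'
#' Per-LOR multiplicative factors `exp(-line integral of mu)` in `(0, 1]`,
#' computed with the model's projector. Useful when many phantoms share one
#' geometry and the attenuation is supplied per sample.
#'
#' @param model a `system_model`
#' @param mumap linear attenuation map in mm^-1 on the model grid
#' @return a numeric vector of length `n_lor`
#' @export
attenuation_factors <- function(model, mumap) {
  mu <- as.vector(as.matrix(mumap))
  if (any(mu < 0)) stop("mumap must be non-negative", call. = FALSE)
  att <- numeric(model$geometry$n_lor)
  for (m in seq_len(model$n_subsets)) {
    att[model$subset_rows[[m]]] <- exp(-as.vector(model$Hs[[m]] %*% mu))
  }
  att
}

#' Replace a system model's attenuation
#'
#' Returns a copy of the model with attenuation factors (and subset
#' sensitivity images) recomputed for a new mu-map, reusing the geometry and
#' sparse projection weights. Much cheaper than rebuilding the system when
#' many phantoms share one scanner geometry.
#'
#' @param model a `system_model`
#' @param mumap linear attenuation map in mm^-1, or `NULL` to remove
#'   attenuation
#' @return a `system_model`
#' @export
set_attenuation <- function(model, mumap) {
  att <- if (is.null(mumap)) rep(1, model$geometry$n_lor) else
    attenuation_factors(model, mumap)
  model$att <- att
  for (m in seq_len(model$n_subsets)) {
    model$sens[, m] <- as.vector(
      Matrix::crossprod(model$Hs[[m]], att[model$subset_rows[[m]]]))
  }
  model$has_attenuation <- !is.null(mumap)
  model
}
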