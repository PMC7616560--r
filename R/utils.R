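# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so every exported operation is a pure
# function of its arguments.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_scalar <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

# Pixel-centre coordinates in mm relative to the grid centre. Row-major grids,
# 0-based pixel (i, j) has centre at (i + 0.5) * spacing; we shift the origin
# to the grid centre for all geometric constructions.
pixel_centres <- function(n, spacing) {
  (seq_len(n) - 0.5) * spacing - n * spacing / 2
}

# Bilinear sampling of matrix `img` at continuous positions (r, c) expressed in
# pixel units on the 0-based centre convention (position p samples pixel
# floor(p - 0.5) + 1 ...). Out-of-grid positions return `fill`.
bilinear_sample <- function(img, r, c, fill = 0) {
  n1 <- nrow(img); n2 <- ncol(img)
  r0 <- floor(r - 0.5); c0 <- floor(c - 0.5)
  fr <- (r - 0.5) - r0; fc <- (c - 0.5) - c0
  val <- numeric(length(r))
  get_px <- function(ri, ci) {
    ok <- ri >= 0 & ri <= (n1 - 1) & ci >= 0 & ci <= (n2 - 1)
    v <- rep(fill, length(ri))
    v[ok] <- img[cbind(ri[ok] + 1L, ci[ok] + 1L)]
    v
  }
  val <- get_px(r0,      c0)      * (1 - fr) * (1 - fc) +
         get_px(r0 + 1,  c0)      * fr       * (1 - fc) +
         get_px(r0,      c0 + 1)  * (1 - fr) * fc +
         get_px(r0 + 1,  c0 + 1)  * fr       * fc
  val
}

# Rotate a matrix about its centre by `deg` degrees (counter-clockwise in the
# (row, col) plane), bilinear or nearest-neighbour interpolation, zero fill.
rotate_image <- function(img, deg, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (deg == 0 && method == "nearest") return(img)
  n1 <- nrow(img); n2 <- ncol(img)
  th <- deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # target pixel centres relative to image centre
  rc <- expand.grid(r = seq_len(n1) - 0.5 - n1 / 2, c = seq_len(n2) - 0.5 - n2 / 2)
  # inverse rotation to source coordinates
  rs <- ct * rc$r + st * rc$c + n1 / 2
  cs <- -st * rc$r + ct * rc$c + n2 / 2
  if (method == "bilinear") {
    out <- bilinear_sample(img, rs, cs)
  } else {
    ri <- round(rs - 0.5); ci <- round(cs - 0.5)
    ok <- ri >= 0 & ri <= (n1 - 1) & ci >= 0 & ci <= (n2 - 1)
    out <- numeric(nrow(rc))
    out[ok] <- img[cbind(ri[ok] + 1L, ci[ok] + 1L)]
  }
  matrix(out, n1, n2)
}

# Shift a matrix by (di, dj) pixels with zero fill.
shift_image <- function(img, di, dj) {
  n1 <- nrow(img); n2 <- ncol(img)
  out <- matrix(0, n1, n2)
  if (abs(di) >= n1 || abs(dj) >= n2) return(out)
  r_dst <- max(1, 1 + di):min(n1, n1 + di)
  c_dst <- max(1, 1 + dj):min(n2, n2 + dj)
  out[r_dst, c_dst] <- img[r_dst - di, c_dst - dj]
  out
}

# Binary erosion with a 3x3 structuring element (shift intersection).
erode_mask <- function(mask) {
  m <- mask * 1
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    out <- out * shift_image(m, di, dj)
  }
  out > 0
}

# Disk mask centred at (r_mm, c_mm) relative to grid centre.
disk_mask <- function(n, spacing, r_mm, c_mm, radius_mm) {
  cc <- pixel_centres(n, spacing)
  outer(cc - r_mm, cc - c_mm, function(a, b) a^2 + b^2) <= radius_mm^2
}

# Smooth a matrix with a small separable Gaussian (sigma in pixels).
gaussian_smooth_px <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  sep_convolve(img, k)
}

# Separable "same" convolution with 1D kernel k applied along rows then cols,
# zero padding at the border.
sep_convolve <- function(img, k) {
  half <- (length(k) - 1L) / 2L
  conv1 <- function(m) {
    # convolve each column of m with k (zero padded)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(k)) {
      d <- o - 1L - half
      src <- seq_len(n) - d
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[o] * m[src[ok], , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(img))))
}
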