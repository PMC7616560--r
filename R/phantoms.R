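#' Synthetic 2D brain phantom samples
#'
#' Procedurally generated brain-like slices standing in for segmented brain
#' atlas data: a deformed elliptical brain with a grey-matter ribbon over a
#' white-matter core and small ventricles, a co-registered T1-like MR image
#' with independent tissue contrast, and a piecewise-constant attenuation
#' (mu) map with a skull ring. All channels share one grid and pixel spacing.
#'
#' Default activity contrasts are grey:white:background = 4:1:0, with hot
#' lesions scaling activity by 2 and cold lesions by 0.25.
#'
#' @param size_px image size in pixels (square grid), at least 32
#' @param spacing_mm pixel spacing in mm (default 2.08)
#' @param seed integer seed; the sample is a pure function of the arguments
#' @return an object of class `phantom` with elements `activity`, `mr`,
#'   `mumap` (matrices), `tissue` (integer matrix: 0 background, 1 white
#'   matter, 2 grey matter), `lesions` (data frame), `lesion_masks` (list of
#'   logical matrices), `rotation_deg`, `spacing_mm`, `size_px`, `seed`
#' @examples
#' ph <- make_base_phantom(64, 2.08, seed = 1)
#' range(ph$activity)
#' @export
make_base_phantom <- function(size_px, spacing_mm = 2.08, seed = 1L) {
  stopifnot_scalar(size_px, "size_px", positive = TRUE, integerish = TRUE)
  stopifnot_scalar(spacing_mm, "spacing_mm", positive = TRUE)
  if (size_px < 32) stop("size_px must be at least 32", call. = FALSE)
  n <- as.integer(size_px)
  fov <- n * spacing_mm

  with_seed(seed, {
    a <- fov * runif(1, 0.31, 0.35)   # brain semi-axis, rows (mm)
    b <- fov * runif(1, 0.37, 0.41)   # brain semi-axis, cols (mm)
    amp  <- runif(4, -0.035, 0.035)   # boundary harmonics, brain
    ph   <- runif(4, 0, 2 * pi)
    amp2 <- runif(4, -0.06, 0.06)     # boundary harmonics, white matter
    ph2  <- runif(4, 0, 2 * pi)
    wscale <- runif(1, 0.58, 0.68)
    vent_r <- b * runif(1, 0.10, 0.14)  # ventricle size (mm)

    cc <- pixel_centres(n, spacing_mm)
    R <- matrix(cc, n, n)            # row coordinate (mm)
    C <- matrix(cc, n, n, byrow = TRUE)
    th <- atan2(C, R)
    harm <- function(am, phs) {
      out <- 0
      for (k in seq_along(am)) out <- out + am[k] * cos((k + 1) * th + phs[k])
      out
    }
    rho <- sqrt((R / a)^2 + (C / b)^2)
    brain <- rho <= (1 + harm(amp, ph))
    white <- rho <= wscale * (1 + harm(amp2, ph2))
    # two ventricles: small ellipses offset laterally from the centre
    vent <- ((R / (1.6 * vent_r))^2 + ((C - 0.55 * vent_r * 2) / vent_r)^2 <= 1) |
            ((R / (1.6 * vent_r))^2 + ((C + 0.55 * vent_r * 2) / vent_r)^2 <= 1)
    vent <- vent & white
    grey <- brain & !white
    white_only <- white & !vent

    head_rho <- sqrt((R / (1.14 * a))^2 + (C / (1.14 * b))^2)
    head <- head_rho <= 1
    skull <- head & head_rho > 0.93 & !brain

    tissue <- matrix(0L, n, n)
    tissue[white_only] <- 1L
    tissue[grey] <- 2L

    activity <- matrix(0, n, n)
    activity[white_only] <- 1
    activity[grey] <- 4
    activity[vent] <- 0.2
    activity <- pmax(gaussian_smooth_px(activity, 0.6), 0)

    mr <- matrix(0, n, n)
    mr[head & !brain] <- 1.2       # scalp / extra-cerebral soft tissue
    mr[skull] <- 0.3               # bone is dark on T1
    mr[grey] <- 1.5
    mr[white_only] <- 3
    mr[vent] <- 0.4
    mr <- pmax(gaussian_smooth_px(mr, 0.6), 0)

    mumap <- matrix(0, n, n)
    mumap[head] <- 0.0096          # soft tissue, mm^-1
    mumap[skull] <- 0.0143         # bone, mm^-1

    structure(list(
      activity = activity, mr = mr, mumap = mumap,
      tissue = tissue,
      lesions = empty_lesion_table(),
      lesion_masks = list(),
      rotation_deg = 0,
      spacing_mm = spacing_mm, size_px = n, seed = as.integer(seed)
    ), class = "phantom")
  })
}

empty_lesion_table <- function() {
  data.frame(id = integer(0), r_mm = numeric(0), c_mm = numeric(0),
             radius_mm = numeric(0), polarity = character(0),
             contrast = numeric(0), modality = character(0),
             stringsAsFactors = FALSE)
}

#' Add circular hot and cold lesions to a phantom
#'
#' Disks of uniform-random radius are placed at uniform-random locations
#' fully inside the brain mask by rejection sampling; each lesion is hot
#' (activity scaled up) or cold (scaled down) with equal probability. A
#' fraction of lesions can be made modality-mismatched: present in only the
#' PET activity or only the MR image, emulating functional lesions without
#' anatomical correlates (and vice versa). Lesions scale the underlying
#' activity/MR values multiplicatively over their mask.
#'
#' @param sample a `phantom`
#' @param n_lesions number of lesions (10 in the standard protocol)
#' @param radius_range_mm length-2 numeric, lesion radius range in mm
#' @param mismatch_fraction fraction in `[0, 1]` of lesions placed in only one
#'   modality (PET-only or MR-only with equal probability)
#' @param hot_contrast,cold_contrast multiplicative contrast of hot/cold lesions
#' @param seed integer seed
#' @return the modified `phantom`, with lesion bookkeeping in `$lesions` and
#'   `$lesion_masks`
#' @export
add_lesions <- function(sample, n_lesions = 10L, radius_range_mm = c(2, 10),
                        mismatch_fraction = 0, hot_contrast = 2,
                        cold_contrast = 0.25, seed = 1L) {
  stopifnot(inherits(sample, "phantom"))
  stopifnot_scalar(n_lesions, "n_lesions", integerish = TRUE)
  if (n_lesions == 0) return(sample)
  n <- sample$size_px; sp <- sample$spacing_mm
  if (length(radius_range_mm) != 2 || any(radius_range_mm <= 0) ||
      radius_range_mm[2] >= n * sp / 2) {
    stop("radius_range_mm must lie within (0, image half-width)", call. = FALSE)
  }
  brain <- sample$tissue > 0L
  cc <- pixel_centres(n, sp)

  with_seed(seed, {
    n_mis <- round(mismatch_fraction * n_lesions)
    mis_idx <- if (n_mis > 0) sort(sample.int(n_lesions, n_mis)) else integer(0)
    occupied <- matrix(FALSE, n, n)
    tab <- empty_lesion_table()
    masks <- list()
    half <- n * sp / 2
    for (k in seq_len(n_lesions)) {
      radius <- runif(1, radius_range_mm[1], radius_range_mm[2])
      placed <- FALSE
      for (attempt in 1:500) {
        r0 <- runif(1, -half, half); c0 <- runif(1, -half, half)
        m <- disk_mask(n, sp, r0, c0, radius)
        if (!any(m)) next
        if (all(brain[m]) && !any(occupied[m])) { placed <- TRUE; break }
      }
      if (!placed) {
        stop(sprintf("could not place lesion %d (radius %.1f mm) inside the brain mask",
                     k, radius), call. = FALSE)
      }
      polarity <- if (runif(1) < 0.5) "hot" else "cold"
      contrast <- if (polarity == "hot") hot_contrast else cold_contrast
      modality <- if (k %in% mis_idx) {
        if (runif(1) < 0.5) "pet_only" else "mr_only"
      } else "shared"
      if (modality != "mr_only") sample$activity[m] <- sample$activity[m] * contrast
      if (modality != "pet_only") sample$mr[m] <- sample$mr[m] * contrast
      occupied <- occupied | m
      tab <- rbind(tab, data.frame(id = k, r_mm = r0, c_mm = c0,
                                   radius_mm = radius, polarity = polarity,
                                   contrast = contrast, modality = modality,
                                   stringsAsFactors = FALSE))
      masks[[k]] <- m
    }
    sample$lesions <- tab
    sample$lesion_masks <- masks
    sample
  })
}

#' Rotation augmentation of a phantom
#'
#' Returns `n_rotations` copies of the sample, each rotated by one
#' uniform-random angle in `[-max_abs_deg, +max_abs_deg]` applied identically
#' to every channel. Continuous channels (activity, MR, mu-map) use bilinear
#' interpolation with zero fill and are clipped at zero; label and lesion
#' masks use nearest-neighbour interpolation.
#'
#' @param sample a `phantom`
#' @param n_rotations number of augmented copies (>= 1)
#' @param max_abs_deg maximum absolute rotation angle in degrees
#' @param seed integer seed
#' @return a list of `phantom` objects
#' @export
augment_rotations <- function(sample, n_rotations = 5L, max_abs_deg = 5,
                              seed = 1L) {
  stopifnot(inherits(sample, "phantom"))
  stopifnot_scalar(n_rotations, "n_rotations", positive = TRUE, integerish = TRUE)
  with_seed(seed, {
    angles <- runif(n_rotations, -max_abs_deg, max_abs_deg)
    lapply(angles, function(deg) rotate_phantom(sample, deg))
  })
}

# Rotate every channel of a phantom by `deg` degrees about the grid centre.
rotate_phantom <- function(sample, deg) {
  out <- sample
  out$activity <- pmax(rotate_image(sample$activity, deg, "bilinear"), 0)
  out$mr <- pmax(rotate_image(sample$mr, deg, "bilinear"), 0)
  out$mumap <- pmax(rotate_image(sample$mumap, deg, "bilinear"), 0)
  out$tissue <- matrix(as.integer(rotate_image(sample$tissue + 0, deg, "nearest")),
                       sample$size_px, sample$size_px)
  out$lesion_masks <- lapply(sample$lesion_masks, function(m) {
    rotate_image(m + 0, deg, "nearest") > 0.5
  })
  if (nrow(sample$lesions)) {
    th <- deg * pi / 180
    r <- sample$lesions$r_mm; c <- sample$lesions$c_mm
    out$lesions$r_mm <- cos(th) * r - sin(th) * c
    out$lesions$c_mm <- sin(th) * r + cos(th) * c
  }
  out$rotation_deg <- sample$rotation_deg + deg
  out
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Synthetic brain phantom: %dx%d px at %.2f mm (seed %d)\n",
              x$size_px, x$size_px, x$spacing_mm, x$seed))
  cat(sprintf("  activity range [%.3g, %.3g]; %d lesion(s); rotation %.2f deg\n",
              min(x$activity), max(x$activity), nrow(x$lesions), x$rotation_deg))
  invisible(x)
}

#' @export
plot.phantom <- function(x, ...) {
  op <- par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(par(op))
  show <- function(m, main) {
    image(t(m)[, nrow(m):1], col = gray.colors(128, 0, 1), axes = FALSE,
          main = main, useRaster = TRUE)
  }
  show(x$activity, "activity")
  show(x$mr, "MR")
  show(x$mumap, "mu-map")
  invisible(x)
}
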