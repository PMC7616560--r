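#' Normalized root mean squared error
#'
#' `NRMSE = sqrt(sum_roi (x - ref)^2) / sqrt(sum_roi ref^2)`; the
#' normalization is the reference's root sum of squares over the region of
#' interest, making the measure invariant to joint rescaling of image and
#' reference.
#'
#' @param x image matrix
#' @param ref reference image matrix (not identically zero on the ROI)
#' @param roi logical matrix restricting the error, or `NULL` for the whole
#'   grid
#' @return a non-negative scalar
#' @export
nrmse <- function(x, ref, roi = NULL) {
  x <- as.matrix(x); ref <- as.matrix(ref)
  if (!all(dim(x) == dim(ref))) stop("image and reference shapes differ", call. = FALSE)
  if (is.null(roi)) {
    d <- x - ref; r <- ref
  } else {
    roi <- as.logical(roi)
    if (!any(roi)) stop("empty ROI", call. = FALSE)
    d <- (x - ref)[roi]; r <- ref[roi]
  }
  denom <- sqrt(sum(r^2))
  if (denom == 0) stop("reference is identically zero on the ROI", call. = FALSE)
  sqrt(sum(d^2)) / denom
}

#' Gaussian post-reconstruction filter
#'
#' Isotropic Gaussian smoothing with the kernel width given as full width at
#' half maximum in mm: `sigma_px = fwhm / (2 sqrt(2 log 2)) / spacing`. The
#' kernel is normalized, so total activity is preserved up to boundary
#' truncation. `fwhm = 0` is the identity.
#'
#' @param x image matrix
#' @param fwhm_mm filter FWHM in mm (e.g. 4)
#' @param spacing_mm pixel spacing in mm
#' @return the filtered image
#' @export
gaussian_post_filter <- function(x, fwhm_mm, spacing_mm = 2.08) {
  if (fwhm_mm < 0) stop("fwhm_mm must be >= 0", call. = FALSE)
  if (fwhm_mm == 0) return(as.matrix(x))
  sigma_px <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
  gaussian_smooth_px(as.matrix(x), sigma_px)
}

#' Activity line profile
#'
#' Samples the image along the segment from `start_mm` to `end_mm` (mm
#' coordinates relative to the grid centre, `(row, col)` order), returning
#' physical positions along the segment and interpolated activity.
#'
#' @param x image matrix
#' @param start_mm,end_mm numeric length-2 endpoints in mm
#' @param spacing_mm pixel spacing in mm
#' @param n_samples number of samples along the segment
#' @param method `"bilinear"` or `"nearest"`
#' @return a data frame with columns `position_mm` and `activity`
#' @export
line_profile <- function(x, start_mm, end_mm, spacing_mm = 2.08,
                         n_samples = NULL, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  n <- nrow(x)
  half <- n * spacing_mm / 2
  if (any(abs(c(start_mm, end_mm)) > half)) {
    stop("profile endpoints must lie inside the grid", call. = FALSE)
  }
  len <- sqrt(sum((end_mm - start_mm)^2))
  if (is.null(n_samples)) n_samples <- max(2L, ceiling(2 * len / spacing_mm) + 1L)
  tt <- seq(0, 1, length.out = n_samples)
  r_mm <- start_mm[1] + tt * (end_mm[1] - start_mm[1])
  c_mm <- start_mm[2] + tt * (end_mm[2] - start_mm[2])
  rp <- (r_mm + half) / spacing_mm
  cp <- (c_mm + half) / spacing_mm
  act <- if (method == "bilinear") {
    bilinear_sample(x, rp, cp)
  } else {
    ri <- pmin(pmax(round(rp - 0.5), 0), n - 1)
    ci <- pmin(pmax(round(cp - 0.5), 0), n - 1)
    x[cbind(ri + 1L, ci + 1L)]
  }
  data.frame(position_mm = tt * len, activity = act)
}

#' Evaluation ROI masks from a phantom
#'
#' Grey matter, white matter, hot-lesion and cold-lesion masks (tissue masks
#' eroded by one pixel to reduce boundary ambiguity), plus the whole-brain
#' mask used for global NRMSE.
#'
#' @param phantom a `phantom`
#' @return a named list of logical matrices
#' @export
roi_masks <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  les <- phantom$lesion_masks
  pol <- phantom$lesions$polarity
  mod <- phantom$lesions$modality
  union_mask <- function(sel) {
    if (!length(sel)) return(matrix(FALSE, phantom$size_px, phantom$size_px))
    Reduce(`|`, les[sel])
  }
  pet_les <- which(mod != "mr_only")
  list(global = phantom$tissue > 0L,
       grey = erode_mask(phantom$tissue == 2L),
       white = erode_mask(phantom$tissue == 1L),
       hot_lesions = union_mask(intersect(which(pol == "hot"), pet_les)),
       cold_lesions = union_mask(intersect(which(pol == "cold"), pet_les)))
}

#' Tabulated NRMSE comparison of reconstruction methods
#'
#' Computes per-method, per-ROI, per-count-level NRMSE over a set of
#' reconstructed images and their references.
#'
#' @param recons a nested list: `recons[[method]][[sample]]` is an image
#'   matrix
#' @param refs list of reference image matrices (one per sample)
#' @param rois a list per sample of named ROI logical matrices (e.g. from
#'   [roi_masks()]); ROIs that are empty for a sample are skipped
#' @param count_levels numeric vector, count level per sample (used only as
#'   a grouping label; default a single group)
#' @return a data frame with columns `method`, `roi`, `count_level`,
#'   `nrmse` (mean over samples) and `n_samples`
#' @export
compare_methods <- function(recons, refs, rois, count_levels = NULL) {
  methods <- names(recons)
  if (is.null(methods)) stop("recons must be a named list of methods", call. = FALSE)
  ns <- length(refs)
  if (is.null(count_levels)) count_levels <- rep(NA_real_, ns)
  roi_names <- names(rois[[1]])
  rows <- list()
  for (mth in methods) {
    if (length(recons[[mth]]) != ns) stop("missing reconstructions for ", mth, call. = FALSE)
    for (rn in roi_names) {
      for (cl in unique(count_levels)) {
        sel <- which(if (is.na(cl)) is.na(count_levels) else count_levels == cl)
        errs <- unlist(lapply(sel, function(s) {
          roi <- rois[[s]][[rn]]
          if (!any(roi)) return(NULL)
          nrmse(recons[[mth]][[s]], refs[[s]], roi)
        }))
        rows[[length(rows) + 1L]] <- data.frame(
          method = mth, roi = rn, count_level = cl,
          nrmse = if (length(errs)) mean(errs) else NA_real_,
          n_samples = length(errs), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("NRMSE comparison (mean over samples):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
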