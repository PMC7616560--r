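#' Scale an activity image to a target expected count level
#'
#' Rescales the activity so that the total expected prompts
#' `sum_i ([Hx]_i + rbar_i)` equal `target_counts`, with a spatially uniform
#' expected-randoms sinogram carrying `randoms_fraction` of the total.
#'
#' @param model a `system_model`
#' @param x activity image (non-negative, not identically zero in the
#'   scanner's view)
#' @param target_counts total expected prompt counts (e.g. `1e6` for a
#'   1M-count acquisition)
#' @param randoms_fraction fraction in `[0, 1)` of total counts due to
#'   accidental coincidences
#' @return a list with the scaled image `x` and the expected-randoms vector
#'   `randoms`
#' @export
scale_to_counts <- function(model, x, target_counts, randoms_fraction = 0.2) {
  stopifnot_scalar(target_counts, "target_counts", positive = TRUE)
  if (randoms_fraction < 0 || randoms_fraction >= 1) {
    stop("randoms_fraction must be in [0, 1)", call. = FALSE)
  }
  trues <- sum(forward_project(model, x))
  if (trues <= 0) stop("phantom has zero activity in the scanner's view", call. = FALSE)
  sc <- target_counts * (1 - randoms_fraction) / trues
  rbar <- rep(target_counts * randoms_fraction / model$geometry$n_lor,
              model$geometry$n_lor)
  list(x = as.matrix(x) * sc, randoms = rbar)
}

#' Sample a Poisson emission sinogram
#'
#' Draws independent counts `y_i ~ Poisson([Hx]_i + rbar_i)`;
#' deterministic given the seed.
#'
#' @inheritParams scale_to_counts
#' @param randoms expected-randoms vector (or scalar) per LOR
#' @param seed integer seed
#' @return a `sinogram`
#' @export
sample_poisson <- function(model, x, randoms = 0, seed = 1L) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("activity must be non-negative", call. = FALSE)
  if (length(randoms) == 1) randoms <- rep(randoms, model$geometry$n_lor)
  if (any(randoms < 0)) stop("randoms must be non-negative", call. = FALSE)
  lam <- forward_project(model, x) + randoms
  y <- with_seed(seed, rpois(length(lam), lam))
  sinogram(y, randoms, model$geometry, seed = as.integer(seed))
}

#' Generate a paired low-dose / reference dataset on disk
#'
#' Builds seeded phantom samples (lesioned, rotation-augmented), simulates
#' low-dose Poisson sinograms with expected randoms, and writes one
#' directory per sample: reference activity (the noise-free count-scaled
#' phantom), counts and randoms sinograms, MR image, mu-map, tissue labels
#' (all NIfTI), and a JSON sidecar with seed, lesion table and rotation. A
#' `manifest.json` indexes the samples. The train split uses rotations
#' within +/-5 degrees; the test split uses different base-phantom seeds,
#' rotations within +/-10 degrees.
#'
#' @param out_dir output directory (created if needed)
#' @param n_slices number of base phantom slices
#' @param n_rotations rotation augmentations per slice
#' @param count_levels expected total prompts; recycled across samples (use
#'   a vector, e.g. `seq(0.2e6, 0.5e6, by = 0.1e6)`, for dose-ladder
#'   experiments)
#' @param split `"train"` or `"test"`
#' @param size_px,spacing_mm phantom grid
#' @param n_lesions,mismatch_fraction lesion protocol per slice
#' @param randoms_fraction fraction of counts due to randoms
#' @param n_subsets ordered subsets of the simulation system model
#' @param seed integer master seed; the dataset is bit-for-bit reproducible
#'   from (arguments, seed)
#' @return (invisibly) the manifest as a data frame
#' @export
build_dataset <- function(out_dir, n_slices = 100L, n_rotations = 5L,
                          count_levels = 1e6, split = c("train", "test"),
                          size_px = 128L, spacing_mm = 2.08,
                          n_lesions = 10L, mismatch_fraction = 0,
                          randoms_fraction = 0.2, n_subsets = 6L,
                          seed = 1L) {
  split <- match.arg(split)
  max_deg <- if (split == "train") 5 else 10
  # disjoint base-seed ranges so test phantoms differ from training ones
  seed_base <- as.integer(seed) * 100000L + (if (split == "train") 0L else 50000L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  geom <- scanner_geometry(size_px, spacing_mm)
  model <- build_system(geom, mumap = NULL, n_subsets = n_subsets)
  manifest <- list()
  idx <- 0L
  for (s in seq_len(n_slices)) {
    base <- make_base_phantom(size_px, spacing_mm, seed = seed_base + s)
    base <- add_lesions(base, n_lesions = n_lesions,
                        mismatch_fraction = mismatch_fraction,
                        seed = seed_base + s + 10000L)
    rots <- augment_rotations(base, n_rotations, max_abs_deg = max_deg,
                              seed = seed_base + s + 20000L)
    for (r in seq_along(rots)) {
      idx <- idx + 1L
      smp <- rots[[r]]
      counts <- count_levels[((idx - 1L) %% length(count_levels)) + 1L]
      att <- attenuation_factors(model, smp$mumap)
      trues <- sum(forward_project(model, smp$activity, att_factors = att))
      sc <- counts * (1 - randoms_fraction) / trues
      xref <- smp$activity * sc
      rbar <- rep(counts * randoms_fraction / geom$n_lor, geom$n_lor)
      lam <- forward_project(model, xref, att_factors = att) + rbar
      y <- with_seed(seed_base + 30000L + idx, rpois(length(lam), lam))
      sdir <- file.path(out_dir, sprintf("sample_%04d", idx))
      dir.create(sdir, showWarnings = FALSE)
      wr <- function(img, name) {
        RNifti::writeNifti(RNifti::asNifti(img, pixdim = c(spacing_mm, spacing_mm)),
                           file.path(sdir, paste0(name, ".nii.gz")))
      }
      wr(xref, "reference")
      wr(smp$mr, "mr")
      wr(smp$mumap, "mumap")
      wr(smp$tissue + 0, "tissue")
      wr(matrix(y, geom$n_radial_bins, geom$n_angles), "sinogram")
      lesion_stack <- if (length(smp$lesion_masks)) {
        Reduce(`+`, lapply(seq_along(smp$lesion_masks), function(k) {
          smp$lesion_masks[[k]] * k
        }))
      } else matrix(0, size_px, size_px)
      wr(lesion_stack, "lesion_labels")
      sidecar <- list(slice = s, rotation_index = r,
                      rotation_deg = smp$rotation_deg,
                      seed_phantom = seed_base + s,
                      seed_noise = seed_base + 30000L + idx,
                      target_counts = counts, randoms_total = sum(rbar),
                      randoms_per_lor = rbar[1],
                      observed_counts = sum(y),
                      activity_scale = sc, split = split,
                      lesions = smp$lesions)
      jsonlite::write_json(sidecar, file.path(sdir, "sample.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      manifest[[idx]] <- data.frame(id = idx, dir = basename(sdir), slice = s,
                                    rotation_index = r,
                                    rotation_deg = smp$rotation_deg,
                                    target_counts = counts,
                                    stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  jsonlite::write_json(list(split = split, n_slices = n_slices,
                            n_rotations = n_rotations, size_px = size_px,
                            spacing_mm = spacing_mm, seed = seed,
                            n_subsets = n_subsets,
                            geometry = unclass(geom)[c("n_angles", "n_radial_bins",
                                                       "bin_spacing_mm")],
                            samples = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Load a dataset written by [build_dataset()]
#'
#' @param dir dataset directory containing `manifest.json`
#' @param ids sample ids to load (default all)
#' @return a list with the `manifest`, the `geometry`, and `samples` — each a
#'   list with `reference`, `mr`, `mumap`, `tissue`, `counts` (vector),
#'   `randoms` (vector) and the sidecar `meta`
#' @export
load_dataset <- function(dir, ids = NULL) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  geom <- scanner_geometry(man$size_px, man$spacing_mm,
                           n_angles = man$geometry$n_angles,
                           n_radial_bins = man$geometry$n_radial_bins,
                           bin_spacing_mm = man$geometry$bin_spacing_mm)
  sel <- if (is.null(ids)) man$samples$id else ids
  samples <- lapply(sel, function(i) {
    sdir <- file.path(dir, man$samples$dir[man$samples$id == i])
    rd <- function(name) {
      m <- as.matrix(RNifti::readNifti(file.path(sdir, paste0(name, ".nii.gz"))))
      matrix(as.numeric(m), nrow(m), ncol(m))
    }
    meta <- jsonlite::read_json(file.path(sdir, "sample.json"), simplifyVector = TRUE)
    list(reference = rd("reference"), mr = rd("mr"), mumap = rd("mumap"),
         tissue = matrix(as.integer(rd("tissue")), man$size_px, man$size_px),
         lesion_labels = rd("lesion_labels"),
         counts = as.vector(rd("sinogram")),
         randoms = rep(meta$randoms_per_lor, geom$n_lor),
         meta = meta)
  })
  list(manifest = man$samples, geometry = geom, config = man, samples = samples)
}
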