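# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# 32x32 phantom with lesions and its system models.
fix_phantom32 <- function() fixture("ph32", {
  ph <- make_base_phantom(32, 2.08, seed = 2)
  add_lesions(ph, n_lesions = 5, radius_range_mm = c(2, 8), seed = 7)
})

fix_geom32 <- function() fixture("geom32", scanner_geometry(32, 2.08))

fix_model32 <- function() fixture("model32", {
  build_system(fix_geom32(), fix_phantom32()$mumap, n_subsets = 6)
})

fix_model32_1sub <- function() fixture("model32_1sub", {
  build_system(fix_geom32(), fix_phantom32()$mumap, n_subsets = 1)
})

# A 1M-scale-down noisy acquisition of the 32x32 phantom (2e5 counts).
fix_sino32 <- function() fixture("sino32", {
  sc <- scale_to_counts(fix_model32(), fix_phantom32()$activity, 2e5,
                        randoms_fraction = 0.2)
  list(sino = sample_poisson(fix_model32(), sc$x, sc$randoms, seed = 11),
       reference = sc$x, randoms = sc$randoms)
})

# Downsample a matrix by 2x2 block averaging (for 16x16 toys).
downsample2 <- function(m) {
  n <- nrow(m) / 2
  out <- matrix(0, n, n)
  for (a in 0:1) for (b in 0:1) {
    out <- out + m[seq(1 + a, 2 * n, 2), seq(1 + b, 2 * n, 2)]
  }
  out / 4
}

# 16x16 toy problem for monotonicity studies.
fix_toy16 <- function() fixture("toy16", {
  ph <- fix_phantom32()
  act <- downsample2(ph$activity)
  mr <- downsample2(ph$mr)
  geom <- scanner_geometry(16, 4.16, n_angles = 24, n_radial_bins = 24,
                           bin_spacing_mm = 4.16)
  model <- build_system(geom, downsample2(ph$mumap), n_subsets = 1)
  sc <- scale_to_counts(model, act, 5e4, randoms_fraction = 0.2)
  sino <- sample_poisson(model, sc$x, sc$randoms, seed = 3)
  list(model = model, sino = sino, reference = sc$x, mr = mr)
})

# Tiny 8x8 problem with a dense system matrix oracle.
fix_tiny8 <- function() fixture("tiny8", {
  geom <- scanner_geometry(8, 2.08, n_angles = 8, n_radial_bins = 12)
  model <- build_system(geom, NULL, n_subsets = 2)
  ph <- make_base_phantom(32, 2.08, seed = 1)
  act <- ph$activity[13:20, 13:20] + 0.5
  lam <- forward_project(model, act) + 0.5
  y <- with_seed_test(21, rpois(length(lam), lam))
  list(model = model, act = act,
       sino = sinogram(y, 0.5, geom),
       # dense attenuated system matrix in native LOR order
       H = {
         H <- matrix(0, geom$n_lor, 64)
         for (m in seq_len(model$n_subsets)) {
           H[model$subset_rows[[m]], ] <- as.matrix(model$Hs[[m]]) *
             model$att[model$subset_rows[[m]]]
         }
         H
       })
})

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Training/evaluation samples on a shared 64x64 geometry (no attenuation in
# the shared model; per-sample attenuation factors).
make_study_sample <- function(model, seed, max_deg = 5, counts = 1e5,
                              randoms_fraction = 0.2, mismatch_fraction = 0) {
  geom <- model$geometry
  ph <- make_base_phantom(geom$image_size_px, geom$image_spacing_mm, seed = seed)
  ph <- add_lesions(ph, n_lesions = 10, radius_range_mm = c(2, 10),
                    mismatch_fraction = mismatch_fraction, seed = seed + 1000L)
  ph <- augment_rotations(ph, 1, max_abs_deg = max_deg, seed = seed + 2000L)[[1]]
  att <- attenuation_factors(model, ph$mumap)
  trues <- sum(forward_project(model, ph$activity, att_factors = att))
  sc <- counts * (1 - randoms_fraction) / trues
  xref <- ph$activity * sc
  rbar <- rep(counts * randoms_fraction / geom$n_lor, geom$n_lor)
  lam <- forward_project(model, xref, att_factors = att) + rbar
  y <- with_seed_test(seed + 3000L, rpois(length(lam), lam))
  list(counts = y, randoms = rbar, reference = xref, mr = ph$mr,
       mumap = ph$mumap, att = att, phantom = ph,
       sino = sinogram(y, rbar, geom, seed = seed + 3000L))
}

fix_model64 <- function() fixture("model64", {
  build_system(scanner_geometry(64, 2.08), NULL, n_subsets = 6)
})
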