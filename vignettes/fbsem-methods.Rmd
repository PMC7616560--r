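---
title: "MAP PET reconstruction by forward-backward splitting EM, and its trained unrolled form"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MAP PET reconstruction by forward-backward splitting EM, and its trained unrolled form}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The reconstruction model

PET measurements are modelled as independent Poisson counts per line of
response (LOR): `y_i ~ Poisson([Hx]_i + r_i)`, where `H` is the system
matrix (geometric intersection weights times attenuation factors), `x` the
non-negative activity image, and `r` the expected accidental-coincidence
(randoms) rate. The maximum a posteriori estimate maximizes

    L(y | x) - beta * P(x),
    L(y | x) = sum_i [ y_i log([Hx]_i + r_i) - ([Hx]_i + r_i) ],

with a convex differentiable penalty `P`. The package solves this by
forward-backward splitting: each ordered-subset state takes

1. a **regularization step** `x_Reg = x - gamma * beta * grad P(x)`,
2. an **EM update** of `x` using the counts of subset `m` (with randoms in
   the denominator and the subset sensitivity image
   `s_j^(m) = sum_{i in subset m} h_ij`),
3. a **fusion** of the two images: the non-negative root of the per-voxel
   quadratic `delta x^2 + (1 - delta x_Reg) x - x_EM = 0` with
   `delta_j = 1 / (gamma s_j^(m))`.

As `gamma -> Inf` the fusion returns `x_EM` and the algorithm is exactly
OSEM (`fbsem_reconstruct` with `prior = NULL` takes this path and is tested
against an independent OSEM loop to machine precision).

### Pair counting in the quadratic prior

The MR-weighted quadratic (Tikhonov) penalty is written as the ordered
double sum `R(x) = 1/2 sum_j sum_{b in N_j} w_jb (x_j - x_b)^2`, in which
every unordered neighbour pair appears twice. The penalty the package puts
into the objective is `P(x) = R(x) / 2` — each pair penalized once. This
convention is deliberate: the exact gradient of `P` for symmetric weights is
the conventional per-voxel form `sum_b w_jb (x_j - x_b)`, and with it the
substitution `beta = 1/2`, `gamma_j = 1 / sum_b w_jb` turns the
regularization step *exactly* into De Pierro's closed-form neighbour
average, `x_Reg,j = sum_b w_jb (x_j + x_b) / (2 sum_b w_jb)`. Had we kept
the double-counted `R` as the penalty, the same reduction would hold only
with an extra factor of 2 buried in either `beta` or the weights. The
identity is asserted to 1e-12 in the tests, and the finite-difference
gradient check runs against `P`.

In De Pierro mode with a general `beta`, the fusion weight is
`delta_j = 2 beta sum_b w_jb / s_j^(m)` (the surrogate derivation of the
quadratic update under the pair-once penalty), which reduces to the printed
`beta = 1/2` pair above. With one subset this mode is a true
minorize-maximize scheme, so the objective trace is non-decreasing; the
generic-gamma mode is a splitting approximation and is monotone only for
small enough steps.

### MR guidance

Anatomical weights are `w_jb = exp(-(m_j - m_b)^2 / (2 sigma^2))` over an
8-connected stencil, symmetrized by averaging with the transpose and
divided by inter-voxel distance (diagonal neighbours carry `1/sqrt(2)`).
`sigma = "auto"` uses the standard deviation of in-grid neighbour
differences (over a mask if supplied); a constant MR image degenerates to
uniform weights. These are deliberately simple guidance weights — no
edge-set truncation or neighbour ranking — and they are what the MAPEM
baseline uses.

## The unrolled network

Fixing `N = N_it x N_sub` states and replacing the gradient regularization
step by a residual convolutional unit yields a recurrent reconstruction
network: `x_Reg = ReLU(x + unit(x[, mr]))`, EM update (non-trainable),
fusion with `delta = 1 / (gamma s^(m))` where `gamma = exp(rho)` is a
trainable scalar. One parameter set is shared by all states. Training
minimizes the mean squared error to reference high-count images with Adam;
backpropagation passes through the regularization and fusion computations
(including their recurrence through previous states) but **not** through
the EM update, which is treated as a fixed operation — the tests verify
this by comparing analytic gradients with finite differences of a forward
pass whose EM images are frozen, and by showing they differ from the fully
differentiated chain.

The unit is fixed by the parameter budget: five 3x3 convolutions (1 or 2
input channels, then 32, 32, 32, 32, 1 output channels), each with a bias
and affine batch normalization, ReLU after the hidden normalizations, and a
final non-negativity ReLU on the residual sum. PET-only input gives exactly
28 612 trainable scalars (320 + 27 744 + 289 + 258 convolution/BN
parameters + gamma); a five-times-32-filter reading would not close to that
number, so the last layer has a single filter. Where the layer ordering was
not decidable (activation before or after normalization), ReLU-after-BN was
chosen as the conventional option.

Numerical choices:

* **Normalization statistics.** The BN layers are shared by all unrolled
  states, whose activation distributions differ strongly (state 1 sees a
  near-uniform image, state N a near-converged one). A single running
  average over states is therefore ill-defined, and inference with such
  averages diverged while training behaved. The package normalizes every
  forward pass with the statistics of the data being processed, in training
  and inference alike; this is deterministic and mirrors instance
  normalization.
* **Initialization.** He initialization for the hidden layers; the final
  convolution starts near zero so the untrained unit is close to the
  identity and the early states behave like a mildly damped EM; `gamma` is
  trained on a log scale (initial value 1) to stay positive.
* **Fusion gradients.** Implicit differentiation of the fused quadratic
  gives `dx/dx_Reg = delta x / S` and `dx/ddelta = x (x_Reg - x) / S` with
  `S = sqrt((1 - delta x_Reg)^2 + 4 delta x_EM)`, guarded at `S >= 1e-9`;
  the rationalized root form `2 x_EM / (B + S)` falls back to
  `(S - B) / (2 delta)` when the denominator underflows.
* **EM guards.** Denominators carry a 1e-12 floor; voxels with zero subset
  sensitivity are frozen at zero and excluded from gradients.

## Synthetic phantoms and what they do (not) show

The phantom generator produces brain-like 2D slices procedurally: a
harmonically deformed ellipse for the brain outline, an inner deformed
region for white matter with a grey-matter ribbon around it, small
ventricles, a soft-tissue/skull attenuation map (0.0096 and 0.0143 per mm),
and a T1-like MR image with independent contrast (white bright, bone
dark). Activity contrasts default to grey:white:background = 4:1:0; lesions
are disks of uniform-random radius 2-10 mm placed fully inside the brain,
hot (x2) or cold (x0.25) with equal probability, optionally present in only
one modality to emulate functional/anatomical mismatch; these contrast
values are package choices (the protocol fixes only the lesion geometry)
and sit in the function signatures. Rotation augmentation draws angles
within +/-5 degrees for training and +/-10 degrees for testing, bilinear
for continuous channels (clipped at zero) and nearest-neighbour for masks.

The simulation emulates count statistics faithfully (expected-count
scaling is exact; Poisson sampling is seeded and Monte-Carlo checked) but
deliberately omits scatter, detector blur, normalization, dead time and 3D
effects, and the parallel-beam geometry stands in for a cylindrical
scanner. Passing tests therefore demonstrate the algorithmic claims —
identities, monotonicity, adjointness, learning behaviour — on data whose
noise model matches the assumptions exactly; they do not certify
performance on real scanner data.

## Problem sizes and study conditions

The full protocol (100 slices, 5 rotations, 500 samples of 128+ pixels,
1M counts, `N_it = 10`, `N_sub = 6`, 50 epochs, 10 minibatches, learning
rate 0.05) is expressed in the defaults of `build_dataset()` and
`fbsem_net()`. The package's own studies (tests and the acceptance script)
run a desk-scale version chosen once: 64x64 grids at 2.08 mm, 1e5 counts
with a 0.2 randoms fraction, 8 training samples, `N_it = 2` unrolled
iterations (12 states), 8 epochs, 10 minibatches (clipped to the sample count), learning rate 0.01 — small
enough to run routinely on one core while keeping every qualitative
behaviour (the trained network and the tuned MAPEM baseline both beat
unfiltered OSEM in mean NRMSE on held-out phantoms). The MAPEM baseline's
`gamma` is selected from a grid centred on the De Pierro value
`1 / (2 mean(sum_b w_jb))` by the NRMSE criterion, mirroring how the
classical baseline is tuned.

## Evaluation conventions

NRMSE is `sqrt(sum_roi (x - ref)^2) / sqrt(sum_roi ref^2)`; the reference
normalization makes it invariant to joint rescaling. ROI tables use the
phantom's tissue and lesion masks eroded by one pixel to reduce boundary
ambiguity. The filtered-OSEM baseline uses an isotropic Gaussian with
FWHM in mm (`sigma_px = fwhm / (2 sqrt(2 log 2)) / spacing`). These
conventions are internally consistent; absolute NRMSE values are not
comparable to bar charts produced under unknown ROI conventions elsewhere.

## Known limitations

* The projector is 2D parallel-beam with interpolation-weight line
  integrals; no scatter, PSF or time-of-flight.
* The generic-gamma splitting mode is not guaranteed monotone for large
  steps (De Pierro mode is, with one subset).
* Training is CPU-bound R/C++; the desk-scale configuration trains in
  minutes, the full protocol in hours.
* Only the quadratic prior ships; the prior interface accepts any
  differentiable penalty but non-quadratic penalties have no De Pierro
  mode.
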