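---
title: "Multi-channel registration and 4D growth-curve atlases: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-channel registration and 4D growth-curve atlases: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mcatlas` implements a symmetric multi-channel demons registration for
combined structural and diffusion (ODF) neonatal brain MRI, and the
spatio-temporal atlas pipeline built on it: age-windowed robust template
averaging, unbiasing average inverse transforms, voxelwise Gompertz
growth-curve fitting, transient-region parcellation and region-of-interest
association statistics. Everything is exercisable on seeded synthetic
phantoms with known ground truth; no imaging data ships with the package.

# Spherical-harmonic representation

ODFs are antipodally symmetric spherical functions and are stored as real,
even-order spherical-harmonic (SH) expansions. The package convention,
fixed in `R/sh.R` and used everywhere, is: fully normalised real SH
(orthonormal under the uniform spherical measure), no Condon-Shortley
phase, degrees `l = 0, 2, ..., lmax`, coefficients ordered `(l, m)`
lexicographically with `m = -l..l` (sine terms at negative `m`). An order
`L` image carries `(L+1)(L+2)/2` coefficients per voxel.

SH rotation — needed to reorient ODFs under spatial transforms — is
implemented as an exact band-wise operator built numerically: the rotated
function is sampled on a Gauss-Legendre x uniform-azimuth product
quadrature exact to degree `2L` and projected back onto the basis. This
avoids hand-coded Wigner recursions; per-band coefficient norms are
preserved to machine precision. The original work reorients ODFs with
apodized point-spread functions whose parameters are not published; the
exact band-wise rotation used here is a documented substitute, and anyone
needing bit-compatibility with the original should be aware of it.

# Similarity metrics

Structural channels are compared with local normalized cross-correlation
(LNCC) over a cubic neighbourhood of half-width `radius` voxels (default
3), with the local mean subtracted inside the same neighbourhood. ODF
channels use local angular correlation (LAC): the same windowed Pearson
form, but accumulated over the `l >= 2` SH coefficients jointly (3D space
x SH dimension), with each coefficient image centred on its local mean.
The `l = 0` term therefore cannot contribute, which makes the metric
insensitive to isotropic magnitude differences between acquisitions.

Both metrics come with a symmetric pair of demons update fields; the pair
is obtained from the correlation form by differentiating with respect to
each image's displacement, contracting residuals against the spatial
gradients of the locally-centred images. Implementation notes:

* neighbourhoods are cubic with uniform weights, computed by exact
  separable box sums and truncated at the grid border (the neighbourhood
  size map enters the mean-centring);
* spatial gradients are central differences, one-sided at borders,
  expressed in world mm through the voxel-to-world affine;
* voxels where either image's centred local sum of squares falls below
  `1e-6 x` its within-mask average are flagged undefined and produce zero
  updates. The update formulas' global constant is absorbed into the
  step-size rule below.

# Multi-channel symmetric registration

Registration proceeds over resolution levels (default scales
`{0.5, 0.75, 1.0}` with SH order schedule `{0, 2, 2}`; at order-0 levels
the ODF contributes its `l = 0` coefficient through the scalar metric).
Both images deform toward a midpoint with half-warps. Each iteration:

1. warp both channel sets by their current half-warps (ODFs reoriented by
   the rotational polar factor of the local warp Jacobian);
2. compute per-channel symmetric update pairs (LNCC for scalar and mask
   roles, LAC for ODF roles);
3. fuse them by certainty-weighted averaging: each channel's weight map is
   the norm of its spatial gradient (for ODF channels the full SH gradient
   norm by default, with an `l = 0`-only switch) normalised to peak at 1,
   recomputed from the warped channels every iteration;
4. smooth the fused update (Gaussian, 1 voxel), apply the step-size rule,
   compose compositively into the half-warps, and smooth the composed
   fields (Gaussian, 0.75 voxel).

The metric only defines updates up to a scale, so a gain is calibrated
once — at the first iteration of the coarsest level, where misalignment is
largest — such that the maximum update magnitude equals
`step_size_voxels` (default 0.5). Later iterations reuse that gain, so
the updates decay naturally as the pair aligns, and are capped at the
step size. (A per-iteration re-normalisation forcing the maximum to the
step size was tried first; it prevents settling, because noise-level
forces get amplified to full step length indefinitely.) A level ends on
an iteration cap, on the mean update magnitude falling below
`convergence_tolerance`, or on a metric plateau (no improvement of the
mean correlation for 3 iterations); ten consecutive increases of the mean
update magnitude abort with a divergence error.

Masks are registered as soft scalar channels under LNCC. The forward and
reverse full warps are compositions through the midpoint, which makes the
scheme symmetric by construction and yields the inverse warps needed for
template unbiasing at no extra cost.

Affine pre-alignment maximises global NCC over 12 parameters
(translation, rotation, log-scale, shear about the volume centre) with a
coarse translation grid search followed by staged Nelder-Mead at two
resolutions. It is off by default in the atlas pipeline because the
phantom cohorts are generated affinely co-aligned; it is enabled by a
single configuration flag for data with bulk pose or size differences.

# Atlas construction

Stage 1 registers every subject to a single reference using structural
and mask channels and robust-averages all warped channels into one global
template set. Stage 2 rescales each subject's ODF so its mean `l = 0`
level inside the brain matches the cohort median (the original work
normalises DWI globally without publishing a formula; a global `l = 0`
match is the simplest faithful reading), re-registers with structural,
mask and ODF channels against the stage-1 templates, then splits the
cohort into disjoint age windows (nearest centre, ties to the younger
window; default centres 37.0-44.0 weeks in 0.5-week steps).

Per window and channel, templates are robust weighted averages: voxelwise
(per SH coefficient), values deviating from the across-subject mean by
more than 1.5 *population* standard deviations get weight zero. The
population divisor matches the voxelwise reading of the weighting rule
and guarantees algebraically that at least one subject is retained at
every voxel; variance is computed in centred two-pass form because the
one-pass formula cancels catastrophically on near-identical warped
values. A window with a single subject yields that subject's map with
full retention (it cannot reject outliers). The weights are
channel-specific.

Unbiasing transforms per window are the voxelwise mean of the subjects'
inverse warps, and the inverse of the log-domain mean of the symmetric
(scale/shear) polar factors of their affines — rotation and translation
are discarded.

# Temporal Gompertz model

Template values, inverse-warp components and affine scale/shear entries
are fitted in age by
`G(t) = (alpha - delta) exp(-exp(-gamma (tau - t))) + delta`, where
`alpha` is the early asymptote, `delta` the mature asymptote, `gamma` the
rate per week and `tau` the peak-growth time. Fitting is per voxel (per
component / entry) by Levenberg-Marquardt with analytic Jacobian, bounds
`gamma` in [-5, 5] and `tau` in the window range widened by 4 weeks, and
initialisation from the first/last thirds' means, mid-range `tau`, and
the range-normalised central slope. The form is mirror-symmetric under
`(alpha <-> delta, gamma -> -gamma)`, so both orientations are tried and
the lower-residual optimum kept (the restart is skipped when the first
fit is already essentially exact). Zero-variance series are not fitted
and report `R^2 = 0` by convention; optimiser failures fall back to the
linear fit with `gamma = sign(slope) * 1e-3`, flagged in a convergence
map. An ordinary linear fit and its `R^2` are always computed alongside.
Windows are weighted equally.

On series with realistic rates (`|gamma|` around 0.3-0.5 per week over a
7-week window) and 5%-of-range noise, `gamma` and `tau` are close to
their identifiability limit: the Cramer-Rao bound for `gamma` at
`gamma = 0.45` is about 24% relative standard deviation, so per-voxel
rate estimates at this noise level are indicative rather than precise,
and the package's validation treats high-accuracy recovery as a
noiseless property. Median `R^2` of the Gompertz fit exceeding the linear
fit's on curved series is the robust, reproducible signature.

The fitted atlas is evaluated at any `t` in [37, 44] weeks by evaluating
the channel curves, then resampling through the fitted `W^-1(t)` followed
by the fitted scale/shear `A^-1(t)` (SH channels reoriented), emitting
the Jacobian determinant map of `W^-1(t)` alongside. The warp and affine
curves are fitted separately, exactly as the averaging produces them.

# Parcellation and statistics

The transient-region map is the voxelwise mean of `|gamma|` over selected
channels. It is thresholded (default 0.25 per week, the published
operating point), decomposed into 26-connected components, and components
below 27 voxels (a 3^3 cube) are dropped; labels are ordered by
descending size. Only this automatic stage is implemented — the original
work refines the map manually, which is out of scope; externally curated
label volumes can be supplied as NIfTI label images instead.

Region statistics use the same 1.5-population-SD robust mean as the
templates. Associations are ordinary least squares of the regional robust
mean on gestational age at birth with postmenstrual age at scan as a
covariate, one model per (region, channel), with Bonferroni correction
over the number of tests.

# The phantom generator

The phantom emulates the *structure* of a co-registered multi-channel
cohort, not anatomy: an ellipsoidal brain with a cortical ribbon and a
central ventricle, two orthogonal WM bundles crossing once, scalar
channels whose tissue values follow known Gompertz trajectories (T2w-like
decreasing and T1w-like increasing around `tau = 40-40.5` weeks with
rates 0.3-0.45 per week, matching the published rate range of 0-0.5), an
order-4 SH ODF channel built from Watson-kernel fibers, and binary
cortex/ventricle masks. A fixed smooth sinusoidal "anatomical texture"
(15% in cortex, 5% in WM) is shared by all subjects: real tissue has
spatial structure everywhere, and without it a correlation-driven
registration can only recover boundary-normal motion (the aperture
problem), which no amount of iteration fixes. Per-subject ground-truth
warps are seeded sums of low-frequency sinusoids, amplitude-capped
(default 2 voxels) and verified positive-Jacobian at generation; noise is
additive Gaussian at a fraction (default 5%) of each channel's dynamic
range, with masks left exact.

What passing phantom tests does *not* show: robustness to acquisition
artifacts, intensity non-uniformity, topology differences between
subjects, or anatomical detail at real cortical-folding scales. The
phantom validates the mathematics and the pipeline plumbing, not clinical
performance.

# Numerical choices and problem sizes

* Trilinear interpolation with clamped (replicate) borders everywhere;
  masks thresholded at 0.5 after interpolation.
* Warp inversion by fixed-point iteration (cap 50), accepted below 0.1
  voxel composition residual.
* Gaussian smoothing kernels truncated at 3 sigma and renormalised over
  the in-bounds support.
* Separable box sums are exact (integer-exact on integer inputs).
* The e-guards on correlation denominators and the 1e-9 relative slack in
  the robust-averaging comparison exist to keep numerically identical
  values from being excluded by rounding noise.

The shipped validation runs at the sizes the package documents for its
own benchmarks: 8^3 fields for metric oracles against literal loop
evaluations, 48^3 two-channel phantoms for registration recovery
(2-voxel known warps), 15 half-week windows for curve fitting, and a
6-subject zero-noise 48^3 cohort for the end-to-end pipeline identity
and checksum determinism. Registration iteration caps default to
(30, 20, 15) per level with plateau stopping; the zero-noise pipeline
benchmark uses (6, 4, 3), which that degenerate cohort saturates.

# Known limitations

* ODF reorientation differs from the original's apodized-PSF scheme (see
  above); absolute SH values after warping are convention-exact but not
  bit-compatible with MRtrix3.
* The affine optimiser is derivative-free; for large rotations combined
  with strong scaling it may need more iterations than the defaults.
* Voxelwise Gompertz rate maps at realistic noise are near their
  information limit (see the Cramer-Rao note above).
* Windows are disjoint; no kernel regression across ages is provided.
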