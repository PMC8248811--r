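# mcatlas

Multi-channel diffeomorphic registration and 4D growth-curve atlas
construction for combined structural + diffusion (ODF) brain MRI, with a
fully synthetic validation suite.

Spatial normalisation of neonatal brain MRI is hard because tissue
contrast changes rapidly with maturation: two scans of the same anatomy at
different ages disagree in intensity even when perfectly aligned. This
package implements a registration and atlas-building toolchain designed
for that regime, for researchers building spatio-temporal templates or
running atlas-space region statistics:

* **Local angular correlation (LAC)** — a windowed Pearson correlation of
  the degree `l >= 2` real spherical-harmonic (SH) coefficients of two ODF
  images over a cubic neighbourhood `N(x)`,

  `r_a(x) = <A,B>_x / (<A,A>_x^1/2 <B,B>_x^1/2)`,

  with each coefficient image centred on its local mean, so the isotropic
  `l = 0` content cannot contribute. Scalar channels use local normalized
  cross-correlation (LNCC). Both metrics yield symmetric demons update
  field pairs.
* **Certainty-weighted multi-channel fusion** — per-channel updates are
  combined by voxelwise weighted averaging with gradient-magnitude
  certainty maps `a_i = |grad A_i|, a^ = a / max(a)`, so locally
  low-contrast channels defer to informative ones.
* **Symmetric multi-resolution demons registration** — both images deform
  toward a midpoint with half-updates; returns forward and inverse warps,
  Jacobian maps, with per-voxel ODF reorientation.
* **4D atlas pipeline** — two-stage cohort registration, age-windowed
  robust weighted template averaging (values beyond 1.5 SD excluded),
  unbiasing average inverse warps and scale/shear affines, and voxelwise
  fitting of the Gompertz growth curve

  `G(t) = (alpha - delta) exp(-exp(-gamma (tau - t))) + delta`

  to templates, warps and affines — `gamma` is the growth rate (per week)
  and `tau` the peak-growth time (weeks).
* **Parcellation and statistics** — transient-region parcellation from the
  mean absolute growth-rate map (threshold 0.25, 26-connected components),
  robust ROI means, and linear-model association with gestational age at
  birth (Bonferroni-corrected).
* **Phantom generator** — seeded multi-channel cohorts (scalar + SH ODF +
  masks) with known Gompertz trajectories, known smooth invertible warps
  and crossing-fiber content, providing ground truth for every stage.

## Worked example

Recover a known 2-voxel smooth deformation on a 48-cube two-channel
phantom, then check that adding the ODF channel improves white-matter
alignment:

```r
library(mcatlas)

spec <- phantom_spec(grid_shape = 48, noise_sigma = 0,
                     warp_amplitude_voxels = 2, seed = 1)
tpl  <- mcatlas:::phantom_template(spec, 40)      # clean template, 40 weeks
subj <- make_phantom_subject(spec, 40, subject_seed = 11)

fixed  <- channel_set("tpl", 40, tpl$channels[c("T2w", "cortex_mask")])
moving <- channel_set("s",  40, subj$channelset$channels[c("T2w", "cortex_mask")])
reg <- register_multichannel(fixed, moving, registration_config())

err <- reg$warp_fixed_to_moving$vectors - subj$truth$warp$vectors
epe <- sqrt(rowSums(matrix(err, ncol = 3)^2))
tis <- mcatlas:::phantom_tissues(spec)
mean(epe[as.vector(tis$brain)])
#> [1] 0.3829...
```

A mean endpoint error of about 0.38 voxels against an initial
misalignment averaging 0.8 voxels (max 2.0): the deformation is largely
recovered. Repeating with `c("T2w", "cortex_mask", "odf")` channels drops
the white-matter endpoint error from about 0.32 to about 0.27 voxels —
the angular-correlation ODF channel contributes orientation information
that the scalar channels do not carry.

Fitting growth curves to a 15-window template series:

```r
tt <- seq(37, 44, by = 0.5)
y  <- gompertz(tt, alpha = 0.75, delta = 0.55, gamma = 0.45, tau = 40.5)
fit <- fit_gompertz_maps(tt, rbind(y))
c(fit$gamma, fit$tau)
#> [1]  0.45 40.50
```

## Command line

`inst/cli/mcatlas.R` wraps the pipeline as subcommands
(`register`, `build-atlas`, `fit-gompertz`, `evaluate-atlas`,
`parcellate`, `roi-stats`, `associate`, `make-phantom`), e.g.

```sh
Rscript inst/cli/mcatlas.R make-phantom --n 6 --noise 0 --out phantom/
Rscript inst/cli/mcatlas.R build-atlas --manifest phantom/manifest.tsv \
    --reference T2w=phantom/reference_T2w.nii.gz,cortex_mask=phantom/reference_cortex_mask.nii.gz,odf=phantom/reference_odf.nii.gz \
    --out atlas/
```

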