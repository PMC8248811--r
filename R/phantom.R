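#' Synthetic multi-channel phantom cohorts
#'
#' Seeded generator of schematic "neonatal brain"-like multi-channel volumes
#' with known ground truth, used to validate every stage of the pipeline:
#' an ellipsoidal brain with a cortical ribbon, a central ventricle and two
#' crossing white-matter bundles; scalar channels whose tissue values follow
#' known Gompertz trajectories in age; an even-order SH ODF channel with
#' single-fiber bundles and a crossing region; binary cortex/ventricle mask
#' channels; plus a smooth invertible random warp and additive noise per
#' subject. All randomness is fixed by seeds.
#'
#' @param grid_shape integer scalar or length-3; default `48`.
#' @param voxel_size_mm isotropic voxel size.
#' @param lmax even SH order of the ODF channel.
#' @param noise_sigma additive Gaussian noise, as a fraction of each
#'   channel's dynamic range.
#' @param warp_amplitude_voxels maximum ground-truth displacement magnitude.
#' @param warp_cycles number of sinusoid cycles across the field of view for
#'   the ground-truth warp (low values give smooth, invertible warps).
#' @param seed base seed for the spec.
#' @param gompertz named list of per-tissue, per-channel Gompertz truth
#'   (alpha, delta, gamma, tau); defaults model a T2w-like signal decreasing
#'   and a T1w-like signal increasing with maturation around 40.5 weeks.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = 48, voxel_size_mm = 1.0, lmax = 4,
                         noise_sigma = 0.05, warp_amplitude_voxels = 2.0,
                         warp_cycles = 1, seed = 1L, gompertz = NULL) {
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  if (warp_amplitude_voxels > 0.25 * min(grid_shape))
    stop("warp amplitude exceeds 25% of the grid extent")
  if (is.null(gompertz)) gompertz <- list(
    # value = (alpha - delta) exp(-exp(-gamma (tau - t))) + delta:
    # alpha is the early (t -> -inf) level, delta the mature level
    T2w = list(wm     = c(alpha = 0.75, delta = 0.55, gamma = 0.45, tau = 40.5),
               cortex = c(alpha = 0.52, delta = 0.45, gamma = 0.30, tau = 40.0),
               ventricle = c(alpha = 1.0, delta = 1.0, gamma = 0.3, tau = 40.5)),
    T1w = list(wm     = c(alpha = 0.45, delta = 0.68, gamma = 0.40, tau = 40.5),
               cortex = c(alpha = 0.50, delta = 0.57, gamma = 0.30, tau = 40.0),
               ventricle = c(alpha = 0.20, delta = 0.20, gamma = 0.3, tau = 40.5)),
    odf_amp = list(bundle = c(alpha = 0.6, delta = 1.1, gamma = 0.5, tau = 40.5))
  )
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm, lmax = as.integer(lmax),
                 noise_sigma = noise_sigma,
                 warp_amplitude_voxels = warp_amplitude_voxels,
                 warp_cycles = warp_cycles, seed = as.integer(seed),
                 gompertz = gompertz),
            class = "phantom_spec")
}

# tissue layout: logical arrays for brain, cortex ribbon, ventricle, WM,
# two bundles and their crossing
phantom_tissues <- function(spec) {
  n <- spec$grid_shape
  cx <- (n - 1) / 2
  ix <- (seq_len(n[1]) - 1 - cx[1]) / (0.42 * n[1])
  iy <- (seq_len(n[2]) - 1 - cx[2]) / (0.38 * n[2])
  iz <- (seq_len(n[3]) - 1 - cx[3]) / (0.36 * n[3])
  rho2 <- outer(outer(ix^2, iy^2, "+"), iz^2, "+")
  brain <- rho2 <= 1
  cortex <- rho2 <= 1 & rho2 > 0.72
  vx <- (seq_len(n[1]) - 1 - cx[1]) / (0.11 * n[1])
  vy <- (seq_len(n[2]) - 1 - cx[2]) / (0.14 * n[2])
  vz <- (seq_len(n[3]) - 1 - cx[3]) / (0.10 * n[3])
  ventricle <- outer(outer(vx^2, vy^2, "+"), vz^2, "+") <= 1
  wm <- brain & !cortex & !ventricle
  w <- 0.09
  ay <- abs(seq_len(n[2]) - 1 - cx[2]) / n[2]
  az <- abs(seq_len(n[3]) - 1 - cx[3]) / n[3]
  ax <- abs(seq_len(n[1]) - 1 - cx[1]) / n[1]
  # bundle 1 along x (offset above the ventricle), bundle 2 along y
  zoff <- abs(seq_len(n[3]) - 1 - (cx[3] + 0.18 * n[3])) / n[3]
  tube1 <- outer(outer(rep(TRUE, n[1]), ay < w, "&"), zoff < w, "&")
  tube2 <- outer(outer(ax < w, rep(TRUE, n[2]), "&"), zoff < w, "&")
  bundle1 <- tube1 & wm
  bundle2 <- tube2 & wm
  list(brain = brain, cortex = cortex, ventricle = ventricle, wm = wm,
       bundle1 = bundle1, bundle2 = bundle2,
       crossing = bundle1 & bundle2)
}

#' Evaluate the Gompertz growth curve
#'
#' `G(t) = (alpha - delta) exp(-exp(-gamma (tau - t))) + delta`: an
#' asymmetric sigmoid with early asymptote `alpha`, mature asymptote
#' `delta`, rate `gamma` (per week) and peak-growth time `tau` (weeks).
#'
#' @param t time (weeks PMA); vectorised over all arguments.
#' @param alpha,delta,gamma,tau curve parameters.
#' @return curve value(s).
#' @export
gompertz <- function(t, alpha, delta, gamma, tau) {
  (alpha - delta) * exp(-exp(-gamma * (tau - t))) + delta
}

phantom_value <- function(spec, channel, tissue, age) {
  p <- spec$gompertz[[channel]][[tissue]]
  gompertz(age, p["alpha"], p["delta"], p["gamma"], p["tau"])
}

# SH coefficients of a single-fiber Watson-like kernel along `v`
fiber_sh_coeffs <- function(v, lmax, kappa = 8) {
  mach <- sh_projection(lmax)
  amp <- exp(kappa * ((mach$directions %*% v)^2 - 1))
  drop(mach$proj %*% amp)
}

# clean template-space channel set at a given age
phantom_template <- function(spec, age) {
  tis <- phantom_tissues(spec)
  n <- spec$grid_shape
  aff <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  # fixed smooth "anatomical" texture, identical across subjects and ages:
  # real tissue has spatial structure everywhere, which is what makes
  # correlation metrics informative in more than the boundary-normal
  # direction. Stronger in cortex than in deep WM, so the ODF channel
  # retains genuine extra information inside the bundles.
  gx <- (seq_len(n[1]) - 1) / n[1]
  gy <- (seq_len(n[2]) - 1) / n[2]
  gz <- (seq_len(n[3]) - 1) / n[3]
  tex <- outer(outer(sin(2 * pi * 3 * gx + 0.4), sin(2 * pi * 3 * gy + 1.1)),
               sin(2 * pi * 3 * gz + 2.3)) +
    0.6 * outer(outer(sin(2 * pi * 5 * gx + 2.0), cos(2 * pi * 4 * gy + 0.7)),
                sin(2 * pi * 5 * gz + 1.5))
  texmod <- array(1, n)
  texmod[tis$cortex] <- 1 + 0.15 * tex[tis$cortex]
  texmod[tis$wm] <- 1 + 0.05 * tex[tis$wm]
  mk_scalar <- function(channel) {
    a <- array(0, n)
    for (t in c("wm", "cortex", "ventricle"))
      a[tis[[t]]] <- phantom_value(spec, channel, t, age)
    # soften boundaries so gradients exist for registration
    smooth3(a * texmod, 0.8)
  }
  t2 <- mk_scalar("T2w"); t1 <- mk_scalar("T1w")
  nc <- sh_n_coef(spec$lmax)
  coef <- array(0, c(n, nc))
  f1 <- fiber_sh_coeffs(c(1, 0, 0), spec$lmax)
  f2 <- fiber_sh_coeffs(c(0, 1, 0), spec$lmax)
  # constant amplitude 0.35 on the sphere: c0 = A * sqrt(4*pi)
  iso <- rep(0, nc); iso[1] <- 0.35 * sqrt(4 * pi)
  bamp <- phantom_value(spec, "odf_amp", "bundle", age)
  flat <- matrix(0, prod(n), nc)
  flat[as.vector(tis$brain), ] <- matrix(iso, sum(tis$brain), nc,
                                         byrow = TRUE)
  flat[as.vector(tis$bundle1), ] <- flat[as.vector(tis$bundle1), ] +
    matrix(bamp * f1, sum(tis$bundle1), nc, byrow = TRUE)
  flat[as.vector(tis$bundle2), ] <- flat[as.vector(tis$bundle2), ] +
    matrix(bamp * f2, sum(tis$bundle2), nc, byrow = TRUE)
  coef <- array(flat, c(n, nc))
  for (k in seq_len(nc)) coef[, , , k] <- smooth3(coef[, , , k], 0.8)
  chans <- list(
    T2w = scalar_image(t2, aff),
    T1w = scalar_image(t1, aff),
    cortex_mask = mask_image(array(as.numeric(tis$cortex), n), aff),
    ventricle_mask = mask_image(array(as.numeric(tis$ventricle), n), aff),
    odf = sh_image(coef, spec$lmax, aff))
  channel_set("template", age, chans)
}

# smooth seeded random warp: per-component sums of low-frequency sinusoids,
# rescaled so the maximum magnitude equals the requested amplitude
phantom_warp <- function(spec, subject_seed) {
  n <- spec$grid_shape
  aff <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  with_seed(subject_seed, {
    u <- array(0, c(n, 3))
    gx <- (seq_len(n[1]) - 1) / n[1]
    gy <- (seq_len(n[2]) - 1) / n[2]
    gz <- (seq_len(n[3]) - 1) / n[3]
    for (j in 1:3) {
      comp <- array(0, n)
      for (h in 1:3) {
        k <- sample(seq_len(max(1, spec$warp_cycles)), 3, replace = TRUE)
        ph <- runif(3, 0, 2 * pi)
        a <- rnorm(1)
        comp <- comp + a *
          outer(outer(sin(2 * pi * k[1] * gx + ph[1]),
                      sin(2 * pi * k[2] * gy + ph[2])),
                sin(2 * pi * k[3] * gz + ph[3]))
      }
      u[, , , j] <- comp
    }
    mag <- sqrt(rowSums(matrix(u, ncol = 3)^2))
    mx <- max(mag)
    if (mx > 0)
      u <- u * (spec$warp_amplitude_voxels * spec$voxel_size_mm / mx)
    w <- displacement_field(u, aff)
    # invertibility is part of the ground-truth contract
    jd <- jacobian_map(w)$values
    if (min(jd) <= 0)
      w$vectors <- w$vectors * 0.5
    w
  })
}

#' Generate one phantom subject
#'
#' Builds the clean template-space channels at the given age, deforms them
#' by a seeded smooth random warp and adds seeded Gaussian noise (masks stay
#' binary and noise-free). The returned ground truth contains the clean
#' channel set, the warp (the field that deforms the template into the
#' subject, i.e. `subject = warp_channelset(template, warp)`), and the
#' tissue layout.
#'
#' @param spec a [phantom_spec].
#' @param age weeks PMA.
#' @param subject_seed integer seed for this subject's warp and noise.
#' @param subject_id id string.
#' @return list with `channelset` and `truth` (clean set, warp, tissues).
#' @export
make_phantom_subject <- function(spec, age, subject_seed,
                                 subject_id = sprintf("sub-%03d", subject_seed)) {
  clean <- phantom_template(spec, age)
  tis <- phantom_tissues(spec)
  if (spec$warp_amplitude_voxels > 0) {
    warp <- phantom_warp(spec, subject_seed)
    subj <- warp_channelset(clean, warp)
  } else {
    warp <- zero_warp(spec$grid_shape,
                      clean$channels[[1]]$voxel_to_world)
    subj <- clean
  }
  if (spec$noise_sigma > 0) {
    subj$channels <- with_seed(subject_seed + 7L, {
      chans <- subj$channels
      for (nm in names(chans)) {
        ch <- chans[[nm]]
        if (inherits(ch, "mask_image")) next
        if (inherits(ch, "sh_image")) {
          rng <- diff(range(ch$coeffs[, , , 1]))
          ch$coeffs <- ch$coeffs +
            array(rnorm(length(ch$coeffs), 0, spec$noise_sigma * rng),
                  dim(ch$coeffs))
        } else {
          rng <- diff(range(ch$values))
          ch$values <- ch$values +
            array(rnorm(length(ch$values), 0, spec$noise_sigma * rng),
                  dim(ch$values))
        }
        chans[[nm]] <- ch
      }
      chans
    })
  }
  subj$subject_id <- subject_id
  subj$age <- age
  list(channelset = subj,
       truth = list(clean = clean, warp = warp, tissues = tis, age = age))
}

#' Generate a phantom cohort
#'
#' @param spec a [phantom_spec].
#' @param n number of subjects (>= 2).
#' @param age_range ages are drawn uniformly (seeded) over this range.
#' @param cohort_seed integer seed.
#' @param ages optional explicit ages (length `n`), overriding the random
#'   draw — for designed cohorts covering chosen age windows.
#' @return list with `subjects` (list of [channel_set]) and `truth` (ages,
#'   per-subject warps and clean maps, the spec's Gompertz parameters).
#' @export
make_cohort <- function(spec, n, age_range = c(37, 44), cohort_seed = 1L,
                        ages = NULL) {
  if (n < 2) stop("cohort needs at least 2 subjects")
  if (is.null(ages))
    ages <- with_seed(cohort_seed,
                      sort(runif(n, age_range[1], age_range[2])))
  stopifnot(length(ages) == n)
  subjects <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    s <- make_phantom_subject(spec, ages[i],
                              subject_seed = cohort_seed * 1000L + i,
                              subject_id = sprintf("sub-%03d", i))
    subjects[[i]] <- s$channelset
    truths[[i]] <- s$truth
  }
  list(subjects = subjects,
       truth = list(ages = ages, per_subject = truths,
                    gompertz = spec$gompertz, spec = spec))
}
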