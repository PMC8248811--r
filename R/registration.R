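#' Registration configuration
#'
#' Settings for the symmetric multi-resolution multi-channel demons
#' registration. Defaults follow common demons practice for this family of
#' methods: three resolution levels at scales `{0.5, 0.75, 1.0}` with SH
#' order schedule `{0, 2, 2}` for ODF channels, cubic metric neighbourhood
#' of radius 3 voxels, Gaussian smoothing of the fused update with 1 voxel
#' standard deviation and of the composed displacement field with 0.75
#' voxel, and per-iteration updates normalised to a maximum magnitude of
#' `step_size_voxels`.
#'
#' @param level_scales resampling factors per level, ascending.
#' @param lmax_schedule even SH order used per level (same length as
#'   `level_scales`); at levels with order 0 the ODF channel contributes its
#'   `l = 0` coefficient through the scalar metric.
#' @param neighborhood_radius LNCC/LAC neighbourhood half-width, voxels.
#' @param sigma_update_voxels,sigma_displacement_voxels Gaussian sigmas for
#'   update-field and displacement-field regularisation, in voxels.
#' @param max_iterations_per_level iteration caps, recycled over levels.
#' @param step_size_voxels maximum update magnitude per iteration, voxels.
#' @param convergence_tolerance stop when the mean update magnitude (voxels)
#'   falls below this.
#' @param seed integer seed recorded with the run (the core iteration is
#'   deterministic; the seed covers any stochastic initialisation).
#' @return a `registration_config` list.
#' @export
registration_config <- function(level_scales = c(0.5, 0.75, 1.0),
                                lmax_schedule = c(0, 2, 2),
                                neighborhood_radius = 3,
                                sigma_update_voxels = 1.0,
                                sigma_displacement_voxels = 0.75,
                                max_iterations_per_level = c(30, 20, 15),
                                step_size_voxels = 0.5,
                                convergence_tolerance = 1e-3,
                                seed = 1L) {
  if (length(level_scales) != length(lmax_schedule))
    stop("level_scales and lmax_schedule must have equal length")
  if (sigma_update_voxels <= 0 || sigma_displacement_voxels <= 0)
    stop("smoothing sigmas must be positive")
  if (any(lmax_schedule %% 2 != 0)) stop("lmax schedule entries must be even")
  structure(list(level_scales = level_scales,
                 lmax_schedule = as.integer(lmax_schedule),
                 neighborhood_radius = as.integer(neighborhood_radius),
                 sigma_update_voxels = sigma_update_voxels,
                 sigma_displacement_voxels = sigma_displacement_voxels,
                 max_iterations_per_level =
                   rep_len(as.integer(max_iterations_per_level),
                           length(level_scales)),
                 step_size_voxels = step_size_voxels,
                 convergence_tolerance = convergence_tolerance,
                 seed = as.integer(seed)),
            class = "registration_config")
}

smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  cpp_gauss_smooth(as.double(arr), as.integer(dim(arr)), sigma)
}

smooth_vec4 <- function(arr4, sigma) {
  for (j in seq_len(dim(arr4)[4]))
    arr4[, , , j] <- smooth3(arr4[, , , j, drop = TRUE], sigma)
  arr4
}

#' Certainty map of a channel
#'
#' Gradient-magnitude certainty used to weight each channel's contribution
#' to the fused update field: the Euclidean norm of the spatial gradient
#' (for SH images, the root sum of squares over all coefficients'
#' per-coefficient gradient norms), normalised by its maximum so the map
#' peaks at exactly 1. A constant channel yields an all-zero map.
#'
#' @param channel a [scalar_image] or [sh_image].
#' @param name optional channel name carried on the result.
#' @param odf_gradient for SH channels, whether the certainty uses the full
#'   SH gradient norm (default) or only the `l = 0` coefficient image.
#' @return a `certainty_map` (values in `[0, 1]`).
#' @export
certainty_map <- function(channel, name = NULL,
                          odf_gradient = c("full", "l0")) {
  odf_gradient <- match.arg(odf_gradient)
  arrs <- if (inherits(channel, "sh_image")) {
    nk <- if (odf_gradient == "l0") 1L else dim(channel$coeffs)[4]
    lapply(seq_len(nk),
           function(k) channel$coeffs[, , , k, drop = TRUE])
  } else list(channel$values)
  d <- dim(arrs[[1]])
  ssq <- array(0, d)
  for (a in arrs) {
    g <- gradient_world(a, channel$voxel_to_world)
    ssq <- ssq + g[[1]]^2 + g[[2]]^2 + g[[3]]^2
  }
  v <- sqrt(ssq)
  m <- max(v)
  if (m > 0) v <- v / m
  structure(list(values = v, channel = name, grid_shape = d,
                 voxel_to_world = channel$voxel_to_world),
            class = "certainty_map")
}

#' Certainty-weighted fusion of channel update fields
#'
#' Combines the per-channel symmetric update pairs into one pair by
#' voxelwise weighted averaging, each direction of the pair weighted by the
#' matching side's normalised certainty maps. Where all certainties vanish
#' the fused update is zero. Each fused component lies within the envelope
#' of the contributing channel updates (convexity).
#'
#' @param updates list of `update_field_pair` objects, one per channel.
#' @param certainties list of `certainty_map` for the fixed side (weights
#'   for the `toward_moving` direction).
#' @param certainties_moving optional list for the moving side; defaults to
#'   `certainties`.
#' @return list with fused `toward_moving` and `toward_fixed` 4D arrays.
#' @export
fuse_updates <- function(updates, certainties,
                         certainties_moving = certainties) {
  n <- length(updates)
  if (n == 0 || length(certainties) != n ||
      length(certainties_moving) != n)
    stop("updates and certainties must be non-empty lists of equal length")
  d <- updates[[1]]$grid_shape
  fuse_side <- function(side, certs) {
    wsum <- array(0, d)
    acc <- array(0, c(d, 3))
    for (i in seq_len(n)) {
      w <- certs[[i]]$values
      wsum <- wsum + w
      up <- updates[[i]][[side]]
      for (j in 1:3) acc[, , , j] <- acc[, , , j] + w * up[, , , j]
    }
    scale <- array(0, d)
    pos <- wsum > 0
    scale[pos] <- 1 / wsum[pos]
    for (j in 1:3) acc[, , , j] <- acc[, , , j] * scale
    acc
  }
  list(toward_moving = fuse_side("toward_moving", certainties),
       toward_fixed = fuse_side("toward_fixed", certainties_moving))
}

# ---- warping -------------------------------------------------------------

interp_at_world <- function(arr, src_affine, world) {
  vox <- world_to_voxel(world, src_affine)
  dm <- dim(arr)
  if (length(dm) == 3) dm <- c(dm, 1L)
  cpp_interp3(as.double(arr), as.integer(dm), vox)
}

# target world coordinates x + u(x) for every voxel of the warp grid
warp_targets <- function(warp) {
  xw <- grid_world_coords(warp$grid_shape, warp$voxel_to_world)
  xw + matrix(warp$vectors, ncol = 3)
}

# per-voxel rotation factors (n x 9, column-major) of the polar
# decomposition of the Jacobian of x -> x + u(x)
warp_rotations <- function(warp) {
  d <- warp$grid_shape
  J <- matrix(0, prod(d), 9)
  for (i in 1:3) {
    g <- gradient_world(warp$vectors[, , , i, drop = TRUE],
                        warp$voxel_to_world)
    for (j in 1:3) J[, i + 3 * (j - 1)] <- as.vector(g[[j]])
  }
  J[, c(1, 5, 9)] <- J[, c(1, 5, 9)] + 1   # add identity
  cpp_polar_rotations(J)
}

#' Warp a channel set through a displacement field
#'
#' Resamples every channel of `subject` onto the warp's reference grid at
#' the warped coordinates `x + u(x)` (pull-back). Scalar channels use
#' trilinear interpolation; masks are interpolated then thresholded at 0.5;
#' SH channels are interpolated per coefficient and reoriented voxelwise by
#' the rotational (polar) factor of the local warp Jacobian.
#'
#' @param subject a [channel_set].
#' @param warp a [displacement_field] on the target grid.
#' @param reorient_odf set `FALSE` to skip ODF reorientation (used
#'   internally at scalar-only registration levels).
#' @return a [channel_set] on the warp grid.
#' @export
warp_channelset <- function(subject, warp, reorient_odf = TRUE) {
  stopifnot(inherits(subject, "channel_set"),
            inherits(warp, "displacement_field"))
  if (!all(is.finite(warp$vectors))) stop("displacement field must be finite")
  tw <- warp_targets(warp)
  d <- warp$grid_shape
  rot <- NULL
  out <- subject$channels
  for (nm in names(out)) {
    ch <- out[[nm]]
    role <- attr(ch, "role")
    if (inherits(ch, "sh_image")) {
      vals <- interp_at_world(ch$coeffs, ch$voxel_to_world, tw)
      if (reorient_odf && ch$lmax >= 2) {
        if (is.null(rot)) rot <- warp_rotations(warp)
        mach <- sh_projection(ch$lmax)
        # rotate_sh with Q = R^T so directions transform with the local
        # linear part of the mapping
        rotT <- rot[, c(1, 4, 7, 2, 5, 8, 3, 6, 9)]
        vals <- cpp_sh_reorient(vals, rotT, ch$lmax, mach$directions,
                                mach$proj)
      }
      new <- sh_image(array(vals, c(d, ncol(vals))), ch$lmax,
                      warp$voxel_to_world)
    } else if (inherits(ch, "mask_image")) {
      vals <- interp_at_world(ch$values, ch$voxel_to_world, tw)
      new <- mask_image(array(as.numeric(vals >= 0.5), d),
                        warp$voxel_to_world)
    } else {
      vals <- interp_at_world(ch$values, ch$voxel_to_world, tw)
      new <- scalar_image(array(vals, d), warp$voxel_to_world)
    }
    attr(new, "role") <- role
    out[[nm]] <- new
  }
  channel_set(subject$subject_id, subject$age, out)
}

#' Invert a displacement field
#'
#' Fixed-point iteration for the inverse of `x -> x + u(x)`:
#' `v <- -u(x + v)` until the composition residual is small.
#'
#' @param warp a [displacement_field] with positive Jacobian determinant.
#' @param max_iter iteration cap.
#' @param tol_voxels target maximum composition residual, in voxels.
#' @return the inverse [displacement_field].
#' @export
invert_warp <- function(warp, max_iter = 50, tol_voxels = 0.05) {
  d <- warp$grid_shape
  sp <- min(voxel_spacing(warp))
  xw <- grid_world_coords(d, warp$voxel_to_world)
  u <- warp$vectors
  dm4 <- as.integer(c(d, 3))
  v <- matrix(0, nrow(xw), 3)
  for (it in seq_len(max_iter)) {
    unew <- -cpp_interp3(as.double(u), dm4,
                         world_to_voxel(xw + v, warp$voxel_to_world))
    delta <- max(abs(unew - v))
    v <- unew
    if (delta < 0.05 * sp) break
  }
  inv <- displacement_field(array(v, c(d, 3)), warp$voxel_to_world)
  # composition residual |u(x + v(x)) + v(x)| in voxels
  res <- cpp_interp3(as.double(u), dm4,
                     world_to_voxel(xw + v, warp$voxel_to_world)) + v
  resv <- max(sqrt(rowSums(res^2))) / sp
  if (resv > 10 * tol_voxels)
    warning(sprintf("warp inversion residual %.3f voxels", resv))
  attr(inv, "residual_voxels") <- resv
  inv
}

#' Jacobian determinant map of a deformation
#'
#' Per-voxel determinant of the Jacobian of the total mapping
#' `x -> x + u(x)` (central differences in world mm). Values above 1 mark
#' local expansion, below 1 contraction.
#'
#' @param warp a [displacement_field].
#' @return a [scalar_image] of determinants.
#' @export
jacobian_map <- function(warp) {
  d <- warp$grid_shape
  J <- vector("list", 9)  # J[[i + 3(j-1)]] = d(phi_i)/d(x_j)
  for (i in 1:3) {
    g <- gradient_world(warp$vectors[, , , i, drop = TRUE],
                        warp$voxel_to_world)
    for (j in 1:3) {
      J[[i + 3 * (j - 1)]] <- g[[j]] + as.numeric(i == j)
    }
  }
  det <- J[[1]] * (J[[5]] * J[[9]] - J[[8]] * J[[6]]) -
         J[[4]] * (J[[2]] * J[[9]] - J[[8]] * J[[3]]) +
         J[[7]] * (J[[2]] * J[[6]] - J[[5]] * J[[3]])
  scalar_image(array(det, d), warp$voxel_to_world)
}

#' Compose two displacement fields
#'
#' Returns the field of the composed mapping: apply `first`, then `second`,
#' i.e. `w(x) = first(x) + second(x + first(x))`.
#'
#' @param first,second displacement fields on the same grid.
#' @return composed [displacement_field].
#' @export
compose_warps <- function(first, second) {
  xw <- grid_world_coords(first$grid_shape, first$voxel_to_world)
  u1 <- matrix(first$vectors, ncol = 3)
  u2 <- cpp_interp3(as.double(second$vectors),
                    as.integer(c(second$grid_shape, 3)),
                    world_to_voxel(xw + u1, second$voxel_to_world))
  displacement_field(array(u1 + u2, c(first$grid_shape, 3)),
                     first$voxel_to_world)
}

zero_warp <- function(grid_shape, voxel_to_world) {
  displacement_field(array(0, c(grid_shape, 3)), voxel_to_world)
}

# resample a displacement field (mm vectors) onto another grid
resample_field <- function(field, grid_shape, voxel_to_world) {
  xw <- grid_world_coords(grid_shape, voxel_to_world)
  v <- cpp_interp3(as.double(field$vectors),
                   as.integer(c(field$grid_shape, 3)),
                   world_to_voxel(xw, field$voxel_to_world))
  displacement_field(array(v, c(grid_shape, 3)), voxel_to_world)
}

# ---- multi-resolution pyramid -------------------------------------------

level_grid <- function(grid_shape, voxel_to_world, scale) {
  new_shape <- pmax(round(grid_shape * scale), 4L)
  M <- voxel_to_world
  M[1:3, 1:3] <- M[1:3, 1:3] %*% diag(grid_shape / new_shape)
  list(grid_shape = as.integer(new_shape), voxel_to_world = M)
}

resample_array_to_grid <- function(arr, src_affine, grid) {
  dm <- dim(arr)
  nc <- if (length(dm) == 3) 1L else dm[4]
  xw <- grid_world_coords(grid$grid_shape, grid$voxel_to_world)
  v <- cpp_interp3(as.double(arr), as.integer(c(dm[1:3], nc)),
                   world_to_voxel(xw, src_affine))
  if (nc == 1) array(v, grid$grid_shape) else array(v, c(grid$grid_shape, nc))
}

# downsample a channel set to a pyramid level; masks stay soft (scalar role
# for the metric), ODFs are truncated to the level lmax (order 0 becomes a
# scalar channel holding the l = 0 coefficient)
channelset_at_level <- function(cs, scale, lmax_level) {
  grid <- level_grid(cs$channels[[1]]$grid_shape,
                     cs$channels[[1]]$voxel_to_world, scale)
  presmooth <- if (scale < 1) 0.5 * sqrt(1 / scale^2 - 1) else 0
  out <- list()
  for (nm in names(cs$channels)) {
    ch <- cs$channels[[nm]]
    role <- attr(ch, "role")
    if (inherits(ch, "sh_image")) {
      nc <- if (lmax_level >= 2) sh_n_coef(min(lmax_level, ch$lmax)) else 1L
      arr <- ch$coeffs[, , , seq_len(nc), drop = FALSE]
      if (presmooth > 0)
        for (k in seq_len(nc))
          arr[, , , k] <- smooth3(arr[, , , k, drop = TRUE], presmooth)
      v <- resample_array_to_grid(arr, ch$voxel_to_world, grid)
      if (nc == 1) {
        new <- scalar_image(array(v, grid$grid_shape), grid$voxel_to_world)
        attr(new, "role") <- "intensity"
      } else {
        new <- sh_image(v, min(lmax_level, ch$lmax), grid$voxel_to_world)
        attr(new, "role") <- "odf"
      }
    } else {
      arr <- if (presmooth > 0) smooth3(ch$values, presmooth) else ch$values
      v <- resample_array_to_grid(arr, ch$voxel_to_world, grid)
      new <- scalar_image(array(v, grid$grid_shape), grid$voxel_to_world)
      attr(new, "role") <- if (identical(role, "odf")) "intensity" else role
    }
    out[[nm]] <- new
  }
  list(channels = out, grid = grid)
}

# warp a plain channel list (level working set) by a field on its own grid
warp_channel_list <- function(channels, warp) {
  tw <- warp_targets(warp)
  d <- warp$grid_shape
  rot <- NULL
  out <- channels
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (inherits(ch, "sh_image")) {
      vals <- interp_at_world(ch$coeffs, ch$voxel_to_world, tw)
      if (is.null(rot)) rot <- warp_rotations(warp)
      mach <- sh_projection(ch$lmax)
      vals <- cpp_sh_reorient(vals, rot[, c(1, 4, 7, 2, 5, 8, 3, 6, 9)],
                              ch$lmax, mach$directions, mach$proj)
      new <- sh_image(array(vals, c(d, ncol(vals))), ch$lmax,
                      warp$voxel_to_world)
      attr(new, "role") <- "odf"
    } else {
      vals <- interp_at_world(ch$values, ch$voxel_to_world, tw)
      new <- scalar_image(array(vals, d), warp$voxel_to_world)
      attr(new, "role") <- attr(ch, "role")
    }
    out[[nm]] <- new
  }
  out
}

#' Symmetric multi-channel demons registration
#'
#' Registers two channel sets with a symmetric multi-resolution demons
#' scheme: both sides deform toward a midpoint with half-updates. At each
#' iteration, per-channel symmetric update pairs are computed (LNCC for
#' scalar and mask roles, LAC for ODF roles at levels with SH order >= 2),
#' fused by certainty-weighted averaging (certainties recomputed from the
#' currently warped channels), Gaussian-smoothed, normalised to
#' `step_size_voxels` maximum magnitude, composed into the running
#' half-warps, and the composed fields are smoothed again. The returned
#' full warps are the compositions through the midpoint.
#'
#' @param fixed,moving [channel_set]s with matching channel names and roles.
#' @param config a [registration_config].
#' @param mask optional [mask_image] on the fixed grid restricting the
#'   metric evaluation.
#' @return list with `warp_moving_to_fixed` and `warp_fixed_to_moving`
#'   [displacement_field]s on the fixed grid, the per-level iteration `log`
#'   (data frame of mean metric and update magnitudes), and the half-warps.
#' @export
register_multichannel <- function(fixed, moving, config = registration_config(),
                                  mask = NULL) {
  stopifnot(inherits(fixed, "channel_set"), inherits(moving, "channel_set"))
  if (!identical(names(fixed$channels), names(moving$channels)))
    stop("fixed and moving channel names do not match")
  for (nm in names(fixed$channels))
    if (!identical(attr(fixed$channels[[nm]], "role"),
                   attr(moving$channels[[nm]], "role")))
      stop("channel role mismatch for '", nm, "'")
  ref <- fixed$channels[[1]]
  uA <- NULL; uB <- NULL
  gain <- NULL
  log_rows <- list()
  for (lev in seq_along(config$level_scales)) {
    scale <- config$level_scales[lev]
    lmax_l <- config$lmax_schedule[lev]
    fl <- channelset_at_level(fixed, scale, lmax_l)
    ml <- channelset_at_level(moving, scale, lmax_l)
    grid <- fl$grid
    sp <- sqrt(colSums(grid$voxel_to_world[1:3, 1:3]^2))
    mask_l <- if (is.null(mask)) NULL else {
      mv <- resample_array_to_grid(mask$values, mask$voxel_to_world, grid)
      mask_image(array(as.numeric(mv >= 0.5), grid$grid_shape),
                 grid$voxel_to_world)
    }
    uA <- if (is.null(uA)) zero_warp(grid$grid_shape, grid$voxel_to_world)
          else resample_field(uA, grid$grid_shape, grid$voxel_to_world)
    uB <- if (is.null(uB)) zero_warp(grid$grid_shape, grid$voxel_to_world)
          else resample_field(uB, grid$grid_shape, grid$voxel_to_world)
    prev_mag <- Inf; n_increase <- 0
    best_met <- -Inf; stall <- 0
    for (it in seq_len(config$max_iterations_per_level[lev])) {
      wf <- warp_channel_list(fl$channels, uA)
      wm <- warp_channel_list(ml$channels, uB)
      updates <- list(); certA <- list(); certB <- list(); mets <- c()
      for (nm in names(wf)) {
        chf <- wf[[nm]]; chm <- wm[[nm]]
        pair <- if (inherits(chf, "sh_image"))
          lac_update_fields(chf, chm, config$neighborhood_radius, mask_l)
        else
          lncc_update_fields(chf, chm, config$neighborhood_radius, mask_l)
        updates[[nm]] <- pair
        certA[[nm]] <- certainty_map(chf, nm)
        certB[[nm]] <- certainty_map(chm, nm)
        cv <- pair$correlation$values
        mets <- c(mets, mean(cv[pair$correlation$defined]))
      }
      fused <- fuse_updates(updates, certA, certB)
      lamA <- smooth_vec4(fused$toward_moving, config$sigma_update_voxels)
      lamB <- smooth_vec4(fused$toward_fixed, config$sigma_update_voxels)
      # step-size rule: the metric fixes the update only up to a constant
      # factor, so the gain is calibrated once, at the first iteration of
      # the coarsest level (where misalignment is largest), so that the
      # maximum update magnitude equals step_size_voxels; later iterations
      # reuse that gain (letting the forces decay naturally as the pair
      # aligns) and are capped at the step size
      magA <- sqrt(matrix(lamA, ncol = 3)^2 %*% rep(1, 3)) / min(sp)
      magB <- sqrt(matrix(lamB, ncol = 3)^2 %*% rep(1, 3)) / min(sp)
      mx <- max(magA, magB)
      if (is.null(gain)) gain <- if (mx > 0) config$step_size_voxels / mx else 0
      s <- if (mx * gain > config$step_size_voxels)
        config$step_size_voxels / mx else gain
      lamA <- lamA * s; lamB <- lamB * s
      mean_mag <- mean(c(magA, magB)) * s
      mx <- mx * s
      log_rows[[length(log_rows) + 1]] <-
        data.frame(level = lev, iteration = it,
                   mean_metric = mean(mets), mean_update_voxels = mean_mag)
      if (mx == 0 || mean_mag < config$convergence_tolerance) break
      # plateau detection: leave the level once the mean metric has stopped
      # improving, before composing further jitter into the field
      if (mean(mets) > best_met + 1e-5) { best_met <- mean(mets); stall <- 0 }
      else stall <- stall + 1
      if (stall >= 3) break
      if (mean_mag > prev_mag) n_increase <- n_increase + 1 else n_increase <- 0
      if (n_increase >= 10)
        stop("registration diverging: mean update magnitude increased for ",
             "10 consecutive iterations")
      prev_mag <- mean_mag
      dA <- displacement_field(lamA, grid$voxel_to_world)
      dB <- displacement_field(lamB, grid$voxel_to_world)
      uA <- compose_warps(dA, uA)
      uB <- compose_warps(dB, uB)
      uA$vectors <- smooth_vec4(uA$vectors, config$sigma_displacement_voxels)
      uB$vectors <- smooth_vec4(uB$vectors, config$sigma_displacement_voxels)
    }
  }
  # back to the full-resolution fixed grid
  uA <- resample_field(uA, ref$grid_shape, ref$voxel_to_world)
  uB <- resample_field(uB, ref$grid_shape, ref$voxel_to_world)
  forward <- compose_warps(invert_warp(uA), uB)
  reverse <- compose_warps(invert_warp(uB), uA)
  list(warp_moving_to_fixed = forward, warp_fixed_to_moving = reverse,
       half_warp_fixed = uA, half_warp_moving = uB,
       log = do.call(rbind, log_rows), config = config)
}

#' Affine pre-alignment by global NCC
#'
#' Estimates a 12-parameter affine (translation, rotation, log-scale,
#' shear, applied about the fixed-volume centre) maximising the global
#' normalised cross-correlation of a driver scalar channel, by staged
#' multi-resolution Nelder-Mead optimisation. Deterministic.
#'
#' @param fixed,moving [channel_set]s.
#' @param driver_channel name of a scalar channel present in both.
#' @param scales resolution levels used, coarse to fine.
#' @param maxit optimiser iteration cap per stage.
#' @return an [affine_transform] mapping fixed world coordinates to moving
#'   world coordinates.
#' @export
affine_register <- function(fixed, moving, driver_channel,
                            scales = c(0.5, 1.0), maxit = 400) {
  chf <- fixed$channels[[driver_channel]]
  chm <- moving$channels[[driver_channel]]
  if (is.null(chf) || is.null(chm) || inherits(chf, "sh_image"))
    stop("driver channel must be a scalar channel present in both sets")
  centre <- grid_centre_world(chf)
  par <- rep(0, 12)
  for (sc in scales) {
    fl <- channelset_at_level(channel_set("f", fixed$age,
                                          fixed$channels[driver_channel]),
                              sc, 0)
    ml <- channelset_at_level(channel_set("m", moving$age,
                                          moving$channels[driver_channel]),
                              sc, 0)
    fv <- fl$channels[[1]]$values
    xw <- grid_world_coords(fl$grid$grid_shape, fl$grid$voxel_to_world)
    marr <- ml$channels[[1]]$values
    maff <- ml$grid$voxel_to_world
    neg_ncc <- function(p) {
      A <- affine_from_params(p, centre)
      tw <- sweep(xw %*% t(A[1:3, 1:3]), 2, A[1:3, 4], "+")
      mv <- interp_at_world(marr, maff, tw)
      s <- stats::cor(as.vector(fv), as.vector(mv))
      if (!is.finite(s)) 1 else -s
    }
    # stage 0 (coarsest level only): grid search over translations, which
    # makes the optimisation robust to periodic structure in the images
    if (sc == scales[1]) {
      ext <- 0.2 * max(chf$grid_shape * voxel_spacing(chf))
      steps <- seq(-ext, ext, length.out = 7)
      best <- neg_ncc(par)
      for (tx in steps) for (ty in steps) for (tz in steps) {
        v <- neg_ncc(c(tx, ty, tz, par[4:12]))
        if (v < best) { best <- v; par[1:3] <- c(tx, ty, tz) }
      }
    }
    # stage 1: translation only; stage 2: all 12 parameters
    o1 <- optim(par[1:3], function(t3) neg_ncc(c(t3, par[4:12])),
                method = "Nelder-Mead", control = list(maxit = maxit))
    par[1:3] <- o1$par
    o2 <- optim(par, neg_ncc, method = "Nelder-Mead",
                control = list(maxit = 3 * maxit,
                               reltol = 1e-10,
                               parscale = c(rep(1, 3), rep(0.05, 9))))
    par <- o2$par
  }
  A <- affine_from_params(par, centre)
  # diagnostic: fraction of fixed voxels landing inside the moving volume
  xw <- grid_world_coords(chf$grid_shape, chf$voxel_to_world)
  tw <- sweep(xw %*% t(A[1:3, 1:3]), 2, A[1:3, 4], "+")
  vox <- world_to_voxel(tw, chm$voxel_to_world)
  inside <- rowSums(vox >= 0 & vox <= matrix(chm$grid_shape - 1,
                                             nrow(vox), 3, byrow = TRUE)) == 3
  if (mean(inside) < 0.05)
    stop(sprintf(paste0("affine registration failed: only %.1f%% of the ",
                        "fixed volume overlaps the moving volume"),
                 100 * mean(inside)))
  affine_transform(A)
}

grid_centre_world <- function(img) {
  c(img$voxel_to_world %*% c((img$grid_shape - 1) / 2, 1))[1:3]
}

# p = (t1..3, rotations r1..3 [rad], log-scales s1..3, shears h1..3)
affine_from_params <- function(p, centre) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  S <- diag(exp(p[7:9]))
  H <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  L <- Rz %*% Ry %*% Rx %*% S %*% H
  M <- diag(4)
  M[1:3, 1:3] <- L
  M[1:3, 4] <- centre - L %*% centre + p[1:3]
  M
}

#' Apply an affine transform to a channel set
#'
#' Resamples all channels at `A x` (pull-back through the affine), with SH
#' channels reoriented by the rotational polar factor of the linear part.
#'
#' @param subject a [channel_set].
#' @param affine an [affine_transform] mapping target world coordinates into
#'   the subject's world coordinates.
#' @param grid optional list with `grid_shape`, `voxel_to_world` of the
#'   output grid; defaults to the subject's own grid.
#' @return resampled [channel_set].
#' @export
apply_affine_channelset <- function(subject, affine, grid = NULL) {
  ch1 <- subject$channels[[1]]
  if (is.null(grid))
    grid <- list(grid_shape = ch1$grid_shape,
                 voxel_to_world = ch1$voxel_to_world)
  xw <- grid_world_coords(grid$grid_shape, grid$voxel_to_world)
  A <- affine$matrix
  tw <- sweep(xw %*% t(A[1:3, 1:3]), 2, A[1:3, 4], "+")
  u <- tw - xw
  w <- displacement_field(array(u, c(grid$grid_shape, 3)),
                          grid$voxel_to_world)
  warp_channelset(subject, w)
}
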