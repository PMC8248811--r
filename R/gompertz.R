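#' Voxelwise Gompertz growth-curve fitting
#'
#' Fits `G(t) = (alpha - delta) exp(-exp(-gamma (tau - t))) + delta` to each
#' voxel's template series across age windows by Levenberg-Marquardt least
#' squares, together with an ordinary linear fit for comparison. `alpha` is
#' the early asymptote, `delta` the mature asymptote, `gamma` the growth
#' rate (per week, bounded to [-5, 5]) and `tau` the peak-growth time
#' (weeks, bounded to the window range widened by 4 weeks on both sides).
#'
#' Initialisation: `alpha`/`delta` from the first/last thirds' means, `tau`
#' mid-range, `gamma` from the range-normalised central slope. Voxels where
#' the optimiser fails fall back to the linear fit, with `gamma` set to
#' `sign(slope) * 1e-3` and `converged = FALSE`. R-squared is
#' `1 - SS_res/SS_tot`, defined as 0 for zero-variance series.
#'
#' @param window_centers numeric times (weeks) of the series, length >= 5.
#' @param series numeric matrix (n_series x n_times), or a list of
#'   [scalar_image] objects (one per window).
#' @param mask optional [mask_image] (image input only): voxels outside it
#'   are not fitted.
#' @return a `gompertz_fit` object: per-voxel `alpha`, `delta`, `gamma`,
#'   `tau`, `r_squared`, `linear_slope`, `linear_intercept`,
#'   `linear_r_squared`, `converged`; plus grid information for image input.
#' @export
fit_gompertz_maps <- function(window_centers, series, mask = NULL) {
  if (is.list(series) && inherits(series[[1]], "scalar_image")) {
    d <- series[[1]]$grid_shape
    Y <- vapply(series, function(im) as.double(im$values),
                numeric(prod(d)))
    keep <- if (is.null(mask)) rep(TRUE, nrow(Y)) else as.vector(mask$values > 0)
    fit <- fit_gompertz_series(window_centers, Y, active = keep)
    fit$grid_shape <- d
    fit$voxel_to_world <- series[[1]]$voxel_to_world
    for (f in c("alpha", "delta", "gamma", "tau", "r_squared",
                "linear_slope", "linear_intercept", "linear_r_squared",
                "converged"))
      fit[[f]] <- array(fit[[f]], d)
    fit
  } else {
    fit_gompertz_series(window_centers, as.matrix(series))
  }
}

# core engine on an n x T matrix; `active` marks rows to fit
fit_gompertz_series <- function(tt, Y, active = rep(TRUE, nrow(Y)),
                                gamma_bound = 5, tau_pad = 4,
                                gamma_min = 1e-3) {
  nT <- length(tt)
  if (nT < 5) stop("Gompertz fitting needs at least 5 time points")
  if (ncol(Y) != nT) stop("series width does not match window count")
  n <- nrow(Y)
  tbar <- mean(tt)
  # vectorised linear fits
  tc <- tt - tbar
  stt <- sum(tc^2)
  mu <- rowMeans(Y)
  slope <- as.vector(Y %*% tc) / stt
  intercept <- mu - slope * tbar
  ss_tot <- rowSums((Y - mu)^2)
  res_lin <- Y - outer(slope, tc) - mu
  ss_lin <- rowSums(res_lin^2)
  lin_r2 <- ifelse(ss_tot > 0, 1 - ss_lin / ss_tot, 0)
  alpha <- mu; delta <- mu
  gamma <- numeric(n); tau <- rep(tbar, n)
  r2 <- numeric(n); converged <- rep(TRUE, n)
  lower <- c(-Inf, -Inf, -gamma_bound, min(tt) - tau_pad)
  upper <- c(Inf, Inf, gamma_bound, max(tt) + tau_pad)
  third <- max(1, floor(nT / 3))
  i_first <- seq_len(third); i_last <- seq(nT - third + 1, nT)
  mid <- c(min(tt) + max(tt)) / 2
  resid_fn <- function(p, y) gompertz(tt, p[1], p[2], p[3], p[4]) - y
  jac_fn <- function(p, y) {
    e_in <- exp(-p[3] * (p[4] - tt))
    e_out <- exp(-e_in)
    dal <- e_out
    dde <- 1 - e_out
    com <- (p[1] - p[2]) * e_out * e_in
    dga <- com * (p[4] - tt)
    dta <- com * p[3]
    cbind(dal, dde, dga, dta)
  }
  fit_rows <- which(active & ss_tot > 0)
  for (i in fit_rows) {
    y <- Y[i, ]
    a0 <- mean(y[i_first]); d0 <- mean(y[i_last])
    g0 <- if (abs(d0 - a0) > 1e-12)
      max(-gamma_bound, min(gamma_bound, exp(1) * slope[i] / (d0 - a0)))
    else sign(slope[i] + 1e-300) * 0.5
    if (g0 == 0 || !is.finite(g0)) g0 <- 0.5
    # the form is mirror-symmetric in (alpha <-> delta, gamma -> -gamma):
    # start from both orientations and keep the better optimum (the second
    # start is skipped when the first already fits essentially exactly)
    p <- NULL; ss <- Inf
    for (p0 in list(c(a0, d0, g0, mid), c(d0, a0, -g0, mid))) {
      ans <- tryCatch(
        suppressWarnings(
          minpack.lm::nls.lm(p0, lower, upper, resid_fn, jac_fn, y = y,
                             control = minpack.lm::nls.lm.control(maxiter = 100))),
        error = function(e) NULL)
      if (!is.null(ans) && ans$info %in% 1:4 && all(is.finite(ans$par))) {
        ss_c <- sum(resid_fn(ans$par, y)^2)
        if (ss_c < ss) { ss <- ss_c; p <- ans$par }
      }
      if (ss < 1e-14 * ss_tot[i]) break
    }
    ok <- !is.null(p)
    if (ok) {
      alpha[i] <- p[1]; delta[i] <- p[2]; gamma[i] <- p[3]; tau[i] <- p[4]
      r2[i] <- 1 - ss / ss_tot[i]
    } else {
      alpha[i] <- intercept[i] + slope[i] * min(tt)
      delta[i] <- intercept[i] + slope[i] * max(tt)
      gamma[i] <- sign(slope[i] + 1e-300) * gamma_min
      tau[i] <- mid
      r2[i] <- lin_r2[i]
      converged[i] <- FALSE
    }
  }
  structure(list(t = tt, alpha = alpha, delta = delta, gamma = gamma,
                 tau = tau, r_squared = r2, linear_slope = slope,
                 linear_intercept = intercept, linear_r_squared = lin_r2,
                 converged = converged, active = active,
                 t_range = range(tt)),
            class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  act <- x$active & is.finite(x$r_squared)
  cat(sprintf(paste0("<gompertz_fit> %d series over t = [%.1f, %.1f] weeks",
                     " (%d fitted, %.1f%% converged)\n"),
              length(x$alpha), x$t_range[1], x$t_range[2], sum(act),
              100 * mean(x$converged[act])))
  cat(sprintf("  median R2: Gompertz %.3f, linear %.3f\n",
              median(x$r_squared[act]), median(x$linear_r_squared[act])))
  invisible(x)
}

#' Evaluate a fitted Gompertz model
#'
#' @param object a `gompertz_fit`.
#' @param t time (weeks) at which to evaluate the fitted curves.
#' @param ... unused.
#' @return array (or vector) of curve values; for fits made from images,
#'   a [scalar_image].
#' @export
predict.gompertz_fit <- function(object, t, ...) {
  v <- gompertz(t, as.vector(object$alpha), as.vector(object$delta),
                as.vector(object$gamma), as.vector(object$tau))
  if (!is.null(object$grid_shape))
    scalar_image(array(v, object$grid_shape), object$voxel_to_world)
  else v
}

#' Fit growth curves to unbiasing transforms
#'
#' Fits the Gompertz form independently to each displacement component of
#' the per-window average inverse warps (per voxel) and to each scale/shear
#' entry of the per-window average inverse affines.
#'
#' @param window_centers times of the windows used (weeks).
#' @param transforms the `unbias` element of a stage-2
#'   [build_atlas_stage] result (lists `warp` and `affine` keyed by window).
#' @return list with `warp` (list of 3 `gompertz_fit`, one per component),
#'   `affine` (`gompertz_fit` over the 9 entries of the linear part), grid
#'   information and the window times.
#' @export
fit_gompertz_warps <- function(window_centers, transforms) {
  keys <- names(transforms$warp)
  if (length(keys) < 5) stop("Gompertz fitting needs at least 5 windows")
  tt <- window_centers
  if (length(tt) != length(keys))
    stop("window_centers must match the transform windows")
  w1 <- transforms$warp[[1]]
  d <- w1$grid_shape
  comp_fits <- lapply(1:3, function(j) {
    Y <- vapply(keys, function(k)
      as.double(transforms$warp[[k]]$vectors[, , , j]), numeric(prod(d)))
    f <- fit_gompertz_series(tt, Y)
    f$grid_shape <- d; f$voxel_to_world <- w1$voxel_to_world
    f
  })
  Ya <- vapply(keys, function(k)
    as.double(transforms$affine[[k]]$matrix[1:3, 1:3]), numeric(9))
  aff_fit <- fit_gompertz_series(tt, Ya)
  list(warp = comp_fits, affine = aff_fit, grid_shape = d,
       voxel_to_world = w1$voxel_to_world, t = tt)
}

#' Assemble and evaluate a 4D atlas
#'
#' `atlas_4d()` bundles per-channel template curve fits with the warp and
#' affine curve fits; `evaluate_atlas()` evaluates the channel curves at an
#' age `t`, then unbiases them by resampling through the fitted average
#' inverse warp `W^-1(t)` followed by the fitted scale/shear affine
#' `A^-1(t)` (SH channels are reoriented), and returns the unbiased maps
#' with the Jacobian determinant map of `W^-1(t)`.
#'
#' @param channel_fits named list of `gompertz_fit` objects from
#'   [fit_gompertz_maps] (image form).
#' @param transform_fits result of [fit_gompertz_warps] (or `NULL` for a
#'   purely biased atlas).
#' @param t_range valid evaluation range in weeks.
#' @return `atlas_4d()`: an `atlas_4d` object.
#' @export
atlas_4d <- function(channel_fits, transform_fits = NULL,
                     t_range = c(37, 44)) {
  stopifnot(length(channel_fits) >= 1,
            !is.null(channel_fits[[1]]$grid_shape))
  structure(list(channel_fits = channel_fits,
                 transform_fits = transform_fits, t_range = t_range,
                 grid_shape = channel_fits[[1]]$grid_shape,
                 voxel_to_world = channel_fits[[1]]$voxel_to_world),
            class = "atlas_4d")
}

#' @rdname atlas_4d
#' @param atlas an `atlas_4d`.
#' @param t evaluation age (weeks), inside `t_range`.
#' @param channels channel names to evaluate (default all).
#' @param unbias apply the fitted unbiasing transforms when available.
#' @return `evaluate_atlas()`: list with `maps` (named list of
#'   [scalar_image]), `warp` (the evaluated `W^-1(t)` or `NULL`), `affine`,
#'   and `jacobian` ([scalar_image] of `W^-1(t)`, or `NULL`).
#' @export
evaluate_atlas <- function(atlas, t, channels = names(atlas$channel_fits),
                           unbias = TRUE) {
  stopifnot(inherits(atlas, "atlas_4d"))
  if (t < atlas$t_range[1] || t > atlas$t_range[2])
    stop(sprintf("t = %.2f outside the atlas range [%.1f, %.1f]",
                 t, atlas$t_range[1], atlas$t_range[2]))
  maps <- lapply(atlas$channel_fits[channels], predict, t = t)
  warp <- NULL; aff <- NULL; jac <- NULL
  if (unbias && !is.null(atlas$transform_fits)) {
    tf <- atlas$transform_fits
    u <- array(0, c(tf$grid_shape, 3))
    for (j in 1:3)
      u[, , , j] <- predict(tf$warp[[j]], t)$values
    warp <- displacement_field(u, tf$voxel_to_world)
    L <- matrix(predict(tf$affine, t), 3, 3)
    M <- diag(4); M[1:3, 1:3] <- L
    aff <- affine_transform(M, flags = c("scale", "shear"))
    cs <- channel_set("atlas", max(atlas$t_range[1], min(t, atlas$t_range[2])),
                      maps)
    cs <- warp_channelset(cs, warp)
    cs <- apply_affine_channelset(cs, aff)
    maps <- cs$channels
    jac <- jacobian_map(warp)
  }
  list(maps = maps, warp = warp, affine = aff, jacobian = jac, t = t)
}

#' Growth-peak offset map
#'
#' Flags voxels whose fitted peak-growth time deviates from a reference
#' time point by at least `threshold` weeks — an indicator of locally
#' earlier or later maturation.
#'
#' @param params a `gompertz_fit` with grid information.
#' @param reference_t reference time (weeks).
#' @param threshold minimum |tau - reference| (weeks).
#' @return a [mask_image].
#' @export
growth_peak_offset_map <- function(params, reference_t = 40.5,
                                   threshold = 0.2) {
  stopifnot(!is.null(params$grid_shape))
  m <- (abs(params$tau - reference_t) >= threshold) * 1.0
  m[!params$active] <- 0
  mask_image(array(m, params$grid_shape), params$voxel_to_world)
}
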