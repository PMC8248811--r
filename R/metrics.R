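#' Local correlation similarity metrics
#'
#' Two windowed correlation metrics drive the multi-channel registration:
#' local normalized cross-correlation (LNCC) for scalar/mask channels and
#' local angular correlation (LAC) for ODF channels. LAC is the Pearson-type
#' correlation of the degree `l >= 2` SH coefficients accumulated over a
#' cubic spatial neighbourhood; each coefficient image is first centred on
#' its local neighbourhood mean, so the `l = 0` term cannot contribute and
#' the metric is insensitive to global amplitude scaling.
#'
#' The neighbourhood is the cube of half-width `radius` voxels, truncated at
#' the grid border, implemented by exact separable box sums. Voxels where
#' either image's local centred sum of squares falls below
#' `1e-6 x` its within-mask mean are flagged undefined (`NA` in `values`)
#' and produce zero update fields.
#'
#' @param fixed,moving two [sh_image] objects on a shared grid with equal
#'   `lmax` (for `local_angular_correlation`) or two [scalar_image] objects
#'   (for `lncc`).
#' @param radius neighbourhood half-width in voxels (>= 1).
#' @param mask optional [mask_image]; metric and updates are evaluated inside
#'   the mask only.
#' @return a `correlation_map`: list with `values` (3D array, `NA` where
#'   undefined), `defined` (logical array), `grid_shape`, `voxel_to_world`.
#' @export
local_angular_correlation <- function(fixed, moving, radius = 3,
                                      mask = NULL) {
  check_sh_pair(fixed, moving)
  core <- local_corr_core(sh_l2plus(fixed), sh_l2plus(moving), radius, mask,
                          fixed$voxel_to_world, updates = FALSE)
  core$corr
}

#' @rdname local_angular_correlation
#' @return `lac_update_fields()` and `lncc_update_fields()` return an
#'   `update_field_pair`: list with `toward_fixed` and `toward_moving`
#'   (4D `(nx,ny,nz,3)` world-mm update vectors), zero where the correlation
#'   is undefined, plus the `correlation` map.
#' @export
lac_update_fields <- function(fixed, moving, radius = 3, mask = NULL) {
  check_sh_pair(fixed, moving)
  core <- local_corr_core(sh_l2plus(fixed), sh_l2plus(moving), radius, mask,
                          fixed$voxel_to_world, updates = TRUE)
  core$pair
}

#' @rdname local_angular_correlation
#' @export
lncc <- function(fixed, moving, radius = 3, mask = NULL) {
  check_scalar_pair(fixed, moving)
  core <- local_corr_core(list(fixed$values), list(moving$values), radius,
                          mask, fixed$voxel_to_world, updates = FALSE)
  core$corr
}

#' @rdname local_angular_correlation
#' @export
lncc_update_fields <- function(fixed, moving, radius = 3, mask = NULL) {
  check_scalar_pair(fixed, moving)
  core <- local_corr_core(list(fixed$values), list(moving$values), radius,
                          mask, fixed$voxel_to_world, updates = TRUE)
  core$pair
}

check_sh_pair <- function(fixed, moving) {
  stopifnot(inherits(fixed, "sh_image"), inherits(moving, "sh_image"))
  if (fixed$lmax != moving$lmax)
    stop("SH order mismatch between channels: ", fixed$lmax, " vs ",
         moving$lmax)
  check_same_grid(fixed, moving)
}

check_scalar_pair <- function(fixed, moving) {
  stopifnot(inherits(fixed, "scalar_image"), inherits(moving, "scalar_image"))
  check_same_grid(fixed, moving)
}

check_same_grid <- function(a, b) {
  if (!all(a$grid_shape == b$grid_shape) ||
      max(abs(a$voxel_to_world - b$voxel_to_world)) > 1e-6)
    stop("images do not share a grid")
  invisible(TRUE)
}

# list of 3D coefficient arrays, degrees l >= 2 only
sh_l2plus <- function(img) {
  deg <- sh_degrees(img$lmax)
  keep <- which(deg >= 2)
  if (length(keep) == 0)
    stop("LAC requires lmax >= 2 (no l >= 2 coefficients present)")
  lapply(keep, function(k) img$coeffs[, , , k, drop = TRUE])
}

box3 <- function(arr, radius) {
  cpp_box_sum(as.double(arr), as.integer(dim(arr)), as.integer(radius))
}

# central-difference spatial gradient in world mm; returns list of 3 arrays
gradient_world <- function(arr, voxel_to_world) {
  d <- dim(arr)
  gi <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    hi <- pmin(seq_len(n) + 1, n)
    lo <- pmax(seq_len(n) - 1, 1)
    den <- hi - lo   # 1 at borders (one-sided), 2 interior
    if (ax == 1) {
      g <- (arr[hi, , , drop = FALSE] - arr[lo, , , drop = FALSE]) /
        array(den, dim = d)
    } else if (ax == 2) {
      g <- (arr[, hi, , drop = FALSE] - arr[, lo, , drop = FALSE]) /
        aperm(array(den, dim = d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      g <- (arr[, , hi, drop = FALSE] - arr[, , lo, drop = FALSE]) /
        aperm(array(den, dim = d[c(3, 1, 2)]), c(2, 3, 1))
    }
    gi[[ax]] <- g
  }
  Minv <- solve(voxel_to_world[1:3, 1:3])
  out <- vector("list", 3)
  for (j in 1:3)
    out[[j]] <- gi[[1]] * Minv[1, j] + gi[[2]] * Minv[2, j] +
      gi[[3]] * Minv[3, j]
  out
}

# shared engine for LNCC/LAC correlation maps and their symmetric demons
# update fields; la/lb are lists of per-coefficient 3D arrays
local_corr_core <- function(la, lb, radius, mask, voxel_to_world, updates) {
  stopifnot(radius >= 1)
  d <- dim(la[[1]])
  nimg <- box3(array(1, d), radius)
  inmask <- if (is.null(mask)) array(TRUE, d) else mask$values > 0
  if (!is.null(mask) && !all(dim(mask$values) == d))
    stop("mask does not share the image grid")
  num <- array(0, d); da <- array(0, d); db <- array(0, d)
  Sa <- vector("list", length(la)); Sb <- Sa
  for (k in seq_along(la)) {
    a <- la[[k]]; b <- lb[[k]]
    Sa[[k]] <- box3(a, radius); Sb[[k]] <- box3(b, radius)
    num <- num + box3(a * b, radius) - Sa[[k]] * Sb[[k]] / nimg
    da <- da + box3(a * a, radius) - Sa[[k]]^2 / nimg
    db <- db + box3(b * b, radius) - Sb[[k]]^2 / nimg
  }
  da <- pmax(da, 0); db <- pmax(db, 0)
  eps_a <- 1e-6 * mean(da[inmask]); eps_b <- 1e-6 * mean(db[inmask])
  defined <- inmask & (da > eps_a) & (db > eps_b)
  vals <- array(NA_real_, d)
  vals[defined] <- (num / sqrt(da * db))[defined]
  corr <- structure(list(values = vals, defined = defined, grid_shape = d,
                         voxel_to_world = voxel_to_world),
                    class = "correlation_map")
  if (!updates) return(list(corr = corr))
  # Eq.-style symmetric pair: common factor 2<A,B>/(<A><B>), per-side
  # residual contracted against the gradient of the locally-centred images
  fac <- array(0, d)
  fac[defined] <- (2 * num / (da * db))[defined]
  ra <- array(0, d); ra[defined] <- (num / da)[defined]
  rb <- array(0, d); rb[defined] <- (num / db)[defined]
  upA <- array(0, c(d, 3)); upB <- array(0, c(d, 3))
  for (k in seq_along(la)) {
    ca <- la[[k]] - Sa[[k]] / nimg      # locally-mean-centred images
    cb <- lb[[k]] - Sb[[k]] / nimg
    ga <- gradient_world(ca, voxel_to_world)
    gb <- gradient_world(cb, voxel_to_world)
    wa <- cb - ra * ca                  # B - (<A,B>/<A>) A
    wb <- ca - rb * cb
    for (j in 1:3) {
      upA[, , , j] <- upA[, , , j] + wa * ga[[j]]
      upB[, , , j] <- upB[, , , j] + wb * gb[[j]]
    }
  }
  for (j in 1:3) {
    upA[, , , j] <- upA[, , , j] * fac
    upB[, , , j] <- upB[, , , j] * fac
  }
  pair <- structure(list(toward_moving = upA, toward_fixed = upB,
                         grid_shape = d, voxel_to_world = voxel_to_world,
                         correlation = corr),
                    class = "update_field_pair")
  list(corr = corr, pair = pair)
}

#' @export
print.correlation_map <- function(x, ...) {
  v <- x$values[x$defined]
  cat(sprintf("<correlation_map> %s, defined %.1f%%, mean %.4f\n",
              paste(x$grid_shape, collapse = "x"),
              100 * mean(x$defined), if (length(v)) mean(v) else NA))
  invisible(x)
}
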