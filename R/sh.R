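#' Real even-order spherical harmonics
#'
#' The package represents orientation distribution functions (ODFs) as
#' band-limited expansions in a real, even-order spherical-harmonic (SH)
#' basis. The convention, used consistently everywhere in the package, is:
#'
#' * fully normalised real SH, orthonormal under the uniform measure on the
#'   sphere (so the `l = 0` basis function is the constant `1/sqrt(4*pi)`);
#' * no Condon-Shortley phase;
#' * only even degrees `l = 0, 2, ..., lmax` (antipodally symmetric
#'   functions), giving `(lmax+1)(lmax+2)/2` coefficients per voxel;
#' * coefficient order is `(l, m)` lexicographic with `l` ascending and
#'   `m = -l, ..., l`; negative `m` carries the `sin(|m| phi)` term, positive
#'   `m` the `cos(m phi)` term. The 0-based column index of `(l, m)` is
#'   `l(l-1)/2 + l + m`.
#'
#' @param directions numeric matrix with one unit 3-vector per row.
#' @param lmax even non-negative integer, maximum SH degree.
#' @return `real_sh_basis()` returns an `nrow(directions) x n_coef` matrix of
#'   basis function values.
#' @examples
#' B <- real_sh_basis(rbind(c(0, 0, 1)), 0)
#' all.equal(B[1, 1], 1 / sqrt(4 * pi))
#' @export
real_sh_basis <- function(directions, lmax) {
  directions <- rbind(directions)
  check_lmax(lmax)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-8))
    stop("all directions must be unit-norm (within 1e-8)")
  cpp_sh_basis(directions, as.integer(lmax))
}

check_lmax <- function(lmax) {
  if (length(lmax) != 1 || lmax < 0 || lmax %% 2 != 0)
    stop("lmax must be a single even non-negative integer, got ", lmax)
  invisible(as.integer(lmax))
}

#' @rdname real_sh_basis
#' @return `sh_n_coef()` returns the number of even-degree coefficients
#'   `(lmax+1)(lmax+2)/2`.
#' @export
sh_n_coef <- function(lmax) {
  check_lmax(lmax)
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

# infer lmax from a coefficient count; NA when no even lmax matches
sh_lmax_from_n <- function(n) {
  for (l in seq(0, 40, by = 2)) if (sh_n_coef(l) == n) return(l)
  NA_integer_
}

# degree of each coefficient column, in package order
sh_degrees <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}

#' Spherical quadrature and direction sets
#'
#' `sh_quadrature()` builds a product quadrature (Gauss-Legendre in
#' `cos(theta)` times uniform in `phi`) exact for spherical polynomials up to
#' the requested degree; it is used to build SH projections and band-wise
#' rotation operators. `sh_directions()` returns a fixed, deterministic,
#' near-uniform antipodally symmetric direction set (sizes 60, 300 and 724
#' are the package's standard sets) built from a Fibonacci hemisphere plus
#' antipodes.
#'
#' @param degree maximum polynomial degree the rule must integrate exactly.
#' @return `sh_quadrature()`: list with `directions` (q x 3) and `weights`
#'   (summing to `4*pi`).
#' @export
sh_quadrature <- function(degree) {
  n_t <- ceiling((degree + 1) / 2)
  n_p <- degree + 1
  gl <- pracma::gaussLegendre(n_t, -1, 1)
  phi <- 2 * pi * (seq_len(n_p) - 1) / n_p
  ct <- rep(gl$x, each = n_p)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, n_t)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = n_p) * (2 * pi / n_p)
  list(directions = dirs, weights = w)
}

#' @rdname sh_quadrature
#' @param n even set size (number of directions including antipodes).
#' @return `sh_directions()`: n x 3 matrix of unit vectors closed under
#'   antipodal inversion.
#' @export
sh_directions <- function(n = 300) {
  if (n %% 2 != 0) stop("direction set size must be even")
  m <- n / 2
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(m) - 0.5
  z <- k / m                      # upper hemisphere only
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(m) - 1)
  d <- cbind(r * cos(th), r * sin(th), z)
  rbind(d, -d)
}

#' Evaluate an ODF at one voxel
#'
#' @param image an [sh_image] object.
#' @param voxel integer index triple, 1-based.
#' @param directions unit direction matrix.
#' @return numeric vector of amplitudes, one per direction.
#' @export
evaluate_odf <- function(image, voxel, directions) {
  stopifnot(inherits(image, "sh_image"))
  voxel <- as.integer(voxel)
  if (length(voxel) != 3 || any(voxel < 1) ||
      any(voxel > image$grid_shape))
    stop("voxel index out of bounds: ", paste(voxel, collapse = ","))
  cf <- image$coeffs[voxel[1], voxel[2], voxel[3], ]
  drop(real_sh_basis(directions, image$lmax) %*% cf)
}

# cached quadrature + basis + projection machinery, one entry per lmax
.sh_cache <- new.env(parent = emptyenv())

sh_projection <- function(lmax) {
  key <- as.character(lmax)
  if (!is.null(.sh_cache[[key]])) return(.sh_cache[[key]])
  qd <- sh_quadrature(2 * max(lmax, 1))
  B <- cpp_sh_basis(qd$directions, as.integer(lmax))
  # P = B' diag(w): exact projector for band-limited functions
  P <- t(B * qd$weights)
  out <- list(directions = qd$directions, weights = qd$weights,
              basis = B, proj = P)
  .sh_cache[[key]] <- out
  out
}

#' Rotate a spherical-harmonic coefficient vector
#'
#' Applies a proper rotation to the spherical function represented by `coeffs`
#' (i.e. returns the coefficients of `f(R^T d)`). The rotation operator is
#' block-diagonal over degrees and is built numerically by sampling the
#' rotated function on an exact quadrature grid and projecting back onto the
#' basis; per-band Euclidean norms are preserved to machine precision.
#'
#' @param coeffs numeric coefficient vector in the package SH order.
#' @param rotation 3 x 3 proper rotation matrix (orthogonal, det +1).
#' @return rotated coefficient vector.
#' @export
rotate_sh <- function(coeffs, rotation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper rotation matrix (orthogonal, det +1)")
  lmax <- sh_lmax_from_n(length(coeffs))
  if (is.na(lmax))
    stop("coefficient length ", length(coeffs),
         " matches no even-degree SH count")
  mach <- sh_projection(lmax)
  # f'(d) = f(R^T d) sampled on the quadrature nodes, then refit
  dirs_rot <- mach$directions %*% rotation   # rows: R^T d
  Brot <- cpp_sh_basis(dirs_rot, as.integer(lmax))
  drop(mach$proj %*% (Brot %*% coeffs))
}
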