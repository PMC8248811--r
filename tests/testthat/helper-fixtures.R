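# shared fixtures, built once per test run

rand_sh_image <- function(d = c(8, 8, 8), lmax = 2, seed = 1,
                          aff = diag(4)) {
  set.seed(seed)
  sh_image(array(rnorm(prod(d) * sh_n_coef(lmax)),
                 c(d, sh_n_coef(lmax))), lmax, aff)
}

rand_scalar_image <- function(d = c(8, 8, 8), seed = 1, aff = diag(4)) {
  set.seed(seed)
  scalar_image(array(rnorm(prod(d)), d), aff)
}

# literal triple-loop evaluation of the local correlation (shared numerator/
# denominator machinery of LAC and LNCC), independent of the package's
# separable-box-filter implementation
loop_local_corr <- function(la, lb, radius) {
  d <- dim(la[[1]])
  nb <- function(i, n) max(1, i - radius):min(n, i + radius)
  r <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- nb(i, d[1]); jj <- nb(j, d[2]); kk <- nb(k, d[3])
    num <- 0; da <- 0; db <- 0
    for (c in seq_along(la)) {
      av <- la[[c]][ii, jj, kk]; bv <- lb[[c]][ii, jj, kk]
      av <- av - mean(av); bv <- bv - mean(bv)
      num <- num + sum(av * bv); da <- da + sum(av^2); db <- db + sum(bv^2)
    }
    r[i, j, k] <- num / sqrt(da * db)
  }
  r
}

# per-voxel loop evaluation of the symmetric update-field pair, using the
# same centred-image gradient definition as documented for the metric
loop_update_fields <- function(la, lb, radius, voxel_to_world = diag(4)) {
  d <- dim(la[[1]])
  nb <- function(i, n) max(1, i - radius):min(n, i + radius)
  nimg <- array(0, d)
  cent <- function(lst) lapply(lst, function(a) {
    out <- array(0, d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      out[i, j, k] <- a[i, j, k] - mean(a[nb(i, d[1]), nb(j, d[2]),
                                          nb(k, d[3])])
    out
  })
  ca <- cent(la); cb <- cent(lb)
  ga <- lapply(ca, mcatlas:::gradient_world, voxel_to_world = voxel_to_world)
  gb <- lapply(cb, mcatlas:::gradient_world, voxel_to_world = voxel_to_world)
  upA <- array(0, c(d, 3)); upB <- array(0, c(d, 3))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ii <- nb(i, d[1]); jj <- nb(j, d[2]); kk <- nb(k, d[3])
    num <- 0; da <- 0; db <- 0
    for (c in seq_along(la)) {
      av <- la[[c]][ii, jj, kk]; bv <- lb[[c]][ii, jj, kk]
      av <- av - mean(av); bv <- bv - mean(bv)
      num <- num + sum(av * bv); da <- da + sum(av^2); db <- db + sum(bv^2)
    }
    fac <- 2 * num / (da * db)
    for (c in seq_along(la)) {
      wa <- cb[[c]][i, j, k] - (num / da) * ca[[c]][i, j, k]
      wb <- ca[[c]][i, j, k] - (num / db) * cb[[c]][i, j, k]
      for (x in 1:3) {
        upA[i, j, k, x] <- upA[i, j, k, x] + fac * wa * ga[[c]][[x]][i, j, k]
        upB[i, j, k, x] <- upB[i, j, k, x] + fac * wb * gb[[c]][[x]][i, j, k]
      }
    }
  }
  list(toward_moving = upA, toward_fixed = upB)
}

sh_coef_list <- function(img, min_l = 2) {
  deg <- mcatlas:::sh_degrees(img$lmax)
  lapply(which(deg >= min_l), function(k) img$coeffs[, , , k, drop = TRUE])
}

# small fast registration config for unit tests
test_reg_config <- function(...) {
  registration_config(max_iterations_per_level = c(10, 8, 6), ...)
}
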