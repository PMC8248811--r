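test_that("age-window assignment: nearest center, ties to younger", {
  centers <- seq(37, 44, by = 0.5)
  w <- assign_age_windows(c(40.20, 40.25, 40.26), centers)
  member_of <- function(a) which(vapply(w, function(x) a %in% x$members,
                                        logical(1)))
  expect_equal(w[[member_of(1)]]$center, 40.0)   # nearest
  expect_equal(w[[member_of(2)]]$center, 40.0)   # exact midpoint -> younger
  expect_equal(w[[member_of(3)]]$center, 40.5)
  expect_equal(length(w), 15)
  # a uniform cohort of 150 fills every window and sizes sum to 150
  set.seed(17)
  ages <- runif(150, 37, 44)
  w2 <- assign_age_windows(ages, centers)
  sizes <- vapply(w2, function(x) length(x$members), integer(1))
  expect_true(all(sizes > 0))
  expect_equal(sum(sizes), 150L)
  expect_warning(assign_age_windows(36.0, centers), "outside")
})

test_that("robust weighted averaging follows the 1.5-SD exclusion rule", {
  d <- c(3, 3, 3)
  mk <- function(v) scalar_image(array(v, d))
  # identical inputs: template equals them, everyone retained
  same <- robust_weighted_average(lapply(1:4, function(i) mk(2.5)))
  expect_equal(same$template$values, array(2.5, d))
  expect_true(all(vapply(same$retention, function(r) all(r == 1),
                         logical(1))))
  # {1,1,1,1,10}: the outlier is excluded; the robust mean equals the
  # direct arithmetic mean of the remaining values
  out <- robust_weighted_average(lapply(c(1, 1, 1, 1, 10), mk))
  expect_equal(out$template$values, array(1, d))
  expect_equal(out$retention[[5]][1, 1, 1], 0)
  # n = 2: each value deviates by exactly 1 SD, nobody can be excluded
  two <- robust_weighted_average(list(mk(3), mk(8)))
  expect_equal(two$template$values, array(5.5, d))
  expect_true(all(vapply(two$retention, function(r) all(r == 1),
                         logical(1))))
  expect_error(robust_weighted_average(list(mk(1))), "at least 2")
  # retention guarantee and envelope on random draws
  set.seed(23)
  X <- matrix(rnorm(2000 * 7), 2000)
  imgs <- lapply(seq_len(7), function(j)
    scalar_image(array(X[, j], c(10, 10, 20))))
  ra <- robust_weighted_average(imgs)
  wsum <- Reduce(`+`, ra$retention)
  expect_gte(min(wsum), 1)
  kept_min <- apply(X + ifelse(sapply(ra$retention, as.vector) == 0, Inf, 0),
                    1, min)
  kept_max <- apply(X + ifelse(sapply(ra$retention, as.vector) == 0, -Inf, 0),
                    1, max)
  expect_true(all(ra$template$values >= array(kept_min, c(10, 10, 20)) - 1e-12))
  expect_true(all(ra$template$values <= array(kept_max, c(10, 10, 20)) + 1e-12))
})

test_that("average inverse warp: zeros, cancelling translations, oracle", {
  d <- c(12, 12, 12)
  z <- mcatlas:::zero_warp(d, diag(4))
  expect_equal(max(abs(average_inverse_warp(list(z, z))$vectors)), 0)
  up <- array(0, c(d, 3)); up[, , , 1] <- 1.2
  um <- array(0, c(d, 3)); um[, , , 1] <- -1.2
  avg <- average_inverse_warp(list(displacement_field(up, diag(4)),
                                   displacement_field(um, diag(4))))
  expect_lt(max(abs(avg$vectors)), 1e-6)
  # equals the loop mean of individually inverted fields
  spec <- phantom_spec(grid_shape = 12, warp_amplitude_voxels = 1)
  ws <- lapply(1:3, function(i) mcatlas:::phantom_warp(spec, i))
  avg2 <- average_inverse_warp(ws)
  ora <- (invert_warp(ws[[1]])$vectors + invert_warp(ws[[2]])$vectors +
            invert_warp(ws[[3]])$vectors) / 3
  expect_lt(max(abs(avg2$vectors - ora)), 1e-8)
  expect_error(average_inverse_warp(list()), "no warps")
})

test_that("average inverse affine: identity, scalings, log-space mean", {
  id <- affine_transform(diag(4))
  expect_equal(average_inverse_affine(list(id, id))$matrix, diag(4))
  s1 <- affine_transform(diag(c(1.3, 1.3, 1.3, 1)))
  expect_equal(average_inverse_affine(list(s1, s1))$matrix,
               diag(c(1 / 1.3, 1 / 1.3, 1 / 1.3, 1)), tolerance = 1e-12)
  a <- affine_transform(diag(c(1.2, 1.05, 0.9, 1)))
  b <- affine_transform(diag(c(1.4, 0.95, 1.1, 1)))
  av <- average_inverse_affine(list(a, b))
  expect_equal(diag(av$matrix)[1:3],
               1 / sqrt(c(1.2 * 1.4, 1.05 * 0.95, 0.9 * 1.1)),
               tolerance = 1e-10)
  expect_equal(av$flags, c("scale", "shear"))
  # rotations are discarded: a pure rotation averages to identity
  th <- 0.4
  R <- diag(4); R[1:2, 1:2] <- rbind(c(cos(th), -sin(th)),
                                     c(sin(th), cos(th)))
  expect_equal(average_inverse_affine(list(affine_transform(R)))$matrix,
               diag(4), tolerance = 1e-12)
})

test_that("stage 1 on copies of the reference returns it unchanged", {
  spec <- phantom_spec(grid_shape = 24, noise_sigma = 0,
                       warp_amplitude_voxels = 0, lmax = 2)
  ref <- mcatlas:::phantom_template(spec, 40)
  cohort <- lapply(1:3, function(i) {
    cs <- ref; cs$subject_id <- sprintf("c%d", i); cs
  })
  st1 <- build_atlas_stage(cohort, ref, stage = 1,
                           config = atlas_config(
                             registration = test_reg_config()))
  sp <- min(voxel_spacing(ref$channels[[1]]))
  for (r in st1$records)
    expect_lt(max(abs(r$warp_to_reference$vectors)) / sp, 0.05)
  expect_equal(st1$templates$T2w$values, ref$channels$T2w$values,
               tolerance = 1e-6)
  expect_equal(st1$templates$odf$coeffs, ref$channels$odf$coeffs,
               tolerance = 1e-5)
})

test_that("robust template averaging rejects a bright lesion", {
  spec <- phantom_spec(grid_shape = 20, noise_sigma = 0,
                       warp_amplitude_voxels = 0, lmax = 2)
  ref <- mcatlas:::phantom_template(spec, 40)
  imgs <- lapply(1:5, function(i) ref$channels$T2w)
  lesioned <- ref$channels$T2w
  les_vox <- as.matrix(expand.grid(9:11, 9:11, 9:11))
  lesioned$values[les_vox] <- lesioned$values[les_vox] + 2
  imgs[[5]] <- lesioned
  ra <- robust_weighted_average(imgs)
  expect_equal(ra$retention[[5]][9, 9, 9], 0)
  expect_equal(ra$template$values, ref$channels$T2w$values,
               tolerance = 1e-10)
})
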