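test_that("Gompertz curve: peak point, asymptotes, degenerate cases", {
  expect_equal(gompertz(40.5, 1, 0.2, 0.5, 40.5), (1 - 0.2) / exp(1) + 0.2)
  expect_equal(gompertz(-1e6, 0.9, 0.3, 0.4, 40), 0.9)
  expect_equal(gompertz(1e6, 0.9, 0.3, 0.4, 40), 0.3)
  expect_equal(gompertz(c(37, 40, 44), 0.7, 0.7, 1.2, 41), rep(0.7, 3))
  # monotone between the asymptotes, direction sign(gamma) * sign(alpha-delta)
  tgrid <- seq(30, 50, length.out = 400)
  for (p in list(c(1, 0, 0.8, 40), c(1, 0, -0.8, 40), c(0, 1, 0.8, 40))) {
    dg <- diff(gompertz(tgrid, p[1], p[2], p[3], p[4]))
    dir <- -sign(p[3]) * sign(p[1] - p[2])
    expect_true(all(dir * dg >= 0))
  }
})

test_that("noiseless series are recovered to high relative accuracy", {
  tt <- seq(37, 44, by = 0.5)
  set.seed(31)
  n <- 60
  al <- runif(n, 0.4, 0.9); de <- runif(n, 0.1, 0.6)
  ga <- runif(n, 0.25, 0.6) * sample(c(-1, 1), n, TRUE)
  ta <- runif(n, 38.5, 42.5)
  Y <- t(sapply(seq_len(n), function(i)
    gompertz(tt, al[i], de[i], ga[i], ta[i])))
  f <- fit_gompertz_maps(tt, Y)
  expect_lt(max(abs(f$alpha - al) / abs(al)), 1e-3)
  expect_lt(max(abs(f$delta - de) / abs(de)), 1e-3)
  expect_lt(max(abs(f$gamma - ga) / abs(ga)), 1e-3)
  expect_lt(max(abs(f$tau - ta) / ta), 1e-3)
  expect_true(all(f$r_squared > 1 - 1e-9))
  expect_true(all(f$converged))
})

test_that("constant series yield alpha = delta and R-squared 0", {
  tt <- seq(37, 44, by = 0.5)
  f <- fit_gompertz_maps(tt, matrix(0.42, 3, length(tt)))
  expect_equal(f$alpha, rep(0.42, 3))
  expect_equal(f$delta, rep(0.42, 3))
  expect_equal(f$r_squared, rep(0, 3))
  expect_equal(f$linear_r_squared, rep(0, 3))
})

test_that("fit is invariant to re-centring the time axis", {
  tt <- seq(37, 44, by = 0.5)
  set.seed(32)
  Y <- t(sapply(1:10, function(i)
    gompertz(tt, runif(1, 0.5, 1), runif(1, 0, 0.5),
             runif(1, 0.3, 1), runif(1, 39, 42)) +
      rnorm(length(tt), 0, 0.005)))
  f1 <- fit_gompertz_maps(tt, Y)
  f2 <- fit_gompertz_maps(tt - 40, Y)
  expect_equal(f2$tau, f1$tau - 40, tolerance = 1e-6)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f2$gamma, f1$gamma, tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-6)
})

test_that("too few windows raise an error", {
  expect_error(fit_gompertz_maps(37:40, matrix(1, 2, 4)), "at least 5")
})

test_that("transform curve fitting: constant and known-Gompertz warps", {
  d <- c(8, 8, 8)
  tt <- seq(37, 44, by = 1)
  keys <- sprintf("%.1f", tt)
  # time-constant warps reproduce themselves at any t
  u0 <- array(rnorm(prod(d) * 3, sd = 0.3), c(d, 3))
  tf <- list(warp = setNames(lapply(tt, function(t)
    displacement_field(u0, diag(4))), keys),
    affine = setNames(lapply(tt, function(t) affine_transform(diag(4))),
                      keys))
  ft <- fit_gompertz_warps(tt, tf)
  for (j in 1:3)
    expect_equal(predict(ft$warp[[j]], 39.7)$values, u0[, , , j],
                 tolerance = 1e-6)
  # components growing as a known Gompertz are recovered
  base <- array(runif(prod(d) * 3, -1, 1), c(d, 3))
  tfg <- list(warp = setNames(lapply(tt, function(t)
    displacement_field(base * gompertz(t, 1, 0.2, 0.8, 40.5), diag(4))),
    keys),
    affine = setNames(lapply(tt, function(t) {
      M <- diag(4); M[1, 1] <- gompertz(t, 1.3, 1.0, 0.8, 40.5)
      affine_transform(M)
    }), keys))
  ftg <- fit_gompertz_warps(tt, tfg)
  for (j in 1:3)
    expect_equal(predict(ftg$warp[[j]], 41.3)$values,
                 base[, , , j] * gompertz(41.3, 1, 0.2, 0.8, 40.5),
                 tolerance = 1e-3)
  A41 <- matrix(predict(ftg$affine, 41.0), 3, 3)
  expect_equal(A41[1, 1], gompertz(41, 1.3, 1.0, 0.8, 40.5),
               tolerance = 1e-3)
})

test_that("atlas evaluation respects the valid range and window centers", {
  d <- c(6, 6, 6)
  tt <- seq(37, 44, by = 0.5)
  set.seed(33)
  truth <- list(al = array(runif(prod(d), 0.6, 0.9), d),
                de = array(runif(prod(d), 0.2, 0.5), d),
                ga = array(runif(prod(d), 0.4, 0.8), d),
                ta = array(runif(prod(d), 39.5, 41.5), d))
  imgs <- lapply(tt, function(t)
    scalar_image(gompertz(t, truth$al, truth$de, truth$ga, truth$ta)))
  fit <- fit_gompertz_maps(tt, imgs)
  atl <- atlas_4d(list(T2w = fit))
  expect_error(evaluate_atlas(atl, 46), "outside")
  ev <- evaluate_atlas(atl, 40.5, unbias = FALSE)
  expect_equal(ev$maps$T2w$values,
               gompertz(40.5, truth$al, truth$de, truth$ga, truth$ta),
               tolerance = 1e-6)
  # midpoint evaluation lies inside the envelope of neighbouring centers
  # (monotone segment)
  e1 <- predict(fit, 40.5)$values; e2 <- predict(fit, 41.0)$values
  mid <- predict(fit, 40.75)$values
  expect_true(all(mid >= pmin(e1, e2) - 1e-9 & mid <= pmax(e1, e2) + 1e-9))
})

test_that("growth-peak offset maps threshold |tau - reference|", {
  d <- c(4, 4, 4)
  fit <- structure(list(tau = array(40.5, d), active = array(TRUE, d),
                        grid_shape = d, voxel_to_world = diag(4)),
                   class = "gompertz_fit")
  expect_equal(sum(growth_peak_offset_map(fit)$values), 0)
  fit$tau <- array(40.8, d)
  expect_equal(sum(growth_peak_offset_map(fit)$values), prod(d))
  set.seed(34)
  fit$tau <- array(runif(prod(d), 40, 41), d)
  m <- growth_peak_offset_map(fit, 40.5, 0.2)
  expect_equal(m$values, (abs(fit$tau - 40.5) >= 0.2) * 1)
})
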