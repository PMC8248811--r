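test_that("certainty maps: constant, normalisation, linear ramp", {
  d <- c(10, 10, 10)
  expect_equal(max(certainty_map(scalar_image(array(3, d)))$values), 0)
  img <- rand_scalar_image(d, seed = 61)
  expect_equal(max(certainty_map(img)$values), 1)
  ramp <- scalar_image(array(rep(seq_len(d[1]), prod(d[2:3])), d))
  cm <- certainty_map(ramp)
  # uniform gradient everywhere: the normalised map is identically 1
  expect_equal(range(cm$values), c(1, 1))
})

test_that("certainty-weighted fusion matches the weighted-mean oracle", {
  d <- c(6, 6, 6)
  set.seed(71)
  ups <- lapply(1:3, function(i) {
    structure(list(toward_moving = array(rnorm(prod(d) * 3), c(d, 3)),
                   toward_fixed = array(rnorm(prod(d) * 3), c(d, 3)),
                   grid_shape = d), class = "update_field_pair")
  })
  certs <- lapply(1:3, function(i)
    structure(list(values = array(runif(prod(d)), d)),
              class = "certainty_map"))
  fu <- fuse_updates(ups, certs)
  # brute-force weighted mean per voxel, per component
  ora <- array(0, c(d, 3)); wsum <- array(0, d)
  for (i in 1:3) {
    wsum <- wsum + certs[[i]]$values
    for (j in 1:3)
      ora[, , , j] <- ora[, , , j] +
        certs[[i]]$values * ups[[i]]$toward_moving[, , , j]
  }
  for (j in 1:3) ora[, , , j] <- ora[, , , j] / wsum
  expect_lt(max(abs(fu$toward_moving - ora)), 1e-12)
  # convexity: each fused component lies in the channel envelope
  for (j in 1:3) {
    stack <- sapply(ups, function(u) as.vector(u$toward_moving[, , , j]))
    expect_true(all(fu$toward_moving[, , , j] >= apply(stack, 1, min) - 1e-12))
    expect_true(all(fu$toward_moving[, , , j] <= apply(stack, 1, max) + 1e-12))
  }
  # single channel passes through wherever certainty > 0
  f1 <- fuse_updates(ups[1], certs[1])
  pos <- certs[[1]]$values > 0
  expect_equal(f1$toward_moving[, , , 2][pos],
               ups[[1]]$toward_moving[, , , 2][pos])
  # equal positive certainties give the arithmetic mean
  ce <- lapply(1:3, function(i)
    structure(list(values = array(0.5, d)), class = "certainty_map"))
  fe <- fuse_updates(ups, ce)
  am <- (ups[[1]]$toward_moving + ups[[2]]$toward_moving +
           ups[[3]]$toward_moving) / 3
  expect_lt(max(abs(fe$toward_moving - am)), 1e-12)
  expect_error(fuse_updates(ups, certs[1:2]), "equal length")
})

test_that("warping: identity, integer translation, ODF reorientation", {
  spec <- phantom_spec(grid_shape = 24, noise_sigma = 0,
                       warp_amplitude_voxels = 0, lmax = 4)
  tpl <- mcatlas:::phantom_template(spec, 40)
  d <- spec$grid_shape
  aff <- tpl$channels[[1]]$voxel_to_world
  # zero warp reproduces the channels
  w0 <- mcatlas:::zero_warp(d, aff)
  same <- warp_channelset(tpl, w0)
  expect_equal(same$channels$T2w$values, tpl$channels$T2w$values,
               tolerance = 1e-12)
  expect_equal(same$channels$odf$coeffs, tpl$channels$odf$coeffs,
               tolerance = 1e-10)
  # integer translation is an exact shift in the interior
  u <- array(0, c(d, 3)); u[, , , 1] <- 2   # sample 2 voxels up in x
  sh <- warp_channelset(tpl, displacement_field(u, aff))
  expect_equal(sh$channels$T2w$values[1:(d[1] - 2), , ],
               tpl$channels$T2w$values[3:d[1], , ], tolerance = 1e-12)
  # global rotation warp rotates the ODF peak with the anatomy
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ctr <- c(aff %*% c((d - 1) / 2, 1))[1:3]
  xw <- mcatlas:::grid_world_coords(d, aff)
  tw <- sweep(sweep(xw, 2, ctr) %*% t(R), 2, ctr, "+")
  wr <- displacement_field(array(tw - xw, c(d, 3)), aff)
  rot <- warp_channelset(tpl, wr)
  # pick a point well inside bundle 1 (fiber along +x, away from the
  # crossing) and look at the voxel it maps to under the pull-back; the
  # anatomy there appears rotated by R^-1, so the peak must sit at R^T x
  tis <- mcatlas:::phantom_tissues(spec)
  p <- c(ctr[1] + 0.22 * d[1], ctr[2], ctr[3] + 0.18 * d[3])
  pvox <- round(p + 1)
  expect_true(tis$bundle1[pvox[1], pvox[2], pvox[3]])
  vox <- round(as.vector(t(R) %*% (p - ctr)) + ctr) + 1
  dirs <- sh_directions(724)
  amp <- evaluate_odf(rot$channels$odf, vox, dirs)
  pk <- dirs[which.max(amp), ]
  want <- as.vector(t(R) %*% c(1, 0, 0))
  ang <- acos(min(1, abs(sum(pk * want)))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("warp inversion: zero, translation, smooth random field", {
  d <- c(16, 16, 16)
  z <- mcatlas:::zero_warp(d, diag(4))
  expect_equal(max(abs(invert_warp(z)$vectors)), 0)
  u <- array(0, c(d, 3)); u[, , , 2] <- 1.3
  inv <- invert_warp(displacement_field(u, diag(4)))
  expect_lt(max(abs(inv$vectors[, , , 2] + 1.3)), 1e-6)
  spec <- phantom_spec(grid_shape = 24, warp_amplitude_voxels = 2)
  w <- mcatlas:::phantom_warp(spec, 3)
  wi <- invert_warp(w)
  expect_lt(attr(wi, "residual_voxels"), 0.1)
})

test_that("Jacobian maps: identity, pure scaling, analytic affine", {
  d <- c(14, 14, 14)
  z <- mcatlas:::zero_warp(d, diag(4))
  expect_equal(jacobian_map(z)$values, array(1, d))
  xw <- mcatlas:::grid_world_coords(d, diag(4))
  s <- 1.06
  us <- array((s - 1) * xw, c(d, 3))
  js <- jacobian_map(displacement_field(us, diag(4)))
  expect_equal(js$values[3:12, 3:12, 3:12],
               array(s^3, c(10, 10, 10)), tolerance = 1e-9)
  A3 <- rbind(c(1.05, 0.02, 0), c(-0.01, 0.95, 0.03), c(0, 0.01, 1.1))
  ua <- array(xw %*% t(A3) - xw, c(d, 3))
  ja <- jacobian_map(displacement_field(ua, diag(4)))
  expect_lt(max(abs(ja$values[3:12, 3:12, 3:12] - det(A3))), 1e-3)
})

test_that("affine registration recovers identity, shift and scale", {
  spec <- phantom_spec(grid_shape = 32, noise_sigma = 0,
                       warp_amplitude_voxels = 0, lmax = 2)
  tpl <- mcatlas:::phantom_template(spec, 40)
  fx <- channel_set("f", 40, tpl$channels["T2w"])
  a0 <- affine_register(fx, fx, "T2w")
  expect_lt(max(abs(a0$matrix[1:3, 4])), 0.1)
  # known 3-voxel shift: the moving image samples fixed at x + 3, so the
  # recovered fixed-to-moving affine carries translation -3
  d <- spec$grid_shape; aff <- tpl$channels[[1]]$voxel_to_world
  u <- array(0, c(d, 3)); u[, , , 1] <- 3
  shifted <- warp_channelset(fx, displacement_field(u, aff))
  a1 <- affine_register(fx, shifted, "T2w")
  expect_lt(abs(a1$matrix[1, 4] + 3), 0.2)
  expect_lt(max(abs(a1$matrix[2:3, 4])), 0.2)
  # known 1.1x scaling about the volume centre (pull-back: the moving image
  # appears shrunk, the recovered scale is 1/1.1)
  ctr <- c(aff %*% c((d - 1) / 2, 1))[1:3]
  xw <- mcatlas:::grid_world_coords(d, aff)
  tw <- sweep(sweep(xw, 2, ctr) * 1.1, 2, ctr, "+")
  scaled <- warp_channelset(fx, displacement_field(array(tw - xw, c(d, 3)),
                                                   aff))
  a2 <- affine_register(fx, scaled, "T2w")
  expect_equal(diag(a2$matrix)[1:3], rep(1 / 1.1, 3), tolerance = 0.01)
})

test_that("multi-channel registration: identity pair and symmetry", {
  spec <- phantom_spec(grid_shape = 32, noise_sigma = 0,
                       warp_amplitude_voxels = 1.5, lmax = 2)
  tpl <- mcatlas:::phantom_template(spec, 40)
  fx <- channel_set("f", 40, tpl$channels[c("T2w", "cortex_mask")])
  cfg <- test_reg_config()
  reg0 <- register_multichannel(fx, fx, cfg)
  sp <- min(voxel_spacing(fx$channels[[1]]))
  expect_lt(max(abs(reg0$warp_moving_to_fixed$vectors)) / sp, 0.05)
  # a warped pair: swapping the roles swaps the output warps
  s <- make_phantom_subject(spec, 40, 5)
  mv <- channel_set("m", 40, s$channelset$channels[c("T2w", "cortex_mask")])
  regAB <- register_multichannel(fx, mv, cfg)
  regBA <- register_multichannel(mv, fx, cfg)
  dmag <- sqrt(rowSums(matrix(regAB$warp_moving_to_fixed$vectors -
                                regBA$warp_fixed_to_moving$vectors,
                              ncol = 3)^2))
  expect_lt(mean(dmag) / sp, 0.2)
  # forward and reverse compose to near-identity
  comp <- compose_warps(regAB$warp_fixed_to_moving,
                        regAB$warp_moving_to_fixed)
  cmag <- sqrt(rowSums(matrix(comp$vectors, ncol = 3)^2))
  expect_lt(mean(cmag) / sp, 0.3)
  expect_error(register_multichannel(fx, channel_set("m", 40,
    s$channelset$channels[c("T2w", "ventricle_mask")]), cfg),
    "channel names")
})
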