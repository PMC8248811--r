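test_that("average growth-rate map takes the mean of absolutes", {
  d <- c(6, 6, 6)
  z <- scalar_image(array(0, d))
  expect_equal(average_growth_rate_map(list(z, z))$values, array(0, d))
  g <- array(runif(prod(d)), d)
  two <- average_growth_rate_map(list(scalar_image(g), scalar_image(-g)))
  expect_equal(two$values, g)
  set.seed(41)
  maps <- lapply(1:4, function(i) scalar_image(array(rnorm(prod(d)), d)))
  av <- average_growth_rate_map(maps)
  ora <- (abs(maps[[1]]$values) + abs(maps[[2]]$values) +
            abs(maps[[3]]$values) + abs(maps[[4]]$values)) / 4
  expect_lt(max(abs(av$values - ora)), 1e-12)
  expect_gte(min(av$values), 0)
  expect_error(average_growth_rate_map(list(z, scalar_image(array(0, c(4, 4, 4))))),
               "grid")
})

test_that("threshold parcellation recovers constructed blobs exactly", {
  d <- c(20, 20, 20)
  g <- array(0, d)
  g[3:6, 3:6, 3:6] <- 0.4        # 64 voxels
  g[12:17, 12:15, 12:14] <- 0.3  # 72 voxels
  g[19, 19, 19] <- 0.9           # 1 voxel, dropped by min size
  p <- threshold_parcellation(scalar_image(g), threshold = 0.25,
                              min_region_voxels = 27)
  expect_equal(nrow(p$table), 2L)
  expect_equal(p$table$n_voxels, c(72L, 64L))  # ordered by size
  expect_equal(sum(p$labels == 1), 72L)
  expect_equal(sum(p$labels == 2), 64L)
  expect_equal(sum(p$labels > 0), 136L)
  # empty cases
  expect_warning(p0 <- threshold_parcellation(scalar_image(array(0, d))),
                 "empty")
  expect_equal(sum(p0$labels), 0)
  expect_warning(threshold_parcellation(scalar_image(g), threshold = 1),
                 "empty")
  # 26-connectivity joins diagonal neighbours, 6-connectivity does not
  gd <- array(0, c(8, 8, 8))
  gd[2, 2, 2] <- 1; gd[3, 3, 3] <- 1
  p26 <- threshold_parcellation(scalar_image(gd), 0.5, 1, connectivity = 26)
  p6 <- threshold_parcellation(scalar_image(gd), 0.5, 1, connectivity = 6)
  expect_equal(nrow(p26$table), 1L)
  expect_equal(nrow(p6$table), 2L)
})

test_that("robust ROI statistics exclude outliers like the template rule", {
  d <- c(10, 10, 10)
  lab <- array(0L, d)
  lab[2:4, 2:4, 2] <- 1L     # 9 voxels
  lab[7:8, 7, 7] <- 2L       # 2 voxels
  parc <- structure(list(labels = lab,
                         table = data.frame(id = 1:2,
                                            name = c("a", "b"),
                                            n_voxels = c(9L, 2L))),
                    class = "parcellation_map")
  v <- array(0, d)
  v[2:4, 2:4, 2] <- c(1, 1, 1, 1, 10, 1, 1, 1, 1)
  v[7:8, 7, 7] <- c(2, 8)
  st <- roi_robust_stats(scalar_image(v), parc, subject_id = "s1",
                         channel = "T2w")
  expect_equal(st$robust_mean[st$roi == 1], 1)      # outlier 10 excluded
  expect_equal(st$n_retained[st$roi == 1], 8L)
  expect_equal(st$robust_mean[st$roi == 2], 5)      # n = 2: both retained
  expect_equal(st$n_retained[st$roi == 2], 2L)
  # constant ROI: everything retained, mean is the constant
  vc <- array(3.3, d)
  stc <- roi_robust_stats(scalar_image(vc), parc)
  expect_equal(stc$robust_mean, c(3.3, 3.3))
  # robust mean lies within the value range whatever the ordering
  expect_true(all(st$robust_mean >= c(1, 2) & st$robust_mean <= c(10, 8)))
})

test_that("association analysis: recovery, Bonferroni arithmetic", {
  set.seed(43)
  n <- 60
  ga <- runif(n, 25, 42); pma <- runif(n, 38, 43)
  tbl <- do.call(rbind, lapply(1:3, function(r)
    data.frame(subject_id = sprintf("s%02d", 1:n), age = pma,
               ga_birth = ga, group = "all", roi = r, channel = "FA",
               robust_mean = 0.02 * ga + 0.05 * pma + rnorm(n, 0, 0.02))))
  res <- association_analysis(tbl)
  expect_equal(nrow(res), 3L)
  for (i in 1:3) {
    expect_true(res$estimable[i])
    expect_lt(abs(res$estimate[i] - 0.02), 2 * res$se[i])
  }
  expect_equal(res$p_bonferroni, pmin(1, res$p_raw * 3))
  # the documented multiplication rule: 20 tests at p = 0.004 -> 0.08
  expect_equal(min(1, 0.004 * 20), 0.08)
  tbl20 <- do.call(rbind, lapply(1:20, function(r) {
    d <- tbl[tbl$roi == 1, ]; d$roi <- r; d
  }))
  res20 <- association_analysis(tbl20)
  expect_equal(res20$p_bonferroni, pmin(1, res20$p_raw * 20))
  # too few subjects -> not estimable
  small <- tbl[tbl$roi == 1, ][1:5, ]
  expect_false(association_analysis(small)$estimable)
})

test_that("association analysis holds its size under a null outcome", {
  set.seed(44)
  n <- 40
  n_tests <- 200
  pr <- vapply(seq_len(n_tests), function(r) {
    tbl <- data.frame(subject_id = seq_len(n), age = runif(n, 38, 43),
                      ga_birth = runif(n, 25, 42), roi = r, channel = "x",
                      robust_mean = rnorm(n))
    association_analysis(tbl)$p_raw
  }, numeric(1))
  hits <- sum(pr < 0.05)
  bounds <- qbinom(c(0.005, 0.995), n_tests, 0.05)
  expect_gte(hits, bounds[1])
  expect_lte(hits, bounds[2])
})
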