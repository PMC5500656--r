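# FCS maps: Fisher transform, distance partition, threshold behavior,
# oracle equivalence, smoothing.

test_that("fisher_z is the clipped arctanh", {
  expect_identical(as.numeric(fisher_z(0)), 0)
  expect_equal(as.numeric(fisher_z(0.2)), 0.202733, tolerance = 1e-5)
  expect_equal(as.numeric(fisher_z(-0.3)), -as.numeric(fisher_z(0.3)))
  z <- fisher_z(1 - 1e-12)
  expect_equal(as.numeric(z), atanh(1 - 1e-7))
  expect_identical(attr(z, "n_clipped"), 1L)
})

test_that("perfectly correlated neighbors give pure short-range FCS", {
  sig <- rnorm(30)
  vals <- rbind(sig, sig, sig)
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0))
  ts <- voxel_ts(vals, coords)
  m <- fcs_maps(ts, 0.2, 75)
  expect_equal(m$short[1:3], rep(2 * atanh(1 - 1e-7), 3), tolerance = 1e-9)
  expect_true(all(m$long[1:3] == 0))
})

test_that("sub-threshold correlations contribute nothing", {
  pair <- exact_cor_pair(50, 0.1)
  ts <- voxel_ts(pair, rbind(c(0, 0, 0), c(3, 0, 0)))
  m <- fcs_maps(ts, 0.2, 75)
  expect_true(all(m$global == 0))
  # the same pair passes a lower threshold
  m2 <- fcs_maps(ts, 0.05, 75)
  expect_equal(m2$global[1], atanh(0.1), tolerance = 1e-9)
})

test_that("vectorized FCS equals the brute-force double-loop oracle", {
  set.seed(21)
  for (rep in 1:5) {
    ts <- random_ts(sample(20:60, 1), 25)
    m <- fcs_maps(ts, 0.2, 9)          # 9 mm cutoff exercises both ranges
    ref <- oracle_fcs(ts$values, ts$coords_mm, 0.2, 9)
    expect_equal(m$global[ts$voxel_index], ref$global, tolerance = 1e-10)
    expect_equal(m$long[ts$voxel_index], ref$long, tolerance = 1e-10)
    expect_equal(m$short[ts$voxel_index], ref$short, tolerance = 1e-10)
  }
})

test_that("the long/short partition is exhaustive and exact", {
  set.seed(22)
  ts <- random_ts(80, 30)
  sweep <- fcs_threshold_sweep(ts, c(0.1, 0.2, 0.3), cutoff_mm = 9)
  for (m in sweep) {
    expect_identical(m$long + m$short, m$global)
    expect_true(all(m$global >= 0))
  }
})

test_that("per-voxel FCS is non-increasing in the threshold", {
  set.seed(23)
  ts <- random_ts(100, 30)
  sweep <- fcs_threshold_sweep(ts, c(0.1, 0.2, 0.3))
  expect_true(all(sweep$r0.2$global <= sweep$r0.1$global))
  expect_true(all(sweep$r0.3$global <= sweep$r0.2$global))
  # duplicated thresholds give identical maps; extreme threshold near-zero map
  dup <- fcs_threshold_sweep(ts, c(0.2, 0.2))
  expect_identical(dup[[1]]$global, dup[[2]]$global)
  hi <- fcs_threshold_sweep(ts, 0.999)[[1]]
  expect_identical(sum(hi$global > 0), 0L)
})

test_that("FCS is equivariant under voxel permutation and time reversal", {
  set.seed(24)
  ts <- random_ts(40, 25)
  m <- fcs_maps(ts, 0.2, 9)
  perm <- sample(40)
  tsp <- voxel_ts(ts$values[perm, ], ts$coords_mm[perm, ],
                  grid_shape = ts$grid_shape, affine = ts$affine,
                  voxel_index = ts$voxel_index[perm])
  mp <- fcs_maps(tsp, 0.2, 9)
  expect_equal(mp$global[ts$voxel_index[perm]],
               m$global[ts$voxel_index[perm]], tolerance = 1e-12)

  tsr <- ts
  tsr$values <- ts$values[, ncol(ts$values):1]
  mr <- fcs_maps(tsr, 0.2, 9)
  expect_equal(mr$global, m$global, tolerance = 1e-10)
  expect_equal(mr$long, m$long, tolerance = 1e-10)
})

test_that("distance ties at the cutoff land in the short-range map", {
  sig <- rnorm(30)
  vals <- rbind(sig, sig)
  ts <- voxel_ts(vals, rbind(c(0, 0, 0), c(45, 60, 0)))  # exactly 75 mm
  m <- fcs_maps(ts, 0.2, 75)
  expect_identical(m$n_ties, 1)
  expect_true(all(m$long == 0))
  expect_gt(m$short[1], 0)
})

test_that("Gaussian smoothing behaves like its kernel", {
  const <- array(2.5, c(9, 9, 9))
  sm <- smooth_map(const, 6, 3)
  expect_equal(sm[5, 5, 5], 2.5, tolerance = 1e-9)  # interior unchanged

  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  sm2 <- smooth_map(imp, 6, 3)
  sigma <- 6 / (2 * sqrt(2 * log(2))) / 3
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2)); g <- g / sum(g)
  g0 <- g[r + 1L]
  expect_equal(sm2[5, 5, 5], g0^3, tolerance = 1e-12)
  expect_equal(sum(sm2), 1, tolerance = 1e-9)       # interior mass conserved

  expect_identical(smooth_map(imp, 0, 3), imp)      # fwhm 0 is the identity
  expect_error(smooth_map(imp, -1, 3), ">= 0")
})
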