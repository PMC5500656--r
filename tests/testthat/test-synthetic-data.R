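# Phantom generator: correlation targets, planted effects, determinism.

test_that("correlated_timeseries matches its target correlation", {
  set.seed(11)
  x <- correlated_timeseries(diag(3), 1000)
  rs <- cor(t(x))[upper.tri(diag(3))]
  expect_lt(max(abs(rs)), 0.15)

  set.seed(12)
  y <- correlated_timeseries(matrix(c(1, 0.9, 0.9, 1), 2), 2000)
  expect_lt(abs(cor(y[1, ], y[2, ]) - 0.9), 0.05)

  # rows exactly standardized
  expect_equal(rowMeans(y), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(y, 1, var), c(1, 1), tolerance = 1e-12)
})

test_that("correlated_timeseries rejects non-positive-definite input", {
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)   # eigenvalue -0.2
  expect_error(correlated_timeseries(bad, 100), "positive definite")
  expect_error(correlated_timeseries(bad, 100), "smallest eigenvalue",
               fixed = FALSE)
  expect_error(correlated_timeseries(matrix(c(1, 0.5, 0.4, 1), 2), 100),
               "symmetric")
})

test_that("correlated_timeseries is deterministic given the RNG seed", {
  C <- matrix(c(1, 0.4, 0.4, 1), 2)
  a <- rsfcs:::with_seed(5, correlated_timeseries(C, 50))
  b <- rsfcs:::with_seed(5, correlated_timeseries(C, 50))
  expect_identical(a, b)
})

test_that("motion traces honor amplitude and spikes", {
  set.seed(1)
  z <- make_motion_trace(100, amplitude_mm = 0, amplitude_deg = 0)
  expect_true(all(z == 0))
  expect_identical(dim(z), c(100L, 6L))

  tr <- make_motion_trace(100, spike = list(time = 50, axis = 1, size = 2.5))
  expect_gte(max(abs(tr[, 1])), 2.5)
  expect_identical(unname(tr[50, 1]), 2.5)

  a <- rsfcs:::with_seed(3, make_motion_trace(60))
  b <- rsfcs:::with_seed(3, make_motion_trace(60))
  expect_identical(a, b)
})

test_that("phantom cohorts are bit-identical under a fixed seed", {
  spec <- tiny_spec(7)
  a <- make_phantom_cohort(spec)
  b <- make_phantom_cohort(spec)
  expect_identical(a$subjects[[1]]$data, b$subjects[[1]]$data)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$motion, b$motion)
})

test_that("a null effect removes all group dependence from the generator", {
  spec <- tiny_spec(1, effect = effect_spec(delta_r = 0))
  C1 <- rsfcs:::subject_latent_corr(spec, 1L, 0.3)
  C2 <- rsfcs:::subject_latent_corr(spec, 2L, 0.3)
  expect_identical(C1, C2)
  coh <- make_phantom_cohort(spec)
  expect_false(any(coh$ground_truth$effect_map))
})

test_that("ground truth flags only hub and distance-qualified partners", {
  grid <- c(36L, 10L, 10L)
  net <- long_range_network(grid)
  spec <- cohort_spec(grid_shape = grid, n_per_group = c(2L, 2L),
                      n_timepoints = 30L, network = net,
                      effect = effect_spec(1L, 0.5, "long"), rng_seed = 2)
  coh <- make_phantom_cohort(spec)
  flagged <- which(coh$ground_truth$effect_map)
  expect_setequal(flagged, unlist(net$blocks))   # hub + every far partner
  # hub-partner centroid distances really exceed the cutoff
  aff <- coh$affine
  cent <- function(b) {
    colMeans(rsfcs:::voxel_to_mm(rsfcs:::index_to_ijk(b, grid), aff))
  }
  for (p in 2:length(net$blocks)) {
    expect_gt(sqrt(sum((cent(net$blocks[[1]]) - cent(net$blocks[[p]]))^2)), 75)
  }

  # same geometry, short-range effect spec: no partner qualifies
  spec_s <- cohort_spec(grid_shape = grid, n_per_group = c(2L, 2L),
                        n_timepoints = 30L, network = net,
                        effect = effect_spec(1L, 0.5, "short"), rng_seed = 2)
  coh_s <- make_phantom_cohort(spec_s)
  expect_false(any(coh_s$ground_truth$effect_map))
})

test_that("generated block correlations converge to their targets", {
  grid <- c(8L, 8L, 8L)
  spec <- cohort_spec(grid_shape = grid, n_per_group = c(1L, 1L),
                      n_timepoints = 2000L, rng_seed = 3,
                      drift_amplitude = 0)
  coh <- make_phantom_cohort(spec)
  net <- spec$network
  flat <- matrix(coh$subjects[[1]]$data, ncol = 2000)
  b1 <- flat[net$blocks[[1]], ]
  b2 <- flat[net$blocks[[2]], ]
  R11 <- cor(t(b1))
  expect_lt(abs(mean(R11[upper.tri(R11)]) - net$target_r_within), 0.05)
  R12 <- cor(t(b1), t(b2))
  expect_lt(abs(mean(R12) - net$target_r_between), 0.05)
})

test_that("clinical table carries the planted group contrasts", {
  coh <- make_phantom_cohort(cohort_spec(n_per_group = c(20L, 20L),
                                         rng_seed = 9))
  cl <- coh$clinical
  expect_identical(nrow(cl), 40L)
  tt <- t.test(hba1c ~ group, data = cl)
  expect_lt(tt$p.value, 1e-4)
  expect_lt(mean(cl$hba1c[cl$group == "control"]),
            mean(cl$hba1c[cl$group == "patient"]))
  expect_true(all(c("age", "gender", "education", "fbg", "mmse", "tmt_a")
                  %in% names(cl)))
})

test_that("degenerate cohort specs are rejected", {
  expect_error(cohort_spec(n_per_group = c(0L, 5L)), "positive")
  expect_error(cohort_spec(grid_shape = c(3L, 8L, 8L)), ">= 4")
  expect_error(cohort_spec(n_timepoints = 15L), "> 20")
})
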