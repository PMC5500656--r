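# Voxel GLM, smoothness estimation, Monte-Carlo extent, cluster extraction.

fake_glm <- function(tmap, mask, df = 20L, affine = NULL) {
  structure(list(tmap = tmap, df = df, residuals = NULL, mask = mask,
                 voxel_index = which(as.logical(mask)), affine = affine,
                 n_zero_variance = 0L),
            class = "voxel_glm")
}

test_that("intercept+group GLM reproduces the pooled-variance t-test", {
  set.seed(41)
  grid <- c(4L, 4L, 2L)
  mask <- array(TRUE, grid)
  n <- 14L
  g <- rep(c(0, 1), each = 7)
  maps <- lapply(seq_len(n), function(i) array(rnorm(prod(grid)), grid))
  X <- cbind(intercept = 1, group = g)
  fit <- fit_voxel_glm(maps, X, mask)
  expect_identical(fit$df, n - 2L)
  Y <- sapply(maps, function(m) as.vector(m))   # voxel x subject
  for (v in seq_len(prod(grid))) {
    tt <- t.test(Y[v, g == 1], Y[v, g == 0], var.equal = TRUE)
    expect_equal(fit$tmap[v], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected with the offending column", {
  grid <- c(3L, 3L, 3L)
  maps <- lapply(1:8, function(i) array(rnorm(27), grid))
  X <- cbind(intercept = 1, group = rep(0, 8))
  expect_error(fit_voxel_glm(maps, X, array(TRUE, grid)), "group")
})

test_that("covariate-adjusted GLM sees the planted deficit as negative T", {
  spec <- tiny_spec(17, effect = effect_spec(hub_block = 1, delta_r = 0.6,
                                             affected_range = "both"))
  coh <- make_phantom_cohort(spec)
  cfg <- run_config(n_sims = 50L)
  gm <- coh$gm_prob > 0.3
  maps <- lapply(seq_along(coh$subjects), function(s) {
    ts <- preprocess_subject(coh$subjects[[s]], coh$motion[[s]], gm,
                             coh$wm_mask, coh$csf_mask, cfg)
    fcs_maps(ts)$global
  })
  fit <- fit_voxel_glm(maps, build_design(coh$clinical), gm)
  hub <- coh$spec$network$blocks[[1]]
  bg <- setdiff(fit$voxel_index, unlist(coh$spec$network$blocks))
  expect_lt(mean(fit$tmap[hub]), mean(fit$tmap[bg]))
  expect_lt(mean(fit$tmap[hub]), 0)
})

test_that("smoothness estimates track the true field smoothness", {
  set.seed(42)
  grid <- c(12L, 12L, 12L)
  mask <- array(TRUE, grid)
  n <- 20
  X <- cbind(intercept = 1, group = rep(c(0, 1), each = 10))
  # spatially independent maps: FWHM about one voxel
  maps <- lapply(seq_len(n), function(i) array(rnorm(prod(grid)), grid))
  fit <- fit_voxel_glm(maps, X, mask)
  sm <- estimate_smoothness(fit, voxel_size_mm = 3)
  expect_true(all(abs(sm$fwhm_mm - 3) / 3 < 0.2))

  # maps smoothed with a known 6 mm kernel: composed kernel+lattice truth
  sm_maps <- lapply(maps, smooth_map, fwhm_mm = 6, voxel_size_mm = 3)
  fit2 <- fit_voxel_glm(sm_maps, X, mask)
  sm2 <- estimate_smoothness(fit2, voxel_size_mm = 3)
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  rho_true <- exp(-9 / (4 * sigma^2))          # lattice lag-1 autocorrelation
  fwhm_true <- 3 * sqrt(2 * log(2) / (1 - rho_true))
  expect_true(all(abs(sm2$fwhm_mm - fwhm_true) / fwhm_true < 0.15))

  expect_error(estimate_smoothness(array(1, grid), mask = mask), "constant")
})

test_that("connectivity definitions separate corner-touching blobs", {
  arr <- array(FALSE, c(6L, 6L, 6L))
  arr[1:2, 1:2, 1] <- TRUE                    # blob A
  arr[3, 3, 2] <- TRUE                        # touches A only at a corner
  lab18 <- label_clusters(arr, 18)
  expect_identical(max(lab18), 2L)
  lab26 <- label_clusters(arr, 26)
  expect_identical(max(lab26), 1L)

  # edge contact: joined under 18, separate under 6
  arr2 <- array(FALSE, c(6L, 6L, 6L))
  arr2[2, 2, 2] <- TRUE
  arr2[3, 3, 2] <- TRUE
  expect_identical(max(label_clusters(arr2, 6)), 2L)
  expect_identical(max(label_clusters(arr2, 18)), 1L)
})

test_that("Monte-Carlo minimum extent responds to smoothness and alpha", {
  mask <- array(TRUE, c(12L, 12L, 12L))
  a0 <- rsfcs:::with_seed(7, alphasim_min_extent(
    mask, c(0.3, 0.3, 0.3), voxel_p = 0.001, n_sims = 200, voxel_size_mm = 3
  ))
  expect_lte(a0$min_extent, 3L)               # near-independent voxels
  a1 <- rsfcs:::with_seed(7, alphasim_min_extent(
    mask, c(12, 12, 12), voxel_p = 0.001, n_sims = 200, voxel_size_mm = 3
  ))
  expect_gt(a1$min_extent, a0$min_extent)     # smoothness grows clusters

  atriv <- rsfcs:::with_seed(7, alphasim_min_extent(
    mask, c(3, 3, 3), voxel_p = 0.001, n_sims = 50, alpha = 1.0
  ))
  expect_identical(atriv$min_extent, 1L)

  # monotone in voxel_p: a looser voxel threshold cannot shrink the extent
  a2 <- rsfcs:::with_seed(7, alphasim_min_extent(
    mask, c(6, 6, 6), voxel_p = 0.01, n_sims = 200, voxel_size_mm = 3
  ))
  a3 <- rsfcs:::with_seed(7, alphasim_min_extent(
    mask, c(6, 6, 6), voxel_p = 0.001, n_sims = 200, voxel_size_mm = 3
  ))
  expect_gte(a2$min_extent, a3$min_extent)
})

test_that("cluster extraction honors extent, sign and connectivity", {
  grid <- c(8L, 8L, 8L)
  mask <- array(TRUE, grid)
  tmap <- array(0, grid)
  blob <- as.matrix(expand.grid(3:4, 3:4, 3)); blob <- rbind(blob, c(3, 3, 4))
  idx <- rsfcs:::ijk_to_index(blob, grid)
  tmap[idx] <- -6; tmap[rsfcs:::ijk_to_index(matrix(c(3, 3, 4), 1), grid)] <- -8
  fit <- fake_glm(tmap, mask, df = 12L, affine = diag(c(3, 3, 3, 1)))

  cl <- extract_clusters(fit, voxel_p = 0.001, min_extent = 4)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$sign, "decrease")
  expect_identical(cl$extent, 5L)
  expect_identical(cl$peak_t, -8)
  expect_equal(c(cl$peak_x, cl$peak_y, cl$peak_z), 3 * (c(3, 3, 4) - 1))

  expect_identical(nrow(extract_clusters(fit, 0.001, min_extent = 6)), 0L)

  # cluster-level p from a supplied null distribution
  cl2 <- extract_clusters(fit, 0.001, 4, null_max_extents = c(1:10))
  expect_equal(cl2$cluster_p, 0.6)

  sets <- cluster_voxel_sets(fit, 0.001, 4)
  expect_length(sets, 1L)
  expect_setequal(sets[[1]], idx)
})
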