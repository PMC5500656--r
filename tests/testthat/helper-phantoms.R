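# Shared fixtures: tiny cohorts and independent brute-force oracles.

# small, fast cohort for smoke/structure tests
tiny_spec <- function(seed = 1, ...) {
  cohort_spec(
    grid_shape = c(8L, 8L, 8L),
    n_per_group = c(4L, 4L),
    n_timepoints = 60L,
    rng_seed = seed,
    ...
  )
}

# random voxel_ts on a synthetic grid (coordinates from a 3 mm affine)
random_ts <- function(n_vox, n_time, grid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) {
    side <- ceiling(n_vox^(1 / 3)) + 1L
    grid <- c(side, side, side)
  }
  idx <- sort(sample.int(prod(grid), n_vox))
  aff <- diag(c(3, 3, 3, 1))
  coords <- rsfcs:::voxel_to_mm(rsfcs:::index_to_ijk(idx, grid), aff)
  voxel_ts(matrix(rnorm(n_vox * n_time), n_vox), coords,
           grid_shape = grid, affine = aff, voxel_index = idx)
}

# independent O(V^2) double-loop FCS oracle (deliberately naive)
oracle_fcs <- function(values, coords, r_threshold, cutoff_mm) {
  V <- nrow(values)
  long <- short <- global <- numeric(V)
  clip <- 1 - 1e-7
  for (i in seq_len(V)) {
    for (j in seq_len(V)) {
      if (i == j) next
      r <- cor(values[i, ], values[j, ])
      if (r > r_threshold) {
        z <- atanh(min(max(r, -clip), clip))
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        global[i] <- global[i] + z
        if (d > cutoff_mm) long[i] <- long[i] + z else short[i] <- short[i] + z
      }
    }
  }
  list(long = long, short = short, global = global)
}

# independent partial-correlation oracle via the precision matrix
oracle_partial_cor <- function(x, y, covs) {
  m <- cbind(x, y, as.matrix(covs))
  P <- solve(stats::cov(m))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# two series with an exact sample correlation r
exact_cor_pair <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  e <- residuals(lm(e ~ x))
  e <- e / sd(e)
  y <- r * x + sqrt(1 - r^2) * e
  rbind(x, y)
}
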