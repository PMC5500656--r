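# Canonical phantom study conditions shared by the examples, the test suite
# and the acceptance script. Each preset is a complete cohort_spec; the seed
# is the only free argument.

#' Null-calibration phantom: no planted effect
#'
#' 12 x 12 x 12 grid at 3 mm, 8 + 8 subjects, 180 volumes at TR 2 s, three
#' correlated blocks, `delta_r = 0`. The grid is deliberately desk-scale; at
#' this size no voxel pair exceeds the 75 mm cutoff, so the long-range map is
#' identically zero and family-wise error is evaluated on the short-range
#' contrast.
#'
#' @param seed cohort RNG seed.
#' @return a [cohort_spec()].
#' @export
preset_null <- function(seed) {
  cohort_spec(
    grid_shape = c(12L, 12L, 12L),
    n_per_group = c(8L, 8L),
    effect = effect_spec(delta_r = 0),
    rng_seed = seed
  )
}

#' Long-range planted-effect phantom
#'
#' Elongated 36 x 10 x 10 grid (105 mm along x at 3 mm voxels) with a hub and
#' a partner block of edge 4 separated by more than 75 mm, voxel-level
#' correlations 0.7 within / 0.5 between blocks, and a multiplicative
#' reduction `delta_r` of the hub--partner correlation in group 2. The
#' planted deficit is purely long-range: within-block (short-range)
#' correlations are identical across groups.
#'
#' @param seed cohort RNG seed.
#' @param delta_r multiplicative between-block correlation reduction in
#'   group 2 (default 0.5).
#' @return a [cohort_spec()].
#' @export
preset_long_effect <- function(seed, delta_r = 0.5) {
  grid <- c(36L, 10L, 10L)
  cohort_spec(
    grid_shape = grid,
    n_per_group = c(8L, 8L),
    network = long_range_network(grid),
    effect = effect_spec(hub_block = 1L, delta_r = delta_r,
                         affected_range = "long"),
    rng_seed = seed
  )
}

#' Clinical-coupling phantom for correlation recovery
#'
#' Compact 10 x 10 x 10 grid with a hub and a partner block (edge 4) whose
#' connectivity scale varies across subjects (`subject_sd`); HbA1c is drawn
#' coupled to that subject latent within each group (both groups), so the
#' ROI battery should recover a negative HbA1c--hub-FCS partial correlation.
#' 50 subjects per group by default.
#'
#' `coupling` is the target correlation between HbA1c and the *measured* hub
#' FCS. Because the per-subject FCS estimate carries finite-length sampling
#' noise (170 retained volumes), the correlation with the underlying latent
#' is attenuated by a factor of about 0.775 for this design (a fixed
#' property of its signal-to-noise composition); the latent mixing weight is
#' scaled by that factor so the planted HbA1c--FCS correlation lands on the
#' target.
#'
#' @param seed cohort RNG seed.
#' @param coupling target correlation between HbA1c and measured hub FCS
#'   (default -0.4).
#' @param n_per_group subjects per group.
#' @param subject_sd between-subject SD of the hub connectivity scale.
#' @return a [cohort_spec()].
#' @export
preset_coupled <- function(seed, coupling = -0.4, n_per_group = c(50L, 50L),
                           subject_sd = 0.4) {
  fcs_attenuation <- 0.775
  latent_weight <- max(-0.95, min(0.95, coupling / fcs_attenuation))
  grid <- c(10L, 10L, 10L)
  net <- network_spec(
    blocks = list(
      cube_block(c(2L, 2L, 2L), 4L, grid),
      cube_block(c(6L, 6L, 6L), 4L, grid)
    ),
    target_r_within = 0.6,
    target_r_between = 0.4
  )
  cohort_spec(
    grid_shape = grid,
    n_per_group = n_per_group,
    network = net,
    effect = effect_spec(hub_block = 1L, delta_r = 0,
                         affected_range = "both",
                         subject_sd = subject_sd),
    noise_sd = 1,
    rng_seed = seed,
    hba1c_coupling = latent_weight
  )
}
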