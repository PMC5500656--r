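# Cohort, network and effect specifications for the phantom generator.

#' Block network specification for a phantom cohort
#'
#' Describes the planted correlation structure: disjoint voxel blocks, each
#' driven by one latent signal, with a common within-block and between-block
#' voxel correlation target. Background voxels carry independent noise.
#'
#' @param blocks list of integer vectors; linear voxel indices (into the 3D
#'   grid, column-major) belonging to each block. Must be disjoint.
#' @param target_r_within voxel-level Pearson correlation between two voxels of
#'   the same block, in (0, 1).
#' @param target_r_between voxel-level correlation between voxels of different
#'   blocks, in `[0, target_r_within)`.
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(blocks, target_r_within = 0.5,
                         target_r_between = 0.2) {
  if (!is.list(blocks) || length(blocks) < 1L) {
    stop("`blocks` must be a non-empty list of voxel index vectors")
  }
  blocks <- lapply(blocks, function(b) sort(unique(as.integer(b))))
  all_idx <- unlist(blocks)
  if (anyDuplicated(all_idx)) {
    stop("network blocks must be disjoint voxel sets")
  }
  check_scalar(target_r_within, "target_r_within", 0, 1, strict_lower = TRUE)
  if (target_r_within >= 1) stop("`target_r_within` must be < 1")
  check_scalar(target_r_between, "target_r_between", 0)
  if (target_r_between >= target_r_within) {
    stop("`target_r_between` must be < `target_r_within`")
  }
  structure(
    list(blocks = blocks, target_r_within = target_r_within,
         target_r_between = target_r_between),
    class = "network_spec"
  )
}

#' Cubic voxel block for network construction
#'
#' @param corner 1-based (i, j, k) corner of the cube.
#' @param edge edge length in voxels.
#' @param grid_shape integer vector of 3 voxel counts.
#' @return sorted integer vector of linear voxel indices.
#' @export
cube_block <- function(corner, edge, grid_shape) {
  stopifnot(all(corner >= 1L), all(corner + edge - 1L <= grid_shape))
  ijk <- as.matrix(expand.grid(
    i = corner[1L] + seq_len(edge) - 1L,
    j = corner[2L] + seq_len(edge) - 1L,
    k = corner[3L] + seq_len(edge) - 1L
  ))
  sort(ijk_to_index(ijk, grid_shape))
}

#' Default block network for a compact phantom grid
#'
#' Places three cubic blocks in the grid interior (one voxel away from the
#' border, which the generator marks as non-gray-matter).
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param block_edge edge length of each cubic block, voxels.
#' @param target_r_within,target_r_between see [network_spec()].
#' @return a `network_spec`.
#' @export
default_network <- function(grid_shape, block_edge = 3L,
                            target_r_within = 0.5, target_r_between = 0.2) {
  grid_shape <- as.integer(grid_shape)
  e <- as.integer(block_edge)
  lo <- c(2L, 2L, 2L)
  hi <- grid_shape - e
  if (any(hi < lo)) stop("grid too small for the requested block edge")
  corners <- list(
    lo,
    c(hi[1L], hi[2L], lo[3L]),
    c(lo[1L], hi[2L], hi[3L])
  )
  network_spec(
    blocks = lapply(corners, cube_block, edge = e, grid_shape = grid_shape),
    target_r_within = target_r_within,
    target_r_between = target_r_between
  )
}

#' Hub-and-partners network separated by more than a distance cutoff
#'
#' Places a hub block at one end of the grid's first axis and `n_partners`
#' partner blocks at the other end, so that every hub--partner voxel pair
#' lies beyond `cutoff_mm`. A hub coupled to several remote regions (each
#' with its own latent signal) mirrors the multi-region connectivity pattern
#' the long-range FCS measure targets, and averages independent
#' latent-correlation sampling noise across partners. Requires an elongated
#' grid (e.g. 36 x 10 x 10 at 3 mm).
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @param voxel_size_mm isotropic voxel size in mm.
#' @param cutoff_mm anatomical distance cutoff every pair must exceed.
#' @param block_edge edge length of each cubic block, voxels.
#' @param n_partners number of partner blocks (1--3) at the far end.
#' @param target_r_within,target_r_between see [network_spec()].
#' @return a `network_spec` whose first block is the hub.
#' @export
long_range_network <- function(grid_shape, voxel_size_mm = 3,
                               cutoff_mm = 75, block_edge = 4L,
                               n_partners = 3L,
                               target_r_within = 0.7,
                               target_r_between = 0.5) {
  grid_shape <- as.integer(grid_shape)
  e <- as.integer(block_edge)
  n_partners <- as.integer(n_partners)
  stopifnot(n_partners >= 1L, n_partners <= 3L)
  far_x <- grid_shape[1L] - e
  # nearest pair: hub max-x face to partner min-x face (y/z may coincide)
  min_gap <- (far_x - (2L + e - 1L)) * voxel_size_mm
  if (min_gap <= cutoff_mm) {
    stop(sprintf(
      "grid of %d voxels along x at %g mm cannot separate hub and partner by > %g mm",
      grid_shape[1L], voxel_size_mm, cutoff_mm
    ))
  }
  lo <- 2L
  hi <- grid_shape[2:3] - e
  if (any(hi < lo)) stop("grid too small for the requested block edge")
  corners <- list(
    c(far_x, lo, lo),
    c(far_x, hi[1L], hi[2L]),
    c(far_x, lo, hi[2L])
  )[seq_len(n_partners)]
  # partner blocks must not overlap in the y/z plane
  if (n_partners > 1L && any(hi < lo + e)) {
    stop("grid cross-section too small for multiple disjoint partner blocks")
  }
  network_spec(
    blocks = c(list(cube_block(c(2L, 2L, 2L), e, grid_shape)),
               lapply(corners, cube_block, edge = e,
                      grid_shape = grid_shape)),
    target_r_within = target_r_within,
    target_r_between = target_r_between
  )
}

#' Planted group-effect specification
#'
#' Describes how group 2 (patients) differs from group 1: the between-block
#' correlations of one hub block are reduced multiplicatively by `delta_r` in
#' group-2 subjects. `affected_range` selects which partner blocks are
#' reduced, by hub-to-partner centroid distance relative to `cutoff_mm`.
#'
#' @param hub_block index (into `network$blocks`) of the hub block.
#' @param delta_r multiplicative reduction in (0, 1]; 0 plants no effect.
#' @param affected_range one of `"long"`, `"short"`, `"both"`.
#' @param cutoff_mm distance cutoff classifying partners as long/short range.
#' @param subject_sd between-subject SD of the hub's connectivity scale (both
#'   groups); drives individual differences used by correlation-recovery
#'   phantoms. 0 makes all subjects of a group exchangeable.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(hub_block = 1L, delta_r = 0,
                        affected_range = c("long", "short", "both"),
                        cutoff_mm = 75, subject_sd = 0) {
  affected_range <- match.arg(affected_range)
  check_scalar(delta_r, "delta_r", 0, 1)
  check_scalar(subject_sd, "subject_sd", 0)
  check_scalar(cutoff_mm, "cutoff_mm", 0, strict_lower = TRUE)
  structure(
    list(hub_block = as.integer(hub_block), delta_r = delta_r,
         affected_range = affected_range, cutoff_mm = cutoff_mm,
         subject_sd = subject_sd),
    class = "effect_spec"
  )
}

#' Full description of a synthetic two-group cohort
#'
#' Collects geometry, acquisition constants, network structure, planted
#' effect, noise and seeds. Defaults mirror a typical 3 T resting-state
#' acquisition: 3 mm isotropic voxels, TR = 2 s, 180 volumes of which the
#' first 10 are discarded downstream.
#'
#' @param grid_shape integer vector of 3 voxel counts, each >= 4.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param n_timepoints acquired volumes per subject (> 20).
#' @param tr_seconds repetition time, seconds.
#' @param n_per_group integer pair: subjects in group 1 (controls) and group 2
#'   (patients).
#' @param network a [network_spec()]; defaults to [default_network()] on the
#'   grid.
#' @param effect an [effect_spec()].
#' @param noise_sd SD of the voxel signal scale (correlations are unaffected).
#' @param rng_seed integer seed; the cohort is a deterministic function of the
#'   spec.
#' @param hba1c_coupling target correlation (usually negative) between HbA1c
#'   and the subject-level hub-connectivity latent, applied within each group;
#'   0 leaves HbA1c independent of the brain data. Requires
#'   `effect$subject_sd > 0` to be recoverable.
#' @param qc_fail_subjects integer indices of subjects whose motion trace gets
#'   a 2.5 mm translation spike (fails the 2 mm QC limit).
#' @param drift_amplitude amplitude (in units of `noise_sd`) of a shared
#'   0.005 Hz scanner drift added to every voxel; removed by the band-pass.
#' @param baseline constant added to every voxel (BOLD-like mean level).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(grid_shape = c(12L, 12L, 12L), voxel_size_mm = 3,
                        n_timepoints = 180L, tr_seconds = 2,
                        n_per_group = c(8L, 8L), network = NULL,
                        effect = effect_spec(), noise_sd = 1,
                        rng_seed = 1L, hba1c_coupling = 0,
                        qc_fail_subjects = integer(0),
                        drift_amplitude = 0.3, baseline = 100) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L)) {
    stop("`grid_shape` must be 3 integers, all >= 4")
  }
  check_scalar(voxel_size_mm, "voxel_size_mm", 0, strict_lower = TRUE)
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints <= 20L) stop("`n_timepoints` must be > 20")
  check_scalar(tr_seconds, "tr_seconds", 0, strict_lower = TRUE)
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) != 2L || any(n_per_group < 1L)) {
    stop("`n_per_group` must be two positive integers")
  }
  if (is.null(network)) network <- default_network(grid_shape)
  stopifnot(inherits(network, "network_spec"), inherits(effect, "effect_spec"))
  n_vox <- prod(grid_shape)
  if (max(unlist(network$blocks)) > n_vox) {
    stop("network block indices exceed the grid")
  }
  if (effect$hub_block > length(network$blocks)) {
    stop("`effect$hub_block` exceeds the number of network blocks")
  }
  check_scalar(noise_sd, "noise_sd", 0, strict_lower = TRUE)
  check_scalar(hba1c_coupling, "hba1c_coupling", -1, 1)
  check_scalar(drift_amplitude, "drift_amplitude", 0)
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
         n_timepoints = n_timepoints, tr_seconds = tr_seconds,
         n_per_group = n_per_group, network = network, effect = effect,
         noise_sd = noise_sd, rng_seed = as.integer(rng_seed),
         hba1c_coupling = hba1c_coupling,
         qc_fail_subjects = as.integer(qc_fail_subjects),
         drift_amplitude = drift_amplitude, baseline = baseline),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec:",
      sprintf("%d x %d x %d grid @ %g mm,", x$grid_shape[1], x$grid_shape[2],
              x$grid_shape[3], x$voxel_size_mm),
      sprintf("%d volumes, TR %g s\n", x$n_timepoints, x$tr_seconds))
  cat(sprintf("  groups: %d controls + %d patients; %d blocks (r_within %.2f, r_between %.2f)\n",
              x$n_per_group[1], x$n_per_group[2], length(x$network$blocks),
              x$network$target_r_within, x$network$target_r_between))
  cat(sprintf("  effect: hub block %d, delta_r %.2f, range '%s'; seed %d\n",
              x$effect$hub_block, x$effect$delta_r, x$effect$affected_range,
              x$rng_seed))
  invisible(x)
}
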