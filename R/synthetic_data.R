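# Synthetic two-group 4D BOLD phantoms with known planted structure.

#' A 4D BOLD image
#'
#' Minimal container for a subject-level 4D volume: intensity array,
#' voxel-to-mm affine, and repetition time.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param affine 4x4 voxel-to-mm affine (0-based voxel indices).
#' @param tr_seconds repetition time in seconds.
#' @return an object of class `bold_image`.
#' @export
bold_image <- function(data, affine, tr_seconds) {
  stopifnot(is.array(data), length(dim(data)) == 4L,
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  check_scalar(tr_seconds, "tr_seconds", 0, strict_lower = TRUE)
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_image: %d x %d x %d voxels, %d volumes, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}

#' Generate node time series with a prescribed correlation matrix
#'
#' Draws `n_timepoints` samples of a multivariate Gaussian with the given
#' correlation matrix (via its Cholesky factor applied to independent
#' innovations), then standardizes each node's series to exactly zero mean
#' and unit variance. The expected sample correlation equals `corr_matrix`.
#'
#' @param corr_matrix symmetric positive-definite matrix with unit diagonal.
#' @param n_timepoints number of time points (>= 3).
#' @return node x time matrix; rows have mean 0 and variance 1.
#' @examples
#' set.seed(1)
#' x <- correlated_timeseries(diag(3), 200)
#' max(abs(cor(t(x))[upper.tri(diag(3))]))  # near 0
#' @export
correlated_timeseries <- function(corr_matrix, n_timepoints) {
  corr_matrix <- as.matrix(corr_matrix)
  n <- nrow(corr_matrix)
  if (ncol(corr_matrix) != n) stop("`corr_matrix` must be square")
  if (max(abs(corr_matrix - t(corr_matrix))) > 1e-8) {
    stop("`corr_matrix` must be symmetric")
  }
  if (max(abs(diag(corr_matrix) - 1)) > 1e-8) {
    stop("`corr_matrix` must have unit diagonal")
  }
  n_timepoints <- as.integer(n_timepoints)
  if (n_timepoints < 3L) stop("`n_timepoints` must be >= 3")
  ch <- tryCatch(chol(corr_matrix), error = function(e) NULL)
  if (is.null(ch)) {
    ev <- min(eigen(corr_matrix, symmetric = TRUE, only.values = TRUE)$values)
    stop(sprintf(
      "`corr_matrix` is not positive definite (smallest eigenvalue %.3e)", ev
    ))
  }
  z <- matrix(rnorm(n * n_timepoints), nrow = n)
  x <- crossprod(ch, z)           # t(ch) %*% z has covariance corr_matrix
  x <- x - rowMeans(x)
  x / sqrt(rowSums(x^2) / (n_timepoints - 1))
}

#' Generate a six-parameter rigid-body motion trace
#'
#' Smooth random-walk translations (mm) and rotations (degrees), optionally
#' with one sample forced to a given size to emulate a sudden head jerk.
#'
#' @param n_timepoints number of time points.
#' @param amplitude_mm typical excursion scale of the translation walks; 0
#'   gives all-zero translations.
#' @param amplitude_deg same for rotations.
#' @param spike optional list `(time, axis, size)`; `axis` in 1..6 (1--3
#'   translations x/y/z, 4--6 rotations) or a column name. That sample is set
#'   to exactly `size`.
#' @return time x 6 matrix with columns trans_x/y/z (mm), rot_x/y/z (deg).
#' @export
make_motion_trace <- function(n_timepoints, amplitude_mm = 0.2,
                              amplitude_deg = 0.2, spike = NULL) {
  n_timepoints <- as.integer(n_timepoints)
  stopifnot(n_timepoints >= 1L)
  check_scalar(amplitude_mm, "amplitude_mm", 0)
  check_scalar(amplitude_deg, "amplitude_deg", 0)
  walk <- function(amp) {
    if (amp == 0) return(numeric(n_timepoints))
    cumsum(rnorm(n_timepoints, sd = amp / sqrt(n_timepoints)))
  }
  tr <- vapply(1:3, function(i) walk(amplitude_mm), numeric(n_timepoints))
  ro <- vapply(1:3, function(i) walk(amplitude_deg), numeric(n_timepoints))
  trace <- cbind(tr, ro)
  colnames(trace) <- c("trans_x", "trans_y", "trans_z",
                       "rot_x", "rot_y", "rot_z")
  if (!is.null(spike)) {
    ax <- spike$axis
    if (is.character(ax)) ax <- match(ax, colnames(trace))
    stopifnot(!is.na(ax), ax >= 1L, ax <= 6L,
              spike$time >= 1L, spike$time <= n_timepoints)
    trace[spike$time, ax] <- spike$size
  }
  trace
}

# latent (block-level) correlation matrix for one subject
subject_latent_corr <- function(spec, group, u) {
  net <- spec$network
  eff <- spec$effect
  n_blocks <- length(net$blocks)
  rho <- net$target_r_between / net$target_r_within
  C <- matrix(rho, n_blocks, n_blocks)
  diag(C) <- 1
  if (n_blocks > 1L) {
    affected <- affected_partners(spec)
    scale <- 1
    if (eff$subject_sd > 0) scale <- scale * (1 + eff$subject_sd * u)
    if (group == 2L && eff$delta_r > 0) scale <- scale * (1 - eff$delta_r)
    scale <- min(max(scale, 0.01), 0.99 / max(rho, 1e-12))
    for (p in affected) {
      C[eff$hub_block, p] <- C[p, eff$hub_block] <- rho * scale
    }
  }
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) {
    stop(sprintf(
      "planted effect makes the latent correlation matrix non-positive-definite (smallest eigenvalue %.3e)",
      ev
    ))
  }
  C
}

# partner blocks affected by the hub effect, classified by centroid distance
affected_partners <- function(spec) {
  net <- spec$network
  eff <- spec$effect
  n_blocks <- length(net$blocks)
  partners <- setdiff(seq_len(n_blocks), eff$hub_block)
  if (eff$affected_range == "both" || length(partners) == 0L) return(partners)
  aff <- phantom_affine(spec$grid_shape, spec$voxel_size_mm)
  centroid <- function(b) {
    colMeans(voxel_to_mm(index_to_ijk(b, spec$grid_shape), aff))
  }
  hub_c <- centroid(net$blocks[[eff$hub_block]])
  d <- vapply(partners, function(p) {
    sqrt(sum((centroid(net$blocks[[p]]) - hub_c)^2))
  }, numeric(1))
  if (eff$affected_range == "long") partners[d > eff$cutoff_mm]
  else partners[d < eff$cutoff_mm]
}

# border voxels of the grid, split into WM / CSF halves
border_masks <- function(grid_shape) {
  arr <- array(TRUE, grid_shape)
  arr[2:(grid_shape[1] - 1), 2:(grid_shape[2] - 1),
      2:(grid_shape[3] - 1)] <- FALSE
  border <- which(arr)
  half <- seq_len(ceiling(length(border) / 2))
  wm <- array(FALSE, grid_shape); wm[border[half]] <- TRUE
  csf <- array(FALSE, grid_shape); csf[border[-half]] <- TRUE
  list(wm = wm, csf = csf, border = border)
}

#' Generate a synthetic two-group phantom cohort
#'
#' Produces per-subject 4D BOLD images and motion traces, a gray-matter
#' probability map, WM/CSF masks, a clinical table, and ground truth (block
#' label map, planted-effect map, per-subject latents). Group-2 subjects'
#' hub-block between-block correlations are reduced per the effect spec; the
#' clinical HbA1c contrast between groups is large, and HbA1c can optionally
#' be coupled to the subject-level hub connectivity for correlation-recovery
#' experiments.
#'
#' The cohort is a deterministic function of the spec (including its
#' `rng_seed`); the caller's RNG state is left untouched.
#'
#' @param spec a [cohort_spec()].
#' @return a list of class `phantom_cohort` with elements `subjects` (list of
#'   `bold_image`), `motion` (list of time x 6 matrices), `gm_prob` (3D
#'   probability array), `wm_mask`, `csf_mask` (3D logical), `clinical`
#'   (data.frame), `ground_truth`, `affine`, and `spec`.
#' @export
make_phantom_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (any(spec$n_per_group == 0L)) stop("`n_per_group` must be positive")
  with_seed(spec$rng_seed, generate_cohort(spec))
}

generate_cohort <- function(spec) {
  grid <- spec$grid_shape
  n_vox <- prod(grid)
  T_all <- spec$n_timepoints
  n1 <- spec$n_per_group[1L]
  n2 <- spec$n_per_group[2L]
  n_sub <- n1 + n2
  group <- rep(c(1L, 2L), c(n1, n2))
  aff <- phantom_affine(grid, spec$voxel_size_mm)
  net <- spec$network

  bm <- border_masks(grid)
  gm_prob <- array(0.9, grid)
  gm_prob[bm$border] <- 0.1

  block_map <- array(0L, grid)
  for (b in seq_along(net$blocks)) block_map[net$blocks[[b]]] <- b

  affected <- affected_partners(spec)
  effect_map <- array(FALSE, grid)
  if (spec$effect$delta_r > 0 && length(affected) > 0L) {
    effect_map[net$blocks[[spec$effect$hub_block]]] <- TRUE
    for (p in affected) effect_map[net$blocks[[p]]] <- TRUE
  }

  u <- rnorm(n_sub)                        # subject hub-connectivity latent
  w <- net$target_r_within
  block_of <- block_map[seq_len(n_vox)]    # 0 = background / border
  in_border <- array(FALSE, grid); in_border[bm$border] <- TRUE
  t_sec <- (seq_len(T_all) - 1) * spec$tr_seconds

  subjects <- vector("list", n_sub)
  motion <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    C <- subject_latent_corr(spec, group[s], u[s])
    S <- correlated_timeseries(C, T_all)   # blocks x time
    vol <- matrix(rnorm(n_vox * T_all), n_vox, T_all)
    for (b in seq_along(net$blocks)) {
      idx <- net$blocks[[b]]
      vol[idx, ] <- sqrt(w) * matrix(S[b, ], length(idx), T_all, byrow = TRUE) +
        sqrt(1 - w) * vol[idx, ]
    }
    # shared WM / CSF compartment signals on the border
    wm_sig <- rnorm(T_all); csf_sig <- rnorm(T_all)
    wm_idx <- which(bm$wm); csf_idx <- which(bm$csf)
    vol[wm_idx, ] <- sqrt(0.7) * matrix(wm_sig, length(wm_idx), T_all,
                                        byrow = TRUE) +
      sqrt(0.3) * vol[wm_idx, ]
    vol[csf_idx, ] <- sqrt(0.7) * matrix(csf_sig, length(csf_idx), T_all,
                                         byrow = TRUE) +
      sqrt(0.3) * vol[csf_idx, ]
    if (spec$drift_amplitude > 0) {
      # drift sits on a Fourier bin of the retained (post-discard) window so
      # the ideal band-pass removes it exactly; ~0.006 Hz for 170 x 2 s
      drift_hz <- 2 / ((T_all - 10) * spec$tr_seconds)
      drift <- spec$drift_amplitude *
        sin(2 * pi * drift_hz * t_sec + runif(1, 0, 2 * pi))
      vol <- vol + matrix(drift, n_vox, T_all, byrow = TRUE)
    }
    vol <- vol * spec$noise_sd + spec$baseline
    subjects[[s]] <- bold_image(array(vol, c(grid, T_all)), aff,
                                spec$tr_seconds)
    spike <- if (s %in% spec$qc_fail_subjects) {
      list(time = min(50L, T_all), axis = 1L, size = 2.5)
    }
    motion[[s]] <- make_motion_trace(T_all, spike = spike)
  }

  clinical <- generate_clinical(n1, n2, u, spec$hba1c_coupling)

  structure(list(
    subjects = subjects,
    motion = motion,
    gm_prob = gm_prob,
    wm_mask = bm$wm,
    csf_mask = bm$csf,
    clinical = clinical,
    ground_truth = list(
      block_map = block_map, effect_map = effect_map,
      hub_block = spec$effect$hub_block, affected_partners = affected,
      subject_latent = u, group = group
    ),
    affine = aff,
    spec = spec
  ), class = "phantom_cohort")
}

# Clinical table with Table-1-like marginals: matched demographics, large
# HbA1c / FBG group contrast, cognition equivalent across groups. `coupling`
# mixes the subject hub latent into HbA1c within each group.
generate_clinical <- function(n1, n2, u, coupling) {
  n <- n1 + n2
  group <- rep(c("control", "patient"), c(n1, n2))
  gender <- unlist(lapply(c(n1, n2), function(k) {
    rep_len(c("M", "F"), k)[sample.int(k)]
  }))
  age <- round(c(rnorm(n1, 55.2, 7.0), rnorm(n2, 56.2, 7.7)))
  education <- pmax(1, round(c(rnorm(n1, 10.9, 2.7), rnorm(n2, 11.4, 3.2))))
  hba1c_noise <- rnorm(n)
  if (coupling != 0) {
    us <- (u - mean(u)) / sd(u)
    mix <- coupling * us + sqrt(1 - coupling^2) * hba1c_noise
  } else {
    mix <- hba1c_noise
  }
  hba1c <- ifelse(group == "patient", 8.6 + 2.05 * mix, 5.6 + 0.35 * mix)
  fbg <- ifelse(group == "patient", rnorm(n, 8.33, 2.70), rnorm(n, 5.13, 0.67))
  data.frame(
    subject = sprintf("sub-%03d", seq_len(n)),
    group = group,
    age = age,
    gender = gender,
    education = education,
    hba1c = round(hba1c, 2),
    fbg = round(pmax(fbg, 3), 2),
    mmse = pmin(30, round(rnorm(n, 29.2, 1.0))),
    tmt_a = round(pmax(rnorm(n, 60, 27), 12), 1),
    stringsAsFactors = FALSE
  )
}
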