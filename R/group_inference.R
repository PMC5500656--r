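# Voxel-wise covariate-adjusted two-group inference with Monte-Carlo
# cluster-extent correction.

#' Build the group-comparison design matrix
#'
#' Columns: intercept, group indicator (patient = 1, control = 0), age,
#' gender (male = 1, female = 0; the coding cannot change the group-contrast
#' T), years of education. With this coding a positive group-contrast T means
#' patients > controls, so a planted patient weakness appears as negative T.
#'
#' @param clinical data.frame with columns `group` ("patient"/"control"),
#'   `age`, `gender` ("M"/"F"), `education`.
#' @return subjects x 5 numeric design matrix.
#' @export
build_design <- function(clinical) {
  need <- c("group", "age", "gender", "education")
  missing_cols <- setdiff(need, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(clinical[need])) stop("clinical covariates contain missing values")
  X <- cbind(
    intercept = 1,
    group = as.numeric(clinical$group == "patient"),
    age = as.numeric(clinical$age),
    gender = as.numeric(clinical$gender == "M"),
    education = as.numeric(clinical$education)
  )
  X
}

# list of 3D arrays -> subjects x voxel matrix over mask indices
stack_maps <- function(maps, voxel_index) {
  do.call(rbind, lapply(maps, function(m) as.vector(m)[voxel_index]))
}

#' Voxel-wise general linear model with a group contrast
#'
#' Ordinary least squares per voxel; T = contrast estimate / standard error
#' with `df = N - p`. With an intercept + group design this reduces exactly
#' to the pooled-variance two-sample t-test. Residuals are returned for
#' smoothness estimation. Voxels whose residual variance is numerically zero
#' (e.g. a map that is identically constant across subjects) get T = 0.
#'
#' @param maps list of per-subject 3D maps (aligned grids), one per row of
#'   the design.
#' @param design subjects x p design matrix (see [build_design()]); must be
#'   full column rank.
#' @param mask 3D logical analysis mask.
#' @param contrast column name or numeric length-p contrast vector selecting
#'   the effect to test (default `"group"`).
#' @param affine optional 4x4 affine carried into cluster tables.
#' @return an object of class `voxel_glm`: `tmap` (3D), `df`, `residuals`
#'   (subjects x voxel), `mask`, `voxel_index`, `affine`, `n_zero_variance`.
#' @export
fit_voxel_glm <- function(maps, design, mask, contrast = "group",
                          affine = NULL) {
  design <- as.matrix(design)
  n <- nrow(design)
  p <- ncol(design)
  if (length(maps) != n) stop("number of maps must match design rows")
  if (n < p + 2L) stop("need at least p + 2 subjects")
  qrX <- qr(design)
  if (qrX$rank < p) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.character(contrast)) {
    stopifnot(contrast %in% colnames(design))
    cvec <- as.numeric(colnames(design) == contrast)
  } else {
    cvec <- as.numeric(contrast)
    stopifnot(length(cvec) == p)
  }
  mask <- as.array(mask)
  voxel_index <- which(as.logical(mask))
  Y <- stack_maps(maps, voxel_index)
  xtx_inv <- chol2inv(chol(crossprod(design)))
  B <- xtx_inv %*% crossprod(design, Y)
  resid <- Y - design %*% B
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  cvar <- drop(t(cvec) %*% xtx_inv %*% cvec)
  est <- drop(cvec %*% B)
  se <- sqrt(cvar * sigma2)
  tval <- ifelse(se > 0, est / se, 0)
  n_zero <- sum(se <= 0)
  tmap <- array(0, dim(mask))
  tmap[voxel_index] <- tval
  structure(list(
    tmap = tmap, df = df, residuals = resid, mask = mask,
    voxel_index = voxel_index, affine = affine, contrast = cvec,
    n_zero_variance = n_zero
  ), class = "voxel_glm")
}

#' @export
print.voxel_glm <- function(x, ...) {
  cat(sprintf("voxel_glm: %d voxels, df = %d, max |T| = %.2f\n",
              length(x$voxel_index), x$df, max(abs(x$tmap))))
  invisible(x)
}

#' Estimate spatial smoothness (per-axis FWHM) of a statistic field
#'
#' Difference-variance estimator on standardized GLM residuals: for each
#' axis, the lag-1 spatial autocorrelation is `rho = 1 - var(diff) / (2 var)`
#' over in-mask neighbor pairs, and the field FWHM is
#' `voxel_size * sqrt(2 ln 2 / (1 - rho))`. Spatially independent voxels give
#' FWHM about 1.18 voxel (the lattice's own resolution); a field smoothed
#' with a Gaussian kernel recovers the composed kernel + lattice smoothness.
#' When residuals are absent the same estimator is applied to the T map
#' itself.
#'
#' @param fit a `voxel_glm`, or a 3D statistic map (then `mask` is required).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param mask 3D logical mask (only when `fit` is a bare map).
#' @return object of class `smoothness`: `fwhm_mm` (length 3), `rho`
#'   (lag-1 autocorrelation per axis), `method`, `voxel_size_mm`.
#' @export
estimate_smoothness <- function(fit, voxel_size_mm = 3, mask = NULL) {
  if (inherits(fit, "voxel_glm")) {
    grid <- dim(fit$mask)
    idx <- fit$voxel_index
    r <- fit$residuals
    sds <- apply(r, 2L, sd)
    if (all(sds <= .Machine$double.eps)) {
      stop("residuals are degenerate (zero variance everywhere)")
    }
    keep <- sds > .Machine$double.eps
    r <- scale(r[, keep, drop = FALSE])
    idx <- idx[keep]
    values <- r
    method <- "residuals"
  } else {
    stopifnot(is.array(fit), length(dim(fit)) == 3L, !is.null(mask))
    grid <- dim(fit)
    idx <- which(as.logical(mask))
    v <- as.vector(fit)[idx]
    if (sd(v) <= .Machine$double.eps) stop("map is constant inside the mask")
    values <- matrix((v - mean(v)) / sd(v), nrow = 1L)
    method <- "tmap"
  }
  if (length(idx) < 2L) stop("mask must contain at least 2 voxels")
  ijk <- index_to_ijk(idx, grid)
  rho <- fwhm <- numeric(3L)
  for (axis in 1:3) {
    nb <- ijk
    nb[, axis] <- nb[, axis] + 1L
    ok <- nb[, axis] <= grid[axis]
    pos2 <- match(ijk_to_index(nb[ok, , drop = FALSE], grid), idx)
    p1 <- which(ok)[!is.na(pos2)]
    p2 <- pos2[!is.na(pos2)]
    if (length(p1) == 0L) {
      rho[axis] <- 0
      fwhm[axis] <- voxel_size_mm * sqrt(2 * log(2))
      next
    }
    d <- values[, p2, drop = FALSE] - values[, p1, drop = FALSE]
    # normalize by the realized mean square (columns are standardized with
    # the n-1 denominator, so their mean square is (n-1)/n, not 1)
    rho[axis] <- min(1 - mean(d^2) / (2 * mean(values^2)), 0.999)
    fwhm[axis] <- voxel_size_mm * sqrt(2 * log(2) / (1 - rho[axis]))
  }
  fwhm <- pmax(fwhm, 0.1 * voxel_size_mm)
  structure(list(fwhm_mm = fwhm, rho = rho, method = method,
                 voxel_size_mm = voxel_size_mm),
            class = "smoothness")
}

#' @export
print.smoothness <- function(x, ...) {
  cat(sprintf("smoothness (%s): FWHM = %.2f x %.2f x %.2f mm\n",
              x$method, x$fwhm_mm[1], x$fwhm_mm[2], x$fwhm_mm[3]))
  invisible(x)
}

# kernel sigma (voxels) whose discretely-convolved white noise matches a
# target lag-1 lattice autocorrelation
sigma_for_rho <- function(rho_target) {
  if (rho_target <= 1e-4) return(0)
  rho_target <- min(rho_target, 0.995)
  disc_rho <- function(sigma) {
    r <- max(1L, ceiling(4 * sigma))
    g <- exp(-(-r:r)^2 / (2 * sigma^2))
    sum(g[-length(g)] * g[-1]) / sum(g^2)
  }
  uniroot(function(s) disc_rho(s) - rho_target,
          interval = c(0.05, 12), tol = 1e-6)$root
}

# neighbor offsets (half set) for 6/18/26-connectivity
connectivity_offsets <- function(connectivity) {
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(d))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1L,
    "18" = nz >= 1L & nz <= 2L,
    "26" = nz >= 1L
  )
  d <- d[keep, , drop = FALSE]
  # lexicographically positive half (each undirected pair once)
  pos <- d[, 1] > 0 | (d[, 1] == 0 & d[, 2] > 0) |
    (d[, 1] == 0 & d[, 2] == 0 & d[, 3] > 0)
  d[pos, , drop = FALSE]
}

#' Label connected components of a 3D binary image
#'
#' Union-find over voxel adjacencies. `connectivity` 6 connects faces, 18
#' faces + edges (the AlphaSim "edge connected" neighborhood), 26 adds
#' corners.
#'
#' @param arr 3D logical array.
#' @param connectivity 6, 18, or 26.
#' @return integer 3D array; 0 = background, components numbered from 1.
#' @export
label_clusters <- function(arr, connectivity = 18L) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  grid <- dim(arr)
  idx <- which(arr != 0)
  out <- array(0L, grid)
  n <- length(idx)
  if (n == 0L) return(out)
  ijk <- index_to_ijk(idx, grid)
  offsets <- connectivity_offsets(as.integer(connectivity))
  e1 <- integer(0); e2 <- integer(0)
  for (m in seq_len(nrow(offsets))) {
    nb <- sweep(ijk, 2L, offsets[m, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= grid[1] &
      nb[, 2] >= 1L & nb[, 2] <= grid[2] &
      nb[, 3] >= 1L & nb[, 3] <= grid[3]
    pos2 <- match(ijk_to_index(nb[ok, , drop = FALSE], grid), idx)
    hit <- !is.na(pos2)
    e1 <- c(e1, which(ok)[hit])
    e2 <- c(e2, pos2[hit])
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(e1)) {
    ra <- find(e1[k]); rb <- find(e2[k])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out[idx] <- match(roots, unique(roots))
  out
}

#' Monte-Carlo (AlphaSim-style) minimum cluster extent
#'
#' Estimates the null distribution of the maximum suprathreshold cluster size
#' in smooth Gaussian noise: each simulation generates white noise on the
#' grid, smooths it so its lattice autocorrelation matches the supplied field
#' smoothness, restandardizes within the mask, applies a two-sided threshold
#' at `|z| >= qnorm(1 - voxel_p / 2)`, and records the maximum cluster extent
#' under the given connectivity. Returns the smallest extent `k` with
#' `P(max extent >= k) <= alpha`.
#'
#' @param mask 3D logical analysis mask (>= 2 voxels).
#' @param fwhm a `smoothness` object or numeric length-3 field FWHM, mm.
#' @param voxel_p cluster-forming (per-voxel) p, two-sided; default 0.001.
#' @param n_sims number of simulations (default 1000).
#' @param alpha cluster-level family-wise error rate (default 0.05).
#' @param connectivity 6, 18 (default; faces + edges), or 26.
#' @param voxel_size_mm isotropic voxel size, mm.
#' @return object of class `alphasim`: `min_extent`, `max_extents` (length
#'   `n_sims`), `sigma_vox`, plus the call parameters.
#' @export
alphasim_min_extent <- function(mask, fwhm, voxel_p = 0.001, n_sims = 1000L,
                                alpha = 0.05, connectivity = 18L,
                                voxel_size_mm = 3) {
  mask <- as.array(mask)
  idx <- which(as.logical(mask))
  if (length(idx) < 2L) stop("mask must contain at least 2 voxels")
  check_scalar(voxel_p, "voxel_p", 0, 1, strict_lower = TRUE)
  if (voxel_p >= 1) stop("`voxel_p` must be < 1")
  check_scalar(alpha, "alpha", 0, 1, strict_lower = TRUE)
  if (inherits(fwhm, "smoothness")) fwhm <- fwhm$fwhm_mm
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  grid <- dim(mask)
  # invert field FWHM -> per-axis kernel sigma matching lattice lag-1 rho
  rho_target <- 1 - 2 * log(2) * (voxel_size_mm / fwhm)^2
  sigma_vox <- vapply(rho_target, sigma_for_rho, numeric(1))
  Ks <- lapply(1:3, function(a) {
    if (sigma_vox[a] > 0) gauss_conv_matrix(grid[a], sigma_vox[a]) else NULL
  })
  zthr <- qnorm(1 - voxel_p / 2)
  supra_arr <- array(FALSE, grid)
  max_extents <- integer(n_sims)
  for (s in seq_len(n_sims)) {
    noise <- array(rnorm(prod(grid)), grid)
    for (a in 1:3) {
      if (is.null(Ks[[a]])) next
      perm <- c(a, setdiff(1:3, a))
      x <- aperm(noise, perm)
      x <- Ks[[a]] %*% matrix(x, nrow = grid[a])
      noise <- aperm(array(x, dim(noise)[perm]), order(perm))
    }
    v <- as.vector(noise)[idx]
    v <- (v - mean(v)) / sd(v)
    supra <- abs(v) >= zthr
    if (!any(supra)) {
      max_extents[s] <- 0L
      next
    }
    supra_arr[] <- FALSE
    supra_arr[idx[supra]] <- TRUE
    labels <- label_clusters(supra_arr, connectivity)
    max_extents[s] <- max(tabulate(labels[labels > 0L]))
  }
  k <- 1L
  while (mean(max_extents >= k) > alpha) k <- k + 1L
  structure(list(
    min_extent = k, max_extents = max_extents, sigma_vox = sigma_vox,
    fwhm_mm = fwhm, voxel_p = voxel_p, n_sims = n_sims, alpha = alpha,
    connectivity = as.integer(connectivity), voxel_size_mm = voxel_size_mm
  ), class = "alphasim")
}

#' @export
print.alphasim <- function(x, ...) {
  cat(sprintf(
    "alphasim: min extent %d voxels (voxel p %g, alpha %g, %d sims, %d-connectivity)\n",
    x$min_extent, x$voxel_p, x$alpha, x$n_sims, x$connectivity
  ))
  invisible(x)
}

#' Extract corrected clusters from a T map
#'
#' Voxels with `|T|` above the two-sided t-quantile for `voxel_p` are labeled
#' by connectivity, separately per sign; components reaching `min_extent` are
#' reported with sign, peak coordinate (mm via the affine), extent and peak T.
#' When the AlphaSim null distribution is supplied, a cluster-level p
#' (`P(max null extent >= extent)`) is attached.
#'
#' @param fit a `voxel_glm`.
#' @param voxel_p cluster-forming p (two-sided), default 0.001.
#' @param min_extent minimum cluster extent in voxels.
#' @param connectivity 6, 18 (default), or 26.
#' @param null_max_extents optional integer vector of simulated maximum
#'   extents (from [alphasim_min_extent()]).
#' @return data.frame with columns sign, peak_x/y/z (mm), extent, peak_t,
#'   cluster_p; zero rows when nothing survives.
#' @export
extract_clusters <- function(fit, voxel_p = 0.001, min_extent = 1L,
                             connectivity = 18L, null_max_extents = NULL) {
  stopifnot(inherits(fit, "voxel_glm"))
  if (fit$df < 1L) stop("degrees of freedom must be >= 1")
  tthr <- qt(1 - voxel_p / 2, df = fit$df)
  inside <- array(FALSE, dim(fit$mask))
  inside[fit$voxel_index] <- TRUE
  rows <- list()
  for (sgn in c(1, -1)) {
    supra <- inside & (sgn * fit$tmap >= tthr)
    if (!any(supra)) next
    labels <- label_clusters(supra, connectivity)
    for (cl in seq_len(max(labels))) {
      vox <- which(labels == cl)
      if (length(vox) < min_extent) next
      tv <- fit$tmap[vox]
      peak <- vox[which.max(abs(tv))]
      peak_mm <- if (!is.null(fit$affine)) {
        voxel_to_mm(index_to_ijk(peak, dim(fit$mask)), fit$affine)
      } else {
        matrix(index_to_ijk(peak, dim(fit$mask)), nrow = 1)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sign = if (sgn > 0) "increase" else "decrease",
        peak_x = peak_mm[1], peak_y = peak_mm[2], peak_z = peak_mm[3],
        extent = length(vox),
        peak_t = tv[which.max(abs(tv))],
        cluster_p = if (is.null(null_max_extents)) NA_real_ else {
          mean(null_max_extents >= length(vox))
        },
        peak_index = peak
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      sign = character(0), peak_x = numeric(0), peak_y = numeric(0),
      peak_z = numeric(0), extent = integer(0), peak_t = numeric(0),
      cluster_p = numeric(0), peak_index = integer(0)
    ))
  }
  out <- do.call(rbind, rows)
  out[order(-out$extent), , drop = FALSE]
}

#' Voxel sets of surviving clusters (for ROI definition)
#'
#' @inheritParams extract_clusters
#' @return list of integer vectors (linear voxel indices), ordered and named
#'   like the rows of [extract_clusters()].
#' @export
cluster_voxel_sets <- function(fit, voxel_p = 0.001, min_extent = 1L,
                               connectivity = 18L) {
  stopifnot(inherits(fit, "voxel_glm"))
  tthr <- qt(1 - voxel_p / 2, df = fit$df)
  inside <- array(FALSE, dim(fit$mask))
  inside[fit$voxel_index] <- TRUE
  sets <- list()
  for (sgn in c(1, -1)) {
    supra <- inside & (sgn * fit$tmap >= tthr)
    if (!any(supra)) next
    labels <- label_clusters(supra, connectivity)
    for (cl in seq_len(max(labels))) {
      vox <- which(labels == cl)
      if (length(vox) >= min_extent) {
        nm <- sprintf("%s_%d", if (sgn > 0) "increase" else "decrease",
                      length(sets) + 1L)
        sets[[nm]] <- vox
      }
    }
  }
  if (length(sets) > 1L) {
    sets <- sets[order(-vapply(sets, length, integer(1)))]
  }
  sets
}
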