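# Voxel-wise functional connectivity strength (weighted degree) maps with a
# long/short anatomical-distance partition.

R_CLIP <- 1 - 1e-7   # correlation clip before arctanh

#' Extract masked voxel time series from a BOLD image
#'
#' Flattens the in-mask voxels of a 4D image into a voxel x time matrix,
#' attaching each voxel's linear grid index and mm coordinate (affine
#' transformed voxel center). Voxels with zero temporal variance are dropped
#' with a message, since they carry no correlation information.
#'
#' @param img a [bold_image()].
#' @param mask 3D logical array on the image grid (e.g. gray-matter
#'   probability > 0.3).
#' @return an object of class `voxel_ts`: list with `values` (voxel x time),
#'   `coords_mm`, `voxel_index`, `grid_shape`, `affine`, `tr_seconds`,
#'   `n_dropped`.
#' @export
mask_timeseries <- function(img, mask) {
  stopifnot(inherits(img, "bold_image"))
  mask <- as.array(mask)
  if (!identical(dim(mask), dim(img$data)[1:3])) {
    stop("mask grid does not match the image grid")
  }
  idx <- which(as.logical(mask))
  if (length(idx) < 1L) stop("mask is empty")
  n_vol <- dim(img$data)[4L]
  flat <- matrix(img$data, ncol = n_vol)
  values <- flat[idx, , drop = FALSE]
  v <- rowSums((values - rowMeans(values))^2)
  zero_var <- v <= .Machine$double.eps * n_vol
  if (any(zero_var)) {
    message(sprintf("dropping %d zero-variance voxel(s) from the mask",
                    sum(zero_var)))
    idx <- idx[!zero_var]
    values <- values[!zero_var, , drop = FALSE]
  }
  coords <- voxel_to_mm(index_to_ijk(idx, dim(mask)), img$affine)
  structure(list(
    values = values, coords_mm = coords, voxel_index = idx,
    grid_shape = dim(mask), affine = img$affine,
    tr_seconds = img$tr_seconds, n_dropped = sum(zero_var)
  ), class = "voxel_ts")
}

#' Build a `voxel_ts` directly from a matrix (for simulation and testing)
#'
#' @param values voxel x time matrix.
#' @param coords_mm voxel x 3 matrix of mm coordinates.
#' @param grid_shape,affine,voxel_index optional grid provenance; by default a
#'   degenerate 1D grid is assumed.
#' @return a `voxel_ts`.
#' @export
voxel_ts <- function(values, coords_mm, grid_shape = NULL, affine = NULL,
                     voxel_index = NULL) {
  values <- as.matrix(values)
  coords_mm <- as.matrix(coords_mm)
  stopifnot(nrow(values) == nrow(coords_mm), ncol(coords_mm) == 3L,
            all(is.finite(coords_mm)))
  structure(list(
    values = values, coords_mm = coords_mm,
    voxel_index = voxel_index %||% seq_len(nrow(values)),
    grid_shape = grid_shape %||% c(nrow(values), 1L, 1L),
    affine = affine, tr_seconds = NA_real_, n_dropped = 0L
  ), class = "voxel_ts")
}

#' Fisher r-to-z transform with clipping
#'
#' `z = arctanh(r)` after clipping `r` to `+/-(1 - 1e-7)`, so duplicated
#' series cannot produce infinities. The number of clipped values can be
#' recovered via `attr(, "n_clipped")`.
#'
#' @param r numeric vector/matrix of correlations.
#' @return transformed values, same shape as `r`.
#' @examples
#' fisher_z(0.2)   # 0.202733
#' @export
fisher_z <- function(r) {
  n_clipped <- sum(abs(r) > R_CLIP, na.rm = TRUE)
  z <- atanh(pmin(pmax(r, -R_CLIP), R_CLIP))
  attr(z, "n_clipped") <- n_clipped
  z
}

# squared pairwise distances between rows of a coordinate matrix
pairwise_dist2 <- function(coords) {
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  d2
}

# correlation matrix of the rows of a voxel x time matrix
row_correlation <- function(values) {
  x <- values - rowMeans(values)
  x <- x / sqrt(rowSums(x^2))
  tcrossprod(x)
}

#' Per-subject FCS maps (long-range, short-range, global)
#'
#' For every voxel, global FCS is the sum of Fisher-z-transformed positive
#' correlations exceeding `r_threshold` (strictly) with all other voxels.
#' The long-range map restricts the sum to voxel pairs separated by more than
#' `cutoff_mm` (Euclidean, mm-space); the short-range map is the complement,
#' with ties at exactly the cutoff assigned to short range so the partition is
#' exhaustive: `long + short = global` holds exactly at every voxel.
#'
#' @param ts a `voxel_ts` (>= 2 voxels, >= 3 time points).
#' @param r_threshold correlation threshold (default 0.2); sub-threshold and
#'   negative correlations contribute nothing.
#' @param cutoff_mm anatomical distance cutoff (default 75 mm).
#' @param normalize divide the sums by (V - 1) for comparability across
#'   masks of different size; off by default (FCS is a sum, not an average).
#' @return an object of class `fcs_maps`: 3D arrays `long`, `short`,
#'   `global` (zero outside the mask), plus `r_threshold`, `cutoff_mm`,
#'   `voxel_index`, `n_clipped`, `n_ties`, `smoothed`, `fwhm_mm`.
#' @export
fcs_maps <- function(ts, r_threshold = 0.2, cutoff_mm = 75,
                     normalize = FALSE) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (nrow(ts$values) < 2L) stop("need at least 2 voxels")
  if (ncol(ts$values) < 3L) stop("need at least 3 time points")
  check_scalar(r_threshold, "r_threshold", 0, 1)
  check_scalar(cutoff_mm, "cutoff_mm", 0, strict_lower = TRUE)
  R <- row_correlation(ts$values)
  d2 <- pairwise_dist2(ts$coords_mm)
  fcs_from_matrices(R, d2, ts, r_threshold, cutoff_mm, normalize)
}

# core FCS computation given precomputed correlation and squared-distance
# matrices; shared with the threshold sweep
fcs_from_matrices <- function(R, d2, ts, r_threshold, cutoff_mm,
                              normalize = FALSE) {
  Z <- atanh(pmin(pmax(R, -R_CLIP), R_CLIP))
  n_clipped <- (sum(R > R_CLIP) - nrow(R)) / 2
  W <- Z * (R > r_threshold)
  diag(W) <- 0
  long_sel <- d2 > cutoff_mm^2
  n_ties <- sum(d2 == cutoff_mm^2) / 2
  # the partition sums are formed independently and global is their sum, so
  # long + short == global holds bitwise
  long_v <- colSums(W * long_sel)
  short_v <- colSums(W * !long_sel)
  if (normalize) {
    long_v <- long_v / (nrow(R) - 1)
    short_v <- short_v / (nrow(R) - 1)
  }
  global_v <- long_v + short_v
  to_map <- function(v) {
    m <- array(0, ts$grid_shape)
    m[ts$voxel_index] <- v
    m
  }
  structure(list(
    long = to_map(long_v), short = to_map(short_v), global = to_map(global_v),
    r_threshold = r_threshold, cutoff_mm = cutoff_mm,
    voxel_index = ts$voxel_index, grid_shape = ts$grid_shape,
    affine = ts$affine, n_clipped = n_clipped, n_ties = n_ties,
    smoothed = FALSE, fwhm_mm = 0
  ), class = "fcs_maps")
}

#' @export
print.fcs_maps <- function(x, ...) {
  cat(sprintf(
    "fcs_maps: %d mask voxels, r > %g, cutoff %g mm%s\n",
    length(x$voxel_index), x$r_threshold, x$cutoff_mm,
    if (x$smoothed) sprintf(", smoothed %g mm FWHM", x$fwhm_mm) else ""
  ))
  invisible(x)
}

#' FCS maps across several correlation thresholds
#'
#' Computes one set of FCS maps per threshold, reusing the correlation and
#' distance matrices. Because every retained term is positive, per-voxel FCS
#' is non-increasing in the threshold.
#'
#' @param ts a `voxel_ts`.
#' @param thresholds numeric vector of thresholds in (0, 1).
#' @param cutoff_mm anatomical distance cutoff, mm.
#' @return named list of `fcs_maps`, one per threshold.
#' @export
fcs_threshold_sweep <- function(ts, thresholds = c(0.1, 0.2, 0.3),
                                cutoff_mm = 75) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie in (0, 1)")
  }
  R <- row_correlation(ts$values)
  d2 <- pairwise_dist2(ts$coords_mm)
  out <- lapply(thresholds, function(thr) {
    fcs_from_matrices(R, d2, ts, thr, cutoff_mm)
  })
  names(out) <- sprintf("r%g", thresholds)
  out
}

# one-axis zero-padded Gaussian convolution matrix
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  offsets <- -r:r
  g <- exp(-offsets^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  K <- matrix(0, n, n)
  for (m in seq_along(offsets)) {
    o <- offsets[m]
    rows <- seq_len(n)
    src <- rows + o
    ok <- src >= 1 & src <= n
    K[cbind(rows[ok], src[ok])] <- K[cbind(rows[ok], src[ok])] + g[m]
  }
  K
}

#' Gaussian spatial smoothing of a 3D map
#'
#' Separable Gaussian convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` per
#' axis (expressed in voxels), with zero padding outside the grid and no mask
#' renormalization. `fwhm_mm = 0` returns the input unchanged.
#'
#' @param map3d 3D numeric array.
#' @param fwhm_mm kernel full width at half maximum, mm (>= 0).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @return smoothed 3D array.
#' @export
smooth_map <- function(map3d, fwhm_mm = 6, voxel_size_mm = 3) {
  stopifnot(is.array(map3d), length(dim(map3d)) == 3L)
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0")
  check_scalar(voxel_size_mm, "voxel_size_mm", 0, strict_lower = TRUE)
  if (fwhm_mm == 0) return(map3d)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  d <- dim(map3d)
  out <- map3d
  for (axis in 1:3) {
    K <- gauss_conv_matrix(d[axis], sigma_vox)
    perm <- c(axis, setdiff(1:3, axis))
    x <- aperm(out, perm)
    x <- K %*% matrix(x, nrow = d[axis])
    x <- array(x, d[perm])
    out <- aperm(x, order(perm))
  }
  out
}

#' Smooth all three maps of an `fcs_maps` object
#'
#' @param maps an `fcs_maps`.
#' @param fwhm_mm kernel FWHM, mm.
#' @param voxel_size_mm isotropic voxel size, mm (defaults to the affine's).
#' @return an `fcs_maps` with smoothed maps and updated metadata.
#' @export
smooth_fcs <- function(maps, fwhm_mm = 6, voxel_size_mm = NULL) {
  stopifnot(inherits(maps, "fcs_maps"))
  if (is.null(voxel_size_mm)) {
    voxel_size_mm <- if (!is.null(maps$affine)) abs(maps$affine[1, 1]) else 3
  }
  maps$long <- smooth_map(maps$long, fwhm_mm, voxel_size_mm)
  maps$short <- smooth_map(maps$short, fwhm_mm, voxel_size_mm)
  maps$global <- smooth_map(maps$global, fwhm_mm, voxel_size_mm)
  maps$smoothed <- TRUE
  maps$fwhm_mm <- fwhm_mm
  maps
}
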