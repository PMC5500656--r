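# Sphere seeds at cluster peaks and seed-to-voxel connectivity z-maps.

#' Sphere seed specification
#'
#' @param center_mm numeric length-3 mm coordinate (cluster peak).
#' @param diameter_mm sphere diameter, mm (default 6).
#' @param label text label for reports.
#' @return an object of class `seed_spec`.
#' @export
seed_spec <- function(center_mm, diameter_mm = 6, label = "seed") {
  center_mm <- as.numeric(center_mm)
  stopifnot(length(center_mm) == 3L, all(is.finite(center_mm)))
  check_scalar(diameter_mm, "diameter_mm", 0, strict_lower = TRUE)
  structure(list(center_mm = center_mm, diameter_mm = diameter_mm,
                 label = as.character(label)),
            class = "seed_spec")
}

#' In-mask voxels of a sphere seed
#'
#' All in-mask voxels whose center lies within `diameter/2` of the seed
#' center (inclusive at the boundary). On a 3 mm isotropic grid a 6 mm
#' diameter sphere centered on a voxel center contains 7 voxels (center plus
#' six face neighbors at exactly 3 mm).
#'
#' @param seed a [seed_spec()].
#' @param grid_shape integer vector of 3 voxel counts.
#' @param affine 4x4 voxel-to-mm affine.
#' @param mask 3D logical array.
#' @return integer vector of linear voxel indices.
#' @export
sphere_voxels <- function(seed, grid_shape, affine, mask) {
  stopifnot(inherits(seed, "seed_spec"))
  mask <- as.logical(mask)
  idx <- which(mask)
  if (length(idx) == 0L) stop("mask is empty")
  coords <- voxel_to_mm(index_to_ijk(idx, grid_shape), affine)
  d <- sqrt(colSums((t(coords) - seed$center_mm)^2))
  inside <- d <= seed$diameter_mm / 2 + 1e-9
  if (!any(inside)) {
    nearest <- idx[which.min(d)]
    stop(sprintf(
      "seed '%s' at (%g, %g, %g) intersects no mask voxel; nearest mask voxel is index %d at %.1f mm",
      seed$label, seed$center_mm[1], seed$center_mm[2], seed$center_mm[3],
      nearest, min(d)
    ))
  }
  idx[inside]
}

#' Seed-to-voxel connectivity z-map
#'
#' The seed signal is the unweighted mean time series over the seed voxels;
#' the map value at each voxel is the Fisher-z-transformed (clipped) Pearson
#' correlation between the seed signal and that voxel. Seed voxels carry
#' their (self-inclusive) value.
#'
#' @param ts a `voxel_ts`.
#' @param seed_voxels integer linear indices; must be a subset of the mask
#'   voxels in `ts`.
#' @return list with `map` (3D z-map, zero outside the mask), `seed_voxels`,
#'   and `n_clipped`.
#' @export
seed_fc_map <- function(ts, seed_voxels) {
  stopifnot(inherits(ts, "voxel_ts"))
  pos <- match(seed_voxels, ts$voxel_index)
  if (anyNA(pos)) {
    stop(sprintf("%d seed voxel(s) are outside the analysis mask",
                 sum(is.na(pos))))
  }
  seed_sig <- colMeans(ts$values[pos, , drop = FALSE])
  if (var(seed_sig) <= .Machine$double.eps) {
    stop("seed signal has zero variance")
  }
  s <- seed_sig - mean(seed_sig)
  s <- s / sqrt(sum(s^2))
  x <- ts$values - rowMeans(ts$values)
  x <- x / sqrt(rowSums(x^2))
  r <- as.vector(x %*% s)
  z <- fisher_z(r)
  map <- array(0, ts$grid_shape)
  map[ts$voxel_index] <- z
  list(map = map, seed_voxels = seed_voxels,
       n_clipped = attr(z, "n_clipped"))
}
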