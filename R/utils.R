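# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' that seeded generators do not clobber the session stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# scalar validation; stops with the argument name in the message
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g (got %g)", name, upper, x), call. = FALSE)
  }
  invisible(x)
}

# voxel (i,j,k) 1-based -> mm coordinates through a 4x4 affine
voxel_to_mm <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3L)
  homog <- cbind(ijk - 1, 1)
  mm <- homog %*% t(affine)
  mm[, 1:3, drop = FALSE]
}

# standard phantom affine: isotropic voxels, origin at the grid center
phantom_affine <- function(grid_shape, voxel_size_mm) {
  aff <- diag(c(rep(voxel_size_mm, 3L), 1))
  aff[1:3, 4] <- -(grid_shape - 1) / 2 * voxel_size_mm
  aff
}

# linear index -> (i,j,k) 1-based
index_to_ijk <- function(idx, dim3) {
  idx0 <- idx - 1L
  i <- idx0 %% dim3[1L]
  j <- (idx0 %/% dim3[1L]) %% dim3[2L]
  k <- idx0 %/% (dim3[1L] * dim3[2L])
  cbind(i, j, k) + 1L
}

ijk_to_index <- function(ijk, dim3) {
  (ijk[, 3L] - 1L) * dim3[1L] * dim3[2L] + (ijk[, 2L] - 1L) * dim3[1L] +
    ijk[, 1L]
}
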