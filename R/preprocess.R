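# Subject-level temporal preprocessing: volume discard, motion QC,
# nuisance regression, band-pass filtering.

#' Discard initial volumes of a BOLD series
#'
#' Drops the first `n_discard` volumes so the signal can be treated as being
#' at steady state; the remaining data are bit-identical to the input tail.
#'
#' @param img a [bold_image()].
#' @param n_discard number of leading volumes to drop (default 10).
#' @return a `bold_image` with `n - n_discard` volumes.
#' @export
discard_initial_volumes <- function(img, n_discard = 10L) {
  stopifnot(inherits(img, "bold_image"))
  n_discard <- as.integer(n_discard)
  n_vol <- dim(img$data)[4L]
  if (n_discard < 0L) stop("`n_discard` must be >= 0")
  if (n_discard >= n_vol) {
    stop(sprintf("cannot discard %d of %d volumes", n_discard, n_vol))
  }
  if (n_discard == 0L) return(img)
  bold_image(img$data[, , , (n_discard + 1L):n_vol, drop = FALSE],
             img$affine, img$tr_seconds)
}

#' Motion quality control for one subject
#'
#' A subject is excluded when any axis strictly exceeds the translation or
#' rotation limit; a maximum of exactly the limit passes.
#'
#' @param trace time x 6 motion matrix (translations mm, rotations deg).
#' @param trans_limit_mm translation limit per axis (default 2 mm).
#' @param rot_limit_deg rotation limit per axis (default 2 degrees).
#' @param subject optional subject identifier carried into the verdict.
#' @return a one-row data.frame: subject, per-axis maxima, `included`.
#' @export
motion_qc <- function(trace, trans_limit_mm = 2.0, rot_limit_deg = 2.0,
                      subject = NA_character_) {
  trace <- as.matrix(trace)
  if (nrow(trace) == 0L) stop("motion trace is empty")
  if (ncol(trace) != 6L) stop("motion trace must have exactly 6 columns")
  if (!all(is.finite(trace))) stop("motion trace contains non-finite values")
  mx <- apply(abs(trace), 2L, max)
  included <- all(mx[1:3] <= trans_limit_mm) && all(mx[4:6] <= rot_limit_deg)
  data.frame(
    subject = subject,
    max_trans_x = mx[1L], max_trans_y = mx[2L], max_trans_z = mx[3L],
    max_rot_x = mx[4L], max_rot_y = mx[5L], max_rot_z = mx[6L],
    included = included,
    row.names = NULL
  )
}

#' Build the nuisance regressor matrix
#'
#' Fourteen columns in fixed order: the six motion parameters, their first
#' temporal derivatives (backward difference, first row zero), then the mean
#' white-matter and mean CSF signals. The global mean signal is deliberately
#' never included.
#'
#' @param trace time x 6 motion matrix (already trimmed to retained volumes).
#' @param img a [bold_image()] with the same number of volumes.
#' @param wm_mask,csf_mask 3D logical masks on the image grid.
#' @return time x 14 numeric matrix with named columns.
#' @export
build_confounds <- function(trace, img, wm_mask, csf_mask) {
  stopifnot(inherits(img, "bold_image"))
  trace <- as.matrix(trace)
  n_vol <- dim(img$data)[4L]
  if (nrow(trace) != n_vol) {
    stop(sprintf("motion trace has %d rows but image has %d volumes",
                 nrow(trace), n_vol))
  }
  if (ncol(trace) != 6L) stop("motion trace must have exactly 6 columns")
  wm_mask <- as.logical(wm_mask); csf_mask <- as.logical(csf_mask)
  if (!any(wm_mask)) stop("WM mask is empty")
  if (!any(csf_mask)) stop("CSF mask is empty")
  flat <- matrix(img$data, ncol = n_vol)   # voxel x time
  wm <- colMeans(flat[wm_mask, , drop = FALSE])
  csf <- colMeans(flat[csf_mask, , drop = FALSE])
  deriv <- rbind(0, diff(trace))
  confounds <- cbind(trace, deriv, wm, csf)
  colnames(confounds) <- c(
    colnames(trace) %||% paste0("motion_", 1:6),
    paste0("d_", colnames(trace) %||% paste0("motion_", 1:6)),
    "wm_mean", "csf_mean"
  )
  if (!all(is.finite(confounds))) stop("confound matrix has non-finite values")
  confounds
}

#' Regress nuisance covariates out of voxel time series
#'
#' Returns the least-squares residuals of each voxel's series after
#' projecting out the confounds plus an intercept. Residuals are exactly
#' orthogonal to every confound column. A rank-deficient confound matrix is
#' handled through the pivoted QR (pseudo-inverse projection) with a warning.
#'
#' @param values voxel x time matrix.
#' @param confounds time x k confound matrix.
#' @return voxel x time residual matrix.
#' @export
regress_nuisance <- function(values, confounds) {
  values <- as.matrix(values)
  confounds <- as.matrix(confounds)
  if (ncol(values) != nrow(confounds)) {
    stop("time dimension of series and confounds must match")
  }
  X <- cbind(intercept = 1, confounds)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning(sprintf(
      "confound matrix is rank deficient (rank %d of %d); using pseudo-inverse projection",
      qrX$rank, ncol(X)
    ))
  }
  t(qr.resid(qrX, t(values)))
}

#' Ideal band-pass filter for voxel time series
#'
#' Frequency-domain rectangular filter: discrete-Fourier bins whose frequency
#' lies in `[low_hz, high_hz]` (inclusive at both edges) are retained, all
#' others -- including the 0 Hz mean -- are zeroed, and the series is
#' inverse-transformed. Applying the filter twice equals applying it once.
#'
#' @param values voxel x time matrix.
#' @param tr_seconds sampling interval (repetition time), seconds.
#' @param low_hz,high_hz pass-band edges; `high_hz` must not exceed the
#'   Nyquist frequency `1 / (2 * tr_seconds)`.
#' @return filtered voxel x time matrix.
#' @export
bandpass <- function(values, tr_seconds, low_hz = 0.01, high_hz = 0.08) {
  values <- as.matrix(values)
  check_scalar(tr_seconds, "tr_seconds", 0, strict_lower = TRUE)
  nyquist <- 1 / (2 * tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz) {
    stop("need 0 <= low_hz < high_hz")
  }
  if (high_hz > nyquist + 1e-12) {
    stop(sprintf("high_hz (%g) exceeds the Nyquist frequency %g Hz",
                 high_hz, nyquist))
  }
  n <- ncol(values)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k) / (n * tr_seconds)   # two-sided bin frequencies
  keep <- freq >= low_hz & freq <= high_hz
  keep[1L] <- FALSE                           # always remove the mean
  spec <- mvfft(t(values))
  spec[!keep, ] <- 0
  t(Re(mvfft(spec, inverse = TRUE)) / n)
}
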