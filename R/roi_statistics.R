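# ROI extraction and clinical statistics: partial correlations, Fisher
# r-to-z group comparison, Bonferroni, demographics tests.

#' Mean map value over an ROI
#'
#' @param map3d 3D numeric array.
#' @param roi_voxels non-empty integer vector of linear voxel indices.
#' @return scalar unweighted mean.
#' @export
roi_mean <- function(map3d, roi_voxels) {
  stopifnot(is.array(map3d))
  if (length(roi_voxels) == 0L) stop("ROI is empty")
  mean(as.vector(map3d)[roi_voxels])
}

#' Partial correlation controlling for covariates
#'
#' Pearson correlation between the OLS residuals of `x` and `y` after
#' regressing each on the covariates plus an intercept; the two-sided p comes
#' from `t = r * sqrt((n - 2 - k) / (1 - r^2))` on `n - 2 - k` degrees of
#' freedom. With no covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame or matrix of k covariates (may be NULL).
#' @return object of class `partial_cor`: list with `r`, `p`, `t`, `n`, `k`,
#'   `df`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(y) == n)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite")
  }
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1L)
    k <- 0L
  } else {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    if (!all(is.finite(cv))) stop("covariates must be finite")
    stopifnot(nrow(cv) == n)
    Z <- cbind(1, cv)
    k <- ncol(cv)
  }
  if (n < k + 4L) stop("need at least k + 4 observations")
  qrZ <- qr(Z)
  rx <- qr.resid(qrZ, x)
  ry <- qr.resid(qrZ, y)
  if (sd(rx) <= 1e-12 || sd(ry) <= 1e-12) {
    stop("x or y is constant after removing covariates")
  }
  r <- cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * pt(-abs(tval), df = df)
  structure(list(r = r, p = p, t = tval, n = n, k = k, df = df),
            class = "partial_cor")
}

#' @export
print.partial_cor <- function(x, ...) {
  cat(sprintf("partial correlation: r = %.3f, p = %.4g (n = %d, k = %d)\n",
              x$r, x$p, x$n, x$k))
  invisible(x)
}

#' Compare two independent correlation coefficients (Fisher r-to-z)
#'
#' `z = (arctanh(r1) - arctanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
#' p from the standard normal.
#'
#' @param r1,r2 correlations with `|r| < 1`.
#' @param n1,n2 sample sizes (> 3).
#' @return list with `z` and `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("both sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * (1 - pnorm(abs(z))))
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adjusted = min(1, p * m)`; ordering of the p-values is preserved.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param family_size number of tests m (>= 1); defaults to `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p, family_size = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (family_size < 1) stop("`family_size` must be >= 1")
  pmin(1, p * family_size)
}

#' Demographics and clinical group-comparison battery
#'
#' For each continuous variable the Lilliefors (Kolmogorov-Smirnov with
#' estimated parameters) test gates the comparison: normal in both groups ->
#' pooled-variance two-sample t-test; otherwise Mann-Whitney U with the
#' normal approximation (no continuity correction). Gender is compared with a
#' Pearson chi-squared test on the 2x2 table without continuity correction.
#' Variables constant in both groups are flagged and skipped.
#'
#' @param clinical data.frame with a `group` column ("patient"/"control") and
#'   a `gender` column ("M"/"F").
#' @param variables character vector of continuous column names to test;
#'   defaults to all numeric columns.
#' @param normality_alpha p-value below which a variable is routed to the
#'   Mann-Whitney test (default 0.05).
#' @return data.frame: variable, test, statistic, p.
#' @export
demographics_tests <- function(clinical, variables = NULL,
                               normality_alpha = 0.05) {
  stopifnot("group" %in% names(clinical))
  g <- clinical$group
  if (length(unique(g)) != 2L) stop("need exactly two non-empty groups")
  if (is.null(variables)) {
    variables <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
  }
  rows <- list()
  if ("gender" %in% names(clinical)) {
    tab <- table(g, clinical$gender)
    res <- suppressWarnings(chisq.test(tab, correct = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "gender", test = "chi-squared",
      statistic = unname(res$statistic), p = res$p.value
    )
  }
  for (v in variables) {
    x1 <- clinical[[v]][g == unique(g)[1L]]
    x2 <- clinical[[v]][g == unique(g)[2L]]
    if (sd(x1) <= 1e-12 && sd(x2) <= 1e-12) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = "skipped (constant)", statistic = NA_real_,
        p = NA_real_
      )
      next
    }
    normal <- tryCatch({
      nortest::lillie.test(x1)$p.value >= normality_alpha &&
        nortest::lillie.test(x2)$p.value >= normality_alpha
    }, error = function(e) TRUE)
    if (normal) {
      res <- t.test(x1, x2, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = "t-test", statistic = unname(res$statistic),
        p = res$p.value
      )
    } else {
      res <- suppressWarnings(
        wilcox.test(x1, x2, exact = FALSE, correct = FALSE)
      )
      n1 <- length(x1); n2 <- length(x2)
      u <- unname(res$statistic)
      zval <- (u - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = "mann-whitney", statistic = zval, p = res$p.value
      )
    }
  }
  do.call(rbind, rows)
}

#' ROI x clinical-variable partial-correlation battery
#'
#' Within each group, partial correlations between every ROI value and every
#' target variable, controlling for age, gender and education; Bonferroni
#' adjustment over the `#ROIs x #variables` family within each group's
#' battery (the family size is reported so users can re-family); and a
#' between-group Fisher r-to-z comparison per (ROI, variable) pair.
#'
#' @param roi_values data.frame of per-subject ROI means, one column per ROI,
#'   rows aligned to `clinical`; an optional `subject` column is checked
#'   against the clinical table.
#' @param clinical clinical table with `subject`, `group`, `age`, `gender`,
#'   `education` and the target variables.
#' @param targets character vector of clinical/cognitive column names.
#' @param covariate_names columns to control for.
#' @return list with `correlations` (group, roi, variable, r, p,
#'   p_bonferroni, n, family_size) and `comparisons` (roi, variable, z, p).
#' @export
correlation_battery <- function(roi_values, clinical,
                                targets = c("hba1c"),
                                covariate_names = c("age", "gender",
                                                    "education")) {
  roi_values <- as.data.frame(roi_values)
  if ("subject" %in% names(roi_values)) {
    if (!identical(as.character(roi_values$subject),
                   as.character(clinical$subject))) {
      stop("subject ids of ROI values and clinical table are misaligned")
    }
    roi_values$subject <- NULL
  }
  if (nrow(roi_values) != nrow(clinical)) {
    stop("ROI values and clinical table have different numbers of subjects")
  }
  rois <- names(roi_values)
  groups <- sort(unique(clinical$group))
  m <- length(rois) * length(targets)
  covs <- clinical[covariate_names]
  if ("gender" %in% names(covs)) {
    covs$gender <- as.numeric(covs$gender == "M")
  }
  cor_rows <- list()
  for (gr in groups) {
    sel <- clinical$group == gr
    for (roi in rois) {
      for (v in targets) {
        pc <- partial_correlation(roi_values[[roi]][sel],
                                  clinical[[v]][sel],
                                  covs[sel, , drop = FALSE])
        cor_rows[[length(cor_rows) + 1L]] <- data.frame(
          group = gr, roi = roi, variable = v, r = pc$r, p = pc$p,
          n = pc$n, family_size = m
        )
      }
    }
  }
  correlations <- do.call(rbind, cor_rows)
  correlations$p_bonferroni <- bonferroni_adjust(correlations$p, m)
  cmp_rows <- list()
  if (length(groups) == 2L) {
    for (roi in rois) {
      for (v in targets) {
        r1 <- correlations[correlations$group == groups[1L] &
                             correlations$roi == roi &
                             correlations$variable == v, ]
        r2 <- correlations[correlations$group == groups[2L] &
                             correlations$roi == roi &
                             correlations$variable == v, ]
        cc <- compare_correlations(r1$r, r1$n, r2$r, r2$n)
        cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
          roi = roi, variable = v, z = cc$z, p = cc$p
        )
      }
    }
  }
  list(
    correlations = correlations,
    comparisons = if (length(cmp_rows)) do.call(rbind, cmp_rows) else NULL
  )
}
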