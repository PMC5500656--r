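# End-to-end orchestration: simulate-or-ingest -> preprocess -> FCS ->
# group inference -> seed FC -> ROI statistics.

#' Pipeline run configuration
#'
#' Every default equals the analysis constants of the method: 10 discarded
#' volumes, 2 mm / 2 degree motion limits, 0.01--0.08 Hz band, correlation
#' threshold 0.2 (robustness sweep 0.1/0.3), 75 mm distance cutoff, 6 mm
#' smoothing FWHM, voxel p = 0.001, 1000 Monte-Carlo simulations,
#' cluster-level alpha = 0.05, 18-connectivity.
#'
#' @param n_discard leading volumes to drop.
#' @param trans_limit_mm,rot_limit_deg motion QC limits.
#' @param low_hz,high_hz band-pass edges.
#' @param detrend add a linear detrend before filtering.
#' @param gm_threshold gray-matter probability threshold for the mask.
#' @param thresholds correlation thresholds for the FCS sweep.
#' @param main_threshold threshold used for group inference.
#' @param cutoff_mm long/short anatomical distance cutoff.
#' @param fwhm_mm smoothing kernel FWHM for FCS and seed maps.
#' @param voxel_p,n_sims,alpha,connectivity cluster-correction parameters.
#' @param seed_diameter_mm seed sphere diameter.
#' @param targets clinical/cognitive columns for the ROI battery.
#' @param covariates covariates controlled in GLM and partial correlations.
#' @param seed global RNG seed for the Monte-Carlo stages.
#' @param run_seed_fc,run_roi_stats enable the follow-up stages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(n_discard = 10L, trans_limit_mm = 2.0,
                       rot_limit_deg = 2.0, low_hz = 0.01, high_hz = 0.08,
                       detrend = FALSE, gm_threshold = 0.3,
                       thresholds = c(0.1, 0.2, 0.3), main_threshold = 0.2,
                       cutoff_mm = 75, fwhm_mm = 6, voxel_p = 0.001,
                       n_sims = 1000L, alpha = 0.05, connectivity = 18L,
                       seed_diameter_mm = 6,
                       targets = c("hba1c", "fbg", "tmt_a"),
                       covariates = c("age", "gender", "education"),
                       seed = 1L, run_seed_fc = TRUE, run_roi_stats = TRUE) {
  structure(as.list(environment()), class = "run_config")
}

# linear detrend (time index) of voxel x time values
detrend_values <- function(values) {
  tt <- seq_len(ncol(values))
  X <- cbind(1, tt)
  t(qr.resid(qr(X), t(values)))
}

#' Preprocess one subject into masked voxel time series
#'
#' Fixed stage order: discard initial volumes (image and motion trace) ->
#' nuisance regression (6 motion + 6 derivatives + WM + CSF means, plus
#' intercept; never the global mean) -> optional linear detrend -> ideal
#' band-pass. Regression and filtering act on the analysis-mask voxels only.
#'
#' @param img a [bold_image()].
#' @param motion full-length time x 6 motion trace.
#' @param gm_mask,wm_mask,csf_mask 3D logical masks.
#' @param config a [run_config()].
#' @return a `voxel_ts` of preprocessed series.
#' @export
preprocess_subject <- function(img, motion, gm_mask, wm_mask, csf_mask,
                               config = run_config()) {
  img2 <- discard_initial_volumes(img, config$n_discard)
  trace2 <- as.matrix(motion)[
    (config$n_discard + 1L):nrow(as.matrix(motion)), , drop = FALSE
  ]
  confounds <- build_confounds(trace2, img2, wm_mask, csf_mask)
  ts <- mask_timeseries(img2, gm_mask)
  vals <- regress_nuisance(ts$values, confounds)
  if (isTRUE(config$detrend)) vals <- detrend_values(vals)
  ts$values <- bandpass(vals, img2$tr_seconds, config$low_hz, config$high_hz)
  ts
}

#' Preprocess, map FCS, and run group inference on a cohort
#'
#' The core analysis stages shared by [run_pipeline()]: motion QC with
#' exclusion, per-subject preprocessing, FCS maps at the main threshold,
#' 6 mm smoothing, voxel-wise covariate-adjusted GLM on the long- and
#' short-range maps, residual smoothness estimation, Monte-Carlo minimum
#' cluster extent, and cluster extraction. A range whose maps are constant
#' across subjects and voxels (e.g. long-range FCS on a grid smaller than
#' the distance cutoff) is skipped.
#'
#' @param cohort a `phantom_cohort` (simulated or read from disk).
#' @param config a [run_config()].
#' @param keep_timeseries keep preprocessed series for the seed stage.
#' @return list with `qc`, `clinical` (included subjects), `design`,
#'   `fcs_smoothed` (per subject), `inference` (per range: `fit`,
#'   `smoothness`, `alphasim`, `clusters`), `mask`, `affine`, and optionally
#'   `timeseries`.
#' @export
analyze_cohort <- function(cohort, config = run_config(),
                           keep_timeseries = TRUE) {
  gm_mask <- cohort$gm_prob > config$gm_threshold
  qc <- do.call(rbind, lapply(seq_along(cohort$subjects), function(s) {
    mat <- as.matrix(cohort$motion[[s]])
    trimmed <- if (config$n_discard > 0L) {
      mat[-seq_len(config$n_discard), , drop = FALSE]
    } else {
      mat
    }
    motion_qc(trimmed, config$trans_limit_mm, config$rot_limit_deg,
              subject = cohort$clinical$subject[s])
  }))
  keep <- which(qc$included)
  if (length(keep) < 4L) stop("fewer than 4 subjects pass motion QC")
  clinical <- cohort$clinical[keep, , drop = FALSE]
  tslist <- lapply(keep, function(s) {
    preprocess_subject(cohort$subjects[[s]], cohort$motion[[s]], gm_mask,
                       cohort$wm_mask, cohort$csf_mask, config)
  })
  voxel_size <- abs(cohort$affine[1, 1])
  fcs_smoothed <- lapply(tslist, function(ts) {
    maps <- fcs_maps(ts, config$main_threshold, config$cutoff_mm)
    smooth_fcs(maps, config$fwhm_mm, voxel_size)
  })
  design <- build_design(clinical)
  inference <- list()
  for (range in c("long", "short")) {
    maps <- lapply(fcs_smoothed, function(m) m[[range]])
    spread <- max(vapply(maps, function(m) max(m) - min(m), numeric(1)))
    if (spread <= .Machine$double.eps) {
      inference[[range]] <- NULL
      next
    }
    fit <- fit_voxel_glm(maps, design, gm_mask, contrast = "group",
                         affine = cohort$affine)
    sm <- estimate_smoothness(fit, voxel_size)
    as_res <- alphasim_min_extent(gm_mask, sm, config$voxel_p,
                                  config$n_sims, config$alpha,
                                  config$connectivity, voxel_size)
    clusters <- extract_clusters(fit, config$voxel_p, as_res$min_extent,
                                 config$connectivity, as_res$max_extents)
    inference[[range]] <- list(fit = fit, smoothness = sm, alphasim = as_res,
                               clusters = clusters)
  }
  out <- list(
    qc = qc, clinical = clinical, design = design,
    fcs_smoothed = fcs_smoothed, inference = inference,
    mask = gm_mask, affine = cohort$affine, voxel_size_mm = voxel_size
  )
  if (keep_timeseries) out$timeseries <- tslist
  out
}

# seed-based follow-up at significant FCS peaks
seed_stage <- function(analysis, config) {
  seeds <- list()
  for (range in names(analysis$inference)) {
    cl <- analysis$inference[[range]]$clusters
    if (nrow(cl) == 0L) next
    for (i in seq_len(nrow(cl))) {
      lbl <- sprintf("%s_%s_%d", range, cl$sign[i], i)
      seeds[[lbl]] <- seed_spec(
        c(cl$peak_x[i], cl$peak_y[i], cl$peak_z[i]),
        config$seed_diameter_mm, lbl
      )
    }
  }
  if (length(seeds) == 0L) return(NULL)
  gm_mask <- analysis$mask
  out <- list()
  for (lbl in names(seeds)) {
    vox <- sphere_voxels(seeds[[lbl]], dim(gm_mask), analysis$affine, gm_mask)
    maps <- lapply(analysis$timeseries, function(ts) {
      smooth_map(seed_fc_map(ts, vox)$map, config$fwhm_mm,
                 analysis$voxel_size_mm)
    })
    fit <- fit_voxel_glm(maps, analysis$design, gm_mask, contrast = "group",
                         affine = analysis$affine)
    sm <- estimate_smoothness(fit, analysis$voxel_size_mm)
    as_res <- alphasim_min_extent(gm_mask, sm, config$voxel_p, config$n_sims,
                                  config$alpha, config$connectivity,
                                  analysis$voxel_size_mm)
    clusters <- extract_clusters(fit, config$voxel_p, as_res$min_extent,
                                 config$connectivity, as_res$max_extents)
    out[[lbl]] <- list(seed = seeds[[lbl]], seed_voxels = vox, fit = fit,
                       smoothness = sm, alphasim = as_res,
                       clusters = clusters, maps = maps)
  }
  out
}

# ROI battery over significant FCS clusters
roi_stage <- function(analysis, config) {
  roi_values <- list()
  for (range in names(analysis$inference)) {
    sets <- cluster_voxel_sets(
      analysis$inference[[range]]$fit, config$voxel_p,
      analysis$inference[[range]]$alphasim$min_extent, config$connectivity
    )
    for (nm in names(sets)) {
      col <- vapply(analysis$fcs_smoothed, function(m) {
        roi_mean(m[[range]], sets[[nm]])
      }, numeric(1))
      roi_values[[sprintf("%s_%s", range, nm)]] <- col
    }
  }
  if (length(roi_values) == 0L) return(NULL)
  targets <- intersect(config$targets, names(analysis$clinical))
  battery <- correlation_battery(as.data.frame(roi_values),
                                 analysis$clinical, targets,
                                 config$covariates)
  battery$roi_values <- as.data.frame(roi_values)
  battery
}

#' Run the full pipeline on a cohort
#'
#' Stage order: simulate or ingest -> motion QC and preprocessing -> FCS maps
#' -> group inference on long- and short-range FCS -> sphere seeds at
#' significant peaks -> seed FC maps and their group inference -> ROI
#' battery against clinical variables. Identical config and seed give
#' identical results. With `out_dir`, T maps, cluster tables, QC and a JSON
#' run manifest are written.
#'
#' @param cohort a `phantom_cohort`, a [cohort_spec()] (simulated on the
#'   fly), or a directory path written by [write_cohort()].
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return list of class `rsfcs_run`: `analysis`, `seed_fc`, `roi_stats`,
#'   `demographics`, `manifest`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (inherits(cohort, "cohort_spec")) cohort <- make_phantom_cohort(cohort)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "phantom_cohort"))
  result <- with_seed(config$seed, {
    analysis <- analyze_cohort(cohort, config, keep_timeseries = TRUE)
    seed_fc <- if (isTRUE(config$run_seed_fc)) seed_stage(analysis, config)
    roi_stats <- if (isTRUE(config$run_roi_stats)) roi_stage(analysis, config)
    list(analysis = analysis, seed_fc = seed_fc, roi_stats = roi_stats)
  })
  demographics <- demographics_tests(
    result$analysis$clinical,
    variables = intersect(c("age", "education", "hba1c", "fbg", "mmse",
                            "tmt_a"), names(result$analysis$clinical))
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("rsfcs")),
    seed = config$seed,
    config = config[setdiff(names(config), "")],
    n_subjects = nrow(cohort$clinical),
    n_included = nrow(result$analysis$clinical),
    excluded_subjects = result$analysis$qc$subject[!result$analysis$qc$included],
    smoothness_fwhm_mm = lapply(result$analysis$inference,
                                function(i) i$smoothness$fwhm_mm),
    min_extent = lapply(result$analysis$inference,
                        function(i) i$alphasim$min_extent),
    n_clusters = lapply(result$analysis$inference,
                        function(i) nrow(i$clusters)),
    elapsed_seconds = proc.time()[["elapsed"]] - t0
  )
  out <- structure(c(result, list(demographics = demographics,
                                  manifest = manifest)),
                   class = "rsfcs_run")
  if (!is.null(out_dir)) write_run_outputs(out, out_dir)
  out
}

#' @export
print.rsfcs_run <- function(x, ...) {
  cat("rsfcs pipeline run\n")
  cat(sprintf("  subjects: %d included of %d\n", x$manifest$n_included,
              x$manifest$n_subjects))
  for (range in names(x$analysis$inference)) {
    inf <- x$analysis$inference[[range]]
    cat(sprintf("  %s-range FCS: min extent %d, %d surviving cluster(s)\n",
                range, inf$alphasim$min_extent, nrow(inf$clusters)))
  }
  if (!is.null(x$seed_fc)) {
    cat(sprintf("  seed FC: %d seed(s) analyzed\n", length(x$seed_fc)))
  }
  invisible(x)
}

# write T maps, cluster tables, QC and the manifest; every file is listed in
# the manifest (no orphan outputs)
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  analysis <- run$analysis
  for (range in names(analysis$inference)) {
    inf <- analysis$inference[[range]]
    tpath <- file.path(out_dir, sprintf("tmap_%s_fcs.nii.gz", range))
    write_map_nifti(inf$fit$tmap, analysis$affine, tpath)
    cpath <- file.path(out_dir, sprintf("clusters_%s_fcs.csv", range))
    write.csv(inf$clusters, cpath, row.names = FALSE)
    files <- c(files, tpath, cpath)
  }
  for (lbl in names(run$seed_fc)) {
    tpath <- file.path(out_dir, sprintf("tmap_seed_%s.nii.gz", lbl))
    write_map_nifti(run$seed_fc[[lbl]]$fit$tmap, analysis$affine, tpath)
    cpath <- file.path(out_dir, sprintf("clusters_seed_%s.csv", lbl))
    write.csv(run$seed_fc[[lbl]]$clusters, cpath, row.names = FALSE)
    files <- c(files, tpath, cpath)
  }
  qpath <- file.path(out_dir, "qc.csv")
  write.csv(analysis$qc, qpath, row.names = FALSE)
  files <- c(files, qpath)
  if (!is.null(run$roi_stats)) {
    rpath <- file.path(out_dir, "roi_correlations.csv")
    write.csv(run$roi_stats$correlations, rpath, row.names = FALSE)
    files <- c(files, rpath)
    if (!is.null(run$roi_stats$comparisons)) {
      zpath <- file.path(out_dir, "roi_correlation_comparisons.csv")
      write.csv(run$roi_stats$comparisons, zpath, row.names = FALSE)
      files <- c(files, zpath)
    }
  }
  dpath <- file.path(out_dir, "demographics_tests.csv")
  write.csv(run$demographics, dpath, row.names = FALSE)
  files <- c(files, dpath)
  manifest <- run$manifest
  manifest$outputs <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
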