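# NIfTI and table I/O behind the pipeline surface (via RNifti).

#' Write a BOLD image to a NIfTI file
#'
#' @param img a [bold_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_bold_nifti <- function(img, path) {
  stopifnot(inherits(img, "bold_image"))
  nii <- RNifti::asNifti(img$data)
  aff <- structure(img$affine, code = 2L)
  nii <- RNifti::`qform<-`(nii, aff)
  nii <- RNifti::`sform<-`(nii, aff)
  pd <- RNifti::pixdim(nii)
  pd[1:3] <- sqrt(colSums(img$affine[1:3, 1:3]^2))
  pd[4L] <- img$tr_seconds
  nii <- RNifti::`pixdim<-`(nii, pd)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a BOLD image from a NIfTI file
#'
#' @param path NIfTI file with a 4D series.
#' @return a [bold_image()] (affine from the sform/qform, TR from pixdim).
#' @export
read_bold_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 4L) stop("expected a 4D NIfTI volume: ", path)
  aff <- unclass(RNifti::xform(nii))
  attributes(aff) <- list(dim = c(4L, 4L))
  tr <- RNifti::pixdim(nii)[4L]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  bold_image(arr, aff, tr)
}

#' Write a 3D map to NIfTI
#'
#' @param map3d 3D numeric array.
#' @param affine 4x4 voxel-to-mm affine.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_map_nifti <- function(map3d, affine, path) {
  stopifnot(is.array(map3d), length(dim(map3d)) == 3L)
  nii <- RNifti::asNifti(map3d)
  aff <- structure(affine, code = 2L)
  nii <- RNifti::`qform<-`(nii, aff)
  nii <- RNifti::`sform<-`(nii, aff)
  pd <- RNifti::pixdim(nii)
  pd[1:3] <- sqrt(colSums(affine[1:3, 1:3]^2))
  nii <- RNifti::`pixdim<-`(nii, pd)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a 3D map from NIfTI
#'
#' @param path NIfTI file with a 3D volume.
#' @return list with `data` (3D array) and `affine`.
#' @export
read_map_nifti <- function(path) {
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  aff <- unclass(RNifti::xform(nii))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = arr, affine = aff)
}

#' Read and validate a clinical table
#'
#' @param path CSV with at least subject, group, age, gender, education.
#' @param required required column names.
#' @return validated data.frame.
#' @export
read_clinical_csv <- function(path,
                              required = c("subject", "group", "age",
                                           "gender", "education")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("clinical table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!complete.cases(tab[required]))
  if (length(bad)) {
    stop(sprintf("clinical table has missing values in row(s) %s",
                 paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(tab$subject)) stop("duplicate subject ids")
  tab
}

#' Write a phantom cohort to disk
#'
#' Per-subject 4D NIfTI and 6-column whitespace-delimited motion traces, the
#' gray-matter probability map, WM/CSF masks, the clinical CSV, the
#' ground-truth block label map, and a JSON manifest echoing the spec.
#'
#' @param cohort a `phantom_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$subjects)) {
    id <- cohort$clinical$subject[s]
    write_bold_nifti(cohort$subjects[[s]],
                     file.path(dir, paste0(id, "_bold.nii.gz")))
    write.table(cohort$motion[[s]],
                file.path(dir, paste0(id, "_motion.txt")),
                row.names = FALSE, col.names = FALSE)
  }
  write_map_nifti(cohort$gm_prob, cohort$affine,
                  file.path(dir, "gm_prob.nii.gz"))
  write_map_nifti(cohort$wm_mask + 0, cohort$affine,
                  file.path(dir, "wm_mask.nii.gz"))
  write_map_nifti(cohort$csf_mask + 0, cohort$affine,
                  file.path(dir, "csf_mask.nii.gz"))
  write_map_nifti(cohort$ground_truth$block_map, cohort$affine,
                  file.path(dir, "ground_truth_blocks.nii.gz"))
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  spec <- cohort$spec
  manifest <- list(
    grid_shape = spec$grid_shape, voxel_size_mm = spec$voxel_size_mm,
    n_timepoints = spec$n_timepoints, tr_seconds = spec$tr_seconds,
    n_per_group = spec$n_per_group, rng_seed = spec$rng_seed,
    delta_r = spec$effect$delta_r,
    affected_range = spec$effect$affected_range,
    hub_block = spec$effect$hub_block,
    n_blocks = length(spec$network$blocks),
    target_r_within = spec$network$target_r_within,
    target_r_between = spec$network$target_r_between,
    subjects = cohort$clinical$subject
  )
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' Checks that all subjects share one grid and affine (to 1e-6).
#'
#' @param dir cohort directory.
#' @return a `phantom_cohort`-like list (without generator ground truth
#'   fields that are not serialized).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort_manifest.json"),
                                  simplifyVector = TRUE)
  clinical <- read_clinical_csv(file.path(dir, "clinical.csv"))
  subjects <- list(); motion <- list()
  ref_aff <- NULL
  for (s in seq_len(nrow(clinical))) {
    id <- clinical$subject[s]
    img <- read_bold_nifti(file.path(dir, paste0(id, "_bold.nii.gz")))
    if (is.null(ref_aff)) {
      ref_aff <- img$affine
    } else {
      if (!identical(dim(img$data)[1:3], dim(subjects[[1]]$data)[1:3])) {
        stop("subject ", id, " has a mismatched grid shape")
      }
      if (max(abs(img$affine - ref_aff)) > 1e-6) {
        stop("subject ", id, " has a mismatched affine")
      }
    }
    subjects[[s]] <- img
    motion[[s]] <- as.matrix(read.table(
      file.path(dir, paste0(id, "_motion.txt"))
    ))
  }
  gm <- read_map_nifti(file.path(dir, "gm_prob.nii.gz"))
  wm <- read_map_nifti(file.path(dir, "wm_mask.nii.gz"))
  csf <- read_map_nifti(file.path(dir, "csf_mask.nii.gz"))
  blocks <- read_map_nifti(file.path(dir, "ground_truth_blocks.nii.gz"))
  structure(list(
    subjects = subjects, motion = motion, gm_prob = gm$data,
    wm_mask = wm$data > 0.5, csf_mask = csf$data > 0.5, clinical = clinical,
    ground_truth = list(block_map = blocks$data),
    affine = ref_aff, manifest = manifest
  ), class = "phantom_cohort")
}
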