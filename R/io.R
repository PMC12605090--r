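#' Write a Z-spectrum image as NIfTI plus sidecars
#'
#' The 4D volume is written rows x cols x 1 x n_offsets with the saturation
#' offsets in a plain-text sidecar (one ppm value per line; NIfTI has no
#' offset-axis convention), the ROI labels as an integer NIfTI, and the
#' ground truth (when present) as JSON.
#'
#' @param img A `zspec_image`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_zspec_image <- function(img, dir) {
  stopifnot(inherits(img, "zspec_image"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(img$data)
  vol <- array(img$data, c(d[1], d[2], 1L, d[3]))
  RNifti::writeNifti(vol, file.path(dir, "zspec.nii.gz"), datatype = "double")
  writeLines(sprintf("%.17g", img$offsets), file.path(dir, "offsets.txt"))
  RNifti::writeNifti(array(img$mask, c(d[1], d[2], 1L)),
                     file.path(dir, "mask.nii.gz"), datatype = "int32")
  meta <- list(roi_names = img$roi_names, groups = as.list(img$groups))
  if (!is.null(img$truth)) {
    meta$truth <- list(
      b0_field = img$truth$b0_field,
      pools = lapply(img$truth$pools, function(p) as.list(p)))
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a Z-spectrum image written by [write_zspec_image]
#'
#' @param dir Directory containing `zspec.nii.gz`, `offsets.txt`,
#'   `mask.nii.gz` and `meta.json`.
#' @return A `zspec_image`.
#' @export
read_zspec_image <- function(dir) {
  vol <- RNifti::readNifti(file.path(dir, "zspec.nii.gz"))
  offsets <- as.numeric(readLines(file.path(dir, "offsets.txt")))
  mask <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- dim(vol)
  stopifnot(d[3] == 1, d[4] == length(offsets))
  truth <- NULL
  if (!is.null(meta$truth)) {
    truth <- list(b0_field = matrix(unlist(meta$truth$b0_field), d[1], d[2]),
                  pools = lapply(meta$truth$pools, function(p)
                    pool_table(p$name, p$amplitude, p$center, p$fwhm)))
  }
  structure(list(data = array(as.numeric(vol), c(d[1], d[2], d[4])),
                 offsets = offsets,
                 mask = matrix(as.integer(mask), d[1], d[2]),
                 roi_names = meta$roi_names,
                 groups = setNames(unlist(meta$groups), names(meta$groups)),
                 truth = truth),
            class = "zspec_image")
}

#' Write a contrast map as NIfTI and CSV
#'
#' @param map A `contrast_map`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_contrast_map <- function(map, dir) {
  stopifnot(inherits(map, "contrast_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(map$value)
  RNifti::writeNifti(array(map$value, c(d, 1L)),
                     file.path(dir, sprintf("map_%s.nii.gz", map$pool_name)),
                     datatype = "double")
  idx <- which(map$mask > 0, arr.ind = TRUE)
  df <- data.frame(x = idx[, 1], y = idx[, 2], pool = map$pool_name,
                   integral = map$value[idx], r2 = map$r2[idx],
                   qc_pass = map$qc_mask[idx])
  utils::write.csv(df, file.path(dir, sprintf("map_%s.csv", map$pool_name)),
                   row.names = FALSE)
  invisible(dir)
}

#' Write a Z-spectrum to CSV (offset_ppm, signal)
#' @param z A [zspectrum].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_zspectrum_csv <- function(z, path) {
  utils::write.csv(data.frame(offset_ppm = z$offsets, signal = z$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a Z-spectrum from CSV (offset_ppm, signal)
#' @param path CSV file with columns `offset_ppm` and `signal`.
#' @return A [zspectrum].
#' @export
read_zspectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  zspectrum(df$offset_ppm, df$signal)
}
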