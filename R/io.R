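# File I/O: TSV tables, JSON layouts and results, NIfTI volumes and motion
# tables. All tables are tab-delimited UTF-8 with a header row; angles are in
# degrees, times in seconds.

#' Read and write trial tables
#'
#' @param trials Trial tibble.
#' @param path File path (TSV).
#' @return `read_trial_table()` returns the trial tibble.
#' @name trial_table_io
NULL

#' @rdname trial_table_io
#' @export
write_trial_table <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname trial_table_io
#' @export
read_trial_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    target_ring = readr::col_character(),
                    catch_view_correct = readr::col_logical()
                  ))
}

#' Read and write pair-label tables
#'
#' @param labels Pair-label tibble from [label_pairs()].
#' @param path File path (TSV).
#' @name pair_label_io
NULL

#' @rdname pair_label_io
#' @export
write_pair_labels <- function(labels, path) {
  readr::write_tsv(labels, path)
  invisible(path)
}

#' @rdname pair_label_io
#' @export
read_pair_labels <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write and read a city layout as JSON
#'
#' @param layout A `city_layout`.
#' @param path File path (JSON).
#' @name layout_io
NULL

#' @rdname layout_io
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(
    list(buildings = layout$buildings, scale = layout$scale,
         ns_street_x = layout$ns_street_x),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname layout_io
#' @export
read_layout_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(buildings = as_tibble(raw$buildings), scale = raw$scale,
                 ns_street_x = raw$ns_street_x),
            class = "city_layout")
}

#' Read and write motion parameter tables
#'
#' Whitespace-delimited text with exactly six columns (translations and
#' rotations), one row per volume, no header.
#'
#' @param motion A 6-column matrix or tibble.
#' @param path File path.
#' @name motion_io
NULL

#' @rdname motion_io
#' @export
write_motion_table <- function(motion, path) {
  m <- as.matrix(motion)
  if (ncol(m) != 6L) abort("motion table must have exactly 6 columns.")
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname motion_io
#' @export
read_motion_table <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6L) {
    abort(sprintf("format error: motion table at '%s' has %d columns, expected 6.",
                  path, ncol(m)))
  }
  colnames(m) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  as_tibble(as.data.frame(m))
}

#' Write and read volumetric data as NIfTI
#'
#' 3-D masks/maps and 4-D time series round-trip through NIfTI; `NA` voxels
#' of searchlight maps are stored as NaN. The repetition time is recorded in
#' the time-dimension pixdim of 4-D images.
#'
#' @param x A 3-D/4-D array, logical mask or `searchlight_map`.
#' @param path File path (`.nii` / `.nii.gz`).
#' @param voxel_mm Isotropic voxel size in mm.
#' @param tr Repetition time in seconds for 4-D images.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_volume <- function(x, path, voxel_mm = 2, tr = NULL) {
  arr <- if (inherits(x, "searchlight_map")) x$map else x
  if (is.logical(arr)) arr <- arr * 1
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(voxel_mm, 3), if (nd == 4L) tr %||% 1)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), pixdim = RNifti::pixdim(img))
}

#' Write a contrast or group result as JSON
#'
#' @param x A `contrast_result`, `permutation_result` or `group_result`.
#' @param path File path (JSON).
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
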