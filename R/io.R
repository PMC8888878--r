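#' Read a 4D BOLD run from a NIfTI file
#'
#' The spatial grid (dims, voxel sizes, affine) is taken from the file
#' header. The repetition time comes from header `pixdim[4]` when nonzero;
#' otherwise the `tr` argument is used. When both are available and
#' disagree, the header wins and the mismatch is reported via `message()`.
#'
#' @param path NIfTI-1 file with a 4D image.
#' @param tr fallback repetition time in seconds.
#' @return A [bold_run()].
#' @export
read_bold <- function(path, tr = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4D image, got %dD: %s", length(d), path))
  hdr <- RNifti::niftiHeader(img)
  tr_hdr <- as.numeric(hdr$pixdim[5])
  if (tr_hdr > 0) {
    if (!is.null(tr) && abs(tr - tr_hdr) > 1e-6)
      message(sprintf("read_bold: header TR %g s overrides argument %g s", tr_hdr, tr))
    tr_use <- tr_hdr
  } else {
    if (is.null(tr)) stop("header pixdim[4] is 0 and no tr argument given")
    tr_use <- tr
  }
  grid <- grid_from_image(img)
  data <- array(as.numeric(img), dim = d)
  bold_run(data, tr = tr_use, grid = grid)
}

grid_from_image <- function(img) {
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume_grid(dim(img)[1:3], affine = aff)
}

#' Write a BOLD run to a NIfTI file
#'
#' @param run a [bold_run()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  RNifti::pixdim(img) <- c(run$grid$voxel_mm, run$tr)
  RNifti::sform(img) <- structure(run$grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a 3D map (or mask) to a NIfTI file
#'
#' @param map 3D numeric or logical array; NA stored as 0.
#' @param grid the [volume_grid()] it lives on.
#' @param path output path.
#' @export
write_map <- function(map, grid, path) {
  m <- array(as.numeric(map), dim = dim(map))
  m[is.na(m)] <- 0
  img <- RNifti::asNifti(m)
  RNifti::pixdim(img) <- grid$voxel_mm
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read tissue and ROI masks from NIfTI files
#'
#' Probabilistic inputs are binarized at > 0.5. Entries named `gm`, `wm`,
#' `csf` become the tissue masks; any other named entries become ROI labels.
#'
#' @param paths named character vector or list of NIfTI paths; must include
#'   `gm`, `wm` and `csf`.
#' @param grid the expected [volume_grid()]; each mask must match its dims.
#' @return A [brain_masks()].
#' @export
read_masks <- function(paths, grid) {
  paths <- as.list(paths)
  need <- c("gm", "wm", "csf")
  if (!all(need %in% names(paths)))
    stop("paths must include entries named gm, wm and csf")
  rd <- function(p) {
    img <- RNifti::readNifti(p)
    if (!identical(dim(img)[1:3], as.integer(grid$dims)))
      stop(sprintf("mask %s does not match the target grid", p))
    array(as.numeric(img) > 0.5, dim = grid$dims)
  }
  masks <- lapply(paths, rd)
  rois <- masks[setdiff(names(masks), need)]
  brain_masks(grid, gm = masks$gm, wm = masks$wm, csf = masks$csf,
              roi_labels = rois)
}

#' Read a 6-column motion-parameter text file
#'
#' Whitespace-delimited, one row per volume: 3 translations in mm then 3
#' rotations in radians.
#'
#' @param path text file path.
#' @param n_volumes optional expected row count.
#' @return A [motion_trace()].
#' @export
read_motion <- function(path, n_volumes = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  motion_trace(m, n_volumes = n_volumes)
}

#' Write a motion trace as plain text
#' @param motion a [motion_trace()].
#' @param path output path.
#' @export
write_motion <- function(motion, path) {
  utils::write.table(format(unclass(motion), digits = 10, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a cohort table from TSV
#'
#' Columns: `id`, `group`, then numeric behavioral scores.
#'
#' @param path TSV file path.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  cohort_table(df)
}

#' Write a cohort table as TSV
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$group <- as.character(df$group)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
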