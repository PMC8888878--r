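#' Spatial sampling grid of a volume
#'
#' A `volume_grid` fixes the spatial frame shared by all volumes in an
#' analysis: array dimensions, voxel sizes in mm, and the 4x4 affine mapping
#' 0-based voxel indices to world (MNI) coordinates in mm.
#'
#' @param dims integer triple (nx, ny, nz), all >= 1.
#' @param voxel_mm positive voxel edge lengths in mm (length 3). Ignored if
#'   `affine` is given (sizes are then taken from the affine columns).
#' @param affine 4x4 voxel-to-mm matrix; must be invertible. Default: axis
#'   aligned with `voxel_mm` scaling, centered so the grid midpoint maps to
#'   the origin.
#' @return An object of class `volume_grid` with fields `dims`, `voxel_mm`,
#'   `affine`.
#' @export
volume_grid <- function(dims, voxel_mm = c(3, 3, 3), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be three integers >= 1")
  if (is.null(affine)) {
    voxel_mm <- as.numeric(voxel_mm)
    if (length(voxel_mm) != 3L || any(voxel_mm <= 0))
      stop("voxel_mm must be three positive lengths")
    affine <- diag(c(voxel_mm, 1))
    affine[1:3, 4] <- -voxel_mm * (dims - 1) / 2
  } else {
    affine <- unname(as.matrix(affine))
    if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
    if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
    voxel_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  if (any(!is.finite(affine))) stop("affine must be finite")
  structure(list(dims = dims, voxel_mm = as.numeric(voxel_mm),
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$dims, b$dims) && max(abs(a$affine - b$affine)) < tol
}

#' Map voxel indices to MNI mm coordinates
#'
#' Applies the grid affine to 0-based voxel indices. `index` may be a single
#' triple or an n x 3 matrix.
#'
#' @param grid a [volume_grid()].
#' @param index 0-based integer voxel indices, length-3 vector or n x 3 matrix.
#' @return mm coordinates, same shape as the input.
#' @export
voxel_to_mni <- function(grid, index) {
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1)
  if (ncol(idx) != 3L) stop("index must have 3 columns")
  if (any(idx < 0) || any(sweep(idx, 2, grid$dims, ">=")))
    stop("voxel index out of range")
  mm <- t(grid$affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
  if (is.matrix(index)) mm else drop(mm)
}

#' Map MNI mm coordinates to voxel indices
#'
#' Inverse of [voxel_to_mni()]; returns continuous (unrounded) 0-based
#' indices.
#'
#' @inheritParams voxel_to_mni
#' @param mm coordinates in mm, length-3 vector or n x 3 matrix.
#' @export
mni_to_voxel <- function(grid, mm) {
  m <- if (is.matrix(mm)) mm else matrix(mm, nrow = 1)
  if (ncol(m) != 3L) stop("mm must have 3 columns")
  idx <- t(solve(grid$affine) %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  if (is.matrix(mm)) idx else drop(idx)
}

#' Tissue and ROI masks on a common grid
#'
#' Bundles gray-matter, white-matter and CSF masks plus any number of named
#' ROI masks, all as logical 3D arrays on one [volume_grid()]. GM/WM/CSF are
#' made pairwise disjoint by the precedence gm > wm > csf; the number of
#' reassigned voxels is reported via `message()`.
#'
#' @param grid a [volume_grid()].
#' @param gm,wm,csf logical (or coercible) 3D arrays matching `grid$dims`.
#' @param roi_labels named list of logical 3D arrays (ROI masks).
#' @return An object of class `brain_masks`.
#' @export
brain_masks <- function(grid, gm, wm, csf, roi_labels = list()) {
  chk <- function(m, nm) {
    m <- array(as.logical(m), dim = dim(m))
    if (!identical(dim(m), as.integer(grid$dims)))
      stop(sprintf("mask '%s' does not match grid dims", nm))
    if (any(is.na(m))) stop(sprintf("mask '%s' contains NA", nm))
    m
  }
  gm <- chk(gm, "gm"); wm <- chk(wm, "wm"); csf <- chk(csf, "csf")
  overlap <- sum(wm & gm) + sum(csf & (gm | wm))
  if (overlap > 0) {
    wm <- wm & !gm
    csf <- csf & !gm & !wm
    message(sprintf("brain_masks: %d overlapping voxels reassigned by gm > wm > csf precedence", overlap))
  }
  if (!any(gm)) stop("gm mask is empty")
  if (length(roi_labels)) {
    if (is.null(names(roi_labels)) || any(names(roi_labels) == ""))
      stop("roi_labels must be a named list")
    nm <- names(roi_labels)
    roi_labels <- lapply(seq_along(roi_labels), function(i)
      chk(roi_labels[[i]], nm[i]))
    names(roi_labels) <- nm
  }
  structure(list(grid = grid, gm = gm, wm = wm, csf = csf,
                 roi_labels = roi_labels),
            class = "brain_masks")
}

#' @export
print.brain_masks <- function(x, ...) {
  cat(sprintf("<brain_masks> gm %d, wm %d, csf %d voxels; ROIs: %s\n",
              sum(x$gm), sum(x$wm), sum(x$csf),
              if (length(x$roi_labels)) paste(names(x$roi_labels), collapse = ", ")
              else "none"))
  invisible(x)
}

#' One subject's 4D BOLD run
#'
#' @param data 4D numeric array (x, y, z, t) of BOLD values; all finite.
#' @param tr repetition time in seconds (> 0).
#' @param grid the [volume_grid()] of the spatial dimensions.
#' @return An object of class `bold_run` with fields `data`, `tr`, `grid`,
#'   `n_volumes`.
#' @export
bold_run <- function(data, tr, grid) {
  if (length(dim(data)) != 4L) stop("BOLD data must be 4D (x, y, z, t)")
  if (!identical(dim(data)[1:3], as.integer(grid$dims)))
    stop("BOLD spatial dims do not match grid")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a positive scalar in seconds")
  if (any(!is.finite(data))) stop("BOLD data contains non-finite values")
  structure(list(data = data, tr = as.numeric(tr), grid = grid,
                 n_volumes = dim(data)[4]),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d x %d x %d x %d, TR = %g s (%.1f s scan)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$n_volumes,
              x$tr, x$tr * x$n_volumes))
  invisible(x)
}

#' Rigid-body motion trace
#'
#' One row per volume: 3 translations (mm) then 3 rotations (radians).
#'
#' @param params numeric matrix with 6 columns.
#' @param n_volumes if given, the row count is validated against it.
#' @return A `motion_trace` (numeric matrix subclass).
#' @export
motion_trace <- function(params, n_volumes = NULL) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion trace must have 6 columns")
  if (any(!is.finite(params))) stop("motion trace contains non-finite values")
  if (!is.null(n_volumes) && nrow(params) != n_volumes)
    stop("motion trace row count does not match run length")
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(params, class = c("motion_trace", "matrix", "array"))
}

#' Cohort table of subjects, groups and behavioral scores
#'
#' @param df data.frame with columns `id`, `group` and numeric score columns.
#' @param groups allowed group labels.
#' @return A `cohort_table` (data.frame subclass).
#' @export
cohort_table <- function(df, groups = c("HC", "AUD-NCI", "ARCI")) {
  if (!all(c("id", "group") %in% names(df)))
    stop("cohort table needs 'id' and 'group' columns")
  if (anyDuplicated(df$id)) stop("subject ids must be unique")
  if (!all(df$group %in% groups))
    stop(sprintf("group labels must be in {%s}", paste(groups, collapse = ", ")))
  df$id <- as.character(df$id)
  df$group <- factor(df$group, levels = groups)
  structure(df, class = c("cohort_table", "data.frame"))
}
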