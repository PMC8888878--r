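#' Deterministic spherical-shell brain phantom
#'
#' Builds a simple brain-like geometry on a centered grid: a white-matter
#' core, a gray-matter shell around it, and a CSF rim, with three disjoint
#' labeled ROIs embedded in the GM shell ("right_insula", "precuneus",
#' "cerebellum_anterior") at fixed angular positions. The layout is purely
#' geometric and identical across calls with the same arguments; the affine
#' centers the grid midpoint on the MNI origin.
#'
#' Compartments are defined on the normalized ellipsoidal radius r (grid
#' center = 0, corner direction faces = 1): WM r <= 0.52, GM 0.52 < r <=
#' 0.84, CSF 0.84 < r <= 0.98. Each ROI is the intersection of the GM shell
#' with a ball of radius 0.22*nx voxels centered at radial fraction 0.68
#' along a fixed unit direction.
#'
#' @param dims integer triple, each >= 12 (smaller grids cannot host all
#'   compartments with usable ROI sizes).
#' @param voxel_mm voxel edge lengths in mm; default 3 mm isotropic.
#' @return list with elements `grid` ([volume_grid()]) and `masks`
#'   ([brain_masks()]).
#' @export
make_phantom <- function(dims = c(16, 16, 16), voxel_mm = c(3, 3, 3)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L) stop("dims must have length 3")
  if (any(dims < 12L))
    stop("layout error: dims must each be >= 12 to host WM core, GM shell, CSF rim and ROIs")
  grid <- volume_grid(dims, voxel_mm = voxel_mm)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ctr <- (dims - 1) / 2
  ix <- array(rep(0:(nx - 1), ny * nz), dims)
  iy <- array(rep(rep(0:(ny - 1), each = nx), nz), dims)
  iz <- array(rep(0:(nz - 1), each = nx * ny), dims)
  r <- sqrt(((ix - ctr[1]) / ctr[1])^2 + ((iy - ctr[2]) / ctr[2])^2 +
            ((iz - ctr[3]) / ctr[3])^2)
  wm  <- r <= 0.52
  gm  <- r <= 0.84 & !wm
  csf <- r <= 0.98 & !wm & !gm

  ball_roi <- function(u) {
    u <- u / sqrt(sum(u^2))
    p <- ctr + u * 0.68 * ctr
    d <- sqrt((ix - p[1])^2 + (iy - p[2])^2 + (iz - p[3])^2)
    gm & d <= 0.22 * nx
  }
  rois <- list(
    right_insula        = ball_roi(c( 0.95,  0.35, -0.20)),
    precuneus           = ball_roi(c(-0.10, -0.95,  0.45)),
    cerebellum_anterior = ball_roi(c(-0.30, -0.50, -0.85))
  )
  sizes <- vapply(rois, sum, numeric(1))
  if (any(sizes < 1))
    stop("layout error: grid too small, an ROI came out empty")
  pair_overlap <- sum(rois[[1]] & rois[[2]]) + sum(rois[[1]] & rois[[3]]) +
    sum(rois[[2]] & rois[[3]])
  if (pair_overlap > 0) stop("layout error: ROIs overlap on this grid")
  masks <- brain_masks(grid, gm = gm, wm = wm, csf = csf, roi_labels = rois)
  list(grid = grid, masks = masks)
}
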