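#' Voxel grid: shape plus voxel-to-world affine
#'
#' A `voxel_grid` describes the sampling lattice of a volume: the number of
#' voxels per axis and the 4x4 affine mapping 0-based voxel indices to world
#' millimetre coordinates (the NIfTI convention; voxel centres sit at integer
#' indices).
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param affine numeric 4x4 voxel-index-to-world transform; must be
#'   invertible with last row `(0, 0, 0, 1)`.
#' @return An object of class `voxel_grid` with fields `shape`, `affine` and
#'   `voxel_size` (mm edge lengths derived from the affine columns).
#' @examples
#' g <- voxel_grid(c(64, 64, 64), diag(c(2, 2, 2, 1)))
#' g$voxel_size
#' @export
voxel_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("'shape' must be three integers >= 1", call. = FALSE)
  affine <- unclass(affine)
  attributes(affine) <- list(dim = dim(affine))
  if (!is.numeric(affine) || !identical(dim(affine), c(4L, 4L)))
    stop("'affine' must be a numeric 4x4 matrix", call. = FALSE)
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-6)
    stop("'affine' last row must be (0, 0, 0, 1)", call. = FALSE)
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("'affine' is singular", call. = FALSE)
  structure(list(
    shape = shape,
    affine = affine,
    voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))
  ), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' Test whether two voxel grids are compatible
#'
#' Two grids are compatible iff their shapes are equal and their affines agree
#' entrywise within an absolute tolerance, which absorbs float serialization
#' noise without hiding real mismatches.
#'
#' @param a,b `voxel_grid` objects.
#' @param tol absolute tolerance on affine entries (default `1e-5`).
#' @return Logical scalar.
#' @export
grids_compatible <- function(a, b, tol = 1e-5) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

#' Verify that a cohort of masks shares one grid
#'
#' All masks in a cohort must live on the same voxel grid before they can be
#' overlaid; this checks every mask against the first and names the offending
#' subject on mismatch.
#'
#' @param masks non-empty list of [lesion_mask] objects.
#' @return The shared `voxel_grid`.
#' @export
check_cohort_grids <- function(masks) {
  if (length(masks) == 0L)
    stop("empty cohort: no masks supplied", call. = FALSE)
  ref <- masks[[1L]]$grid
  for (m in masks) {
    if (!grids_compatible(ref, m$grid))
      stop(sprintf("grid mismatch: subject '%s' is not on the cohort grid",
                   m$subject_id), call. = FALSE)
  }
  ref
}

# world coords (n x 3, mm) of 0-based voxel indices (n x 3)
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

# 0-based fractional voxel indices (n x 3) of world points (n x 3, mm)
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  t(solve(grid$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

# all voxel centres of a grid as an n x 3 matrix of 0-based indices,
# in R's column-major linear order
grid_indices <- function(grid) {
  s <- grid$shape
  as.matrix(expand.grid(i = 0:(s[1] - 1L), j = 0:(s[2] - 1L),
                        k = 0:(s[3] - 1L), KEEP.OUT.ATTRS = FALSE))
}

# world coords of every voxel centre, linear order matching array storage
grid_world_coords <- function(grid) {
  voxel_to_world(grid, grid_indices(grid))
}
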