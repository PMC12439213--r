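#' Spacing-aware voxel grid
#'
#' An `image_grid` describes the geometry every volumetric object in this
#' package lives on: the array shape in voxels, the physical voxel spacing in
#' millimetres, and the patient-coordinate position (mm) of the *center* of
#' voxel `(1,1,1)`. Voxel `(i,j,k)` (1-based) has its center at
#' `origin + (i-1, j-1, k-1) * spacing`. The z axis increases cranially
#' (towards the head); the caudal cut-off rule for tubular organs relies on
#' this convention.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, voxel spacing in mm (all > 0).
#' @param origin numeric vector of length 3, mm coordinates of the first
#'   voxel center. Defaults to `c(0, 0, 0)`.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(10, 10, 5), spacing = c(1, 1, 2))
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || anyNA(shape) || any(shape < 1L))
    stop("grid shape must be 3 integers, all >= 1")
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("grid spacing must be 3 positive numbers (mm)")
  if (length(origin) != 3L || anyNA(origin))
    stop("grid origin must be 3 numbers (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
format.image_grid <- function(x, ...) {
  sprintf("%dx%dx%d @ (%g,%g,%g) mm", x$shape[1], x$shape[2], x$shape[3],
          x$spacing[1], x$spacing[2], x$spacing[3])
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

grid_axis_mm <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing[axis]
}

#' Binary structure mask on a voxel grid
#'
#' The unit of all geometric comparison: a named structure represented as a
#' 3-D logical occupancy array bound to an [image_grid()].
#'
#' @param voxels logical 3-D array (or array coercible to logical); `TRUE`
#'   marks voxels belonging to the structure.
#' @param grid an [image_grid()] whose shape matches `dim(voxels)`.
#' @param structure_name name of the anatomical structure.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(voxels, grid, structure_name = "structure") {
  if (!inherits(grid, "image_grid")) stop("grid must be an image_grid")
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  if (anyNA(voxels)) stop("mask voxels must not contain NA")
  if (!identical(as.integer(dim(voxels)), grid$shape))
    stop(sprintf("mask shape (%s) does not match grid shape (%s)",
                 paste(dim(voxels), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  structure(list(voxels = voxels, grid = grid,
                 structure_name = as.character(structure_name)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("structure_mask '%s': %d voxels set on %s (%.3f cc)\n",
              x$structure_name, sum(x$voxels), format(x$grid), volume_cc(x)))
  invisible(x)
}

#' Structure volume in cubic centimetres
#'
#' Volume is the set-voxel count times the voxel volume
#' `sx * sy * sz / 1000` cc. An empty mask has volume 0.
#'
#' @param mask a [structure_mask()].
#' @return Volume in cc.
#' @examples
#' g <- image_grid(c(10, 10, 10))
#' v <- array(TRUE, c(10, 10, 10))
#' volume_cc(structure_mask(v, g))  # 1000 mm^3 = 1 cc
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$voxels) * prod(mask$grid$spacing) / 1000
}

n_voxels <- function(mask) sum(mask$voxels)

is_empty_mask <- function(mask) !any(mask$voxels)

# Bounding box of set voxels as list(lo, hi) of 1-based index triples,
# or NULL for an empty mask.
mask_bbox <- function(mask) {
  bb <- cpp_bbox(mask$voxels, dim(mask$voxels))
  if (!length(bb)) return(NULL)
  list(lo = bb[1:3], hi = bb[4:6])
}

# Crop a mask to an index window, producing a mask on a subgrid whose origin
# is shifted so physical coordinates are preserved.
crop_mask <- function(mask, lo, hi) {
  g <- mask$grid
  lo <- pmax(as.integer(lo), 1L)
  hi <- pmin(as.integer(hi), g$shape)
  sub <- array(cpp_crop3d(mask$voxels, dim(mask$voxels), lo, hi),
               dim = hi - lo + 1L)
  newg <- image_grid(hi - lo + 1L, g$spacing, g$origin + (lo - 1L) * g$spacing)
  structure_mask(sub, newg, mask$structure_name)
}

# Common crop of two same-grid masks to the union bounding box plus a margin;
# exact for all surface-distance and overlap metrics.
crop_pair <- function(a, b, margin = 1L) {
  ba <- mask_bbox(a); bb <- mask_bbox(b)
  if (is.null(ba) || is.null(bb)) return(list(a = a, b = b))
  lo <- pmin(ba$lo, bb$lo) - margin
  hi <- pmax(ba$hi, bb$hi) + margin
  list(a = crop_mask(a, lo, hi), b = crop_mask(b, lo, hi))
}

# Physical (mm) coordinates of set voxel centers, n x 3 matrix.
voxel_coords_mm <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$grid$spacing, "*"), 2, mask$grid$origin, "+")
}
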