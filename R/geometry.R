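#' Surface voxels of a structure
#'
#' The surface is the set of voxels that are set in the mask but not in its
#' face-connected (6-neighbourhood) binary erosion. Outside the array counts
#' as background, so voxels on the array border are surface; an isolated
#' voxel is its own surface.
#'
#' @param mask a non-empty [structure_mask()].
#' @return A `surface_set`: list with `voxels` (logical array of surface
#'   membership) and `grid`.
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  if (is_empty_mask(mask)) stop("empty structure: no surface")
  eroded <- cpp_erode6(mask$voxels, dim(mask$voxels))
  surf <- mask$voxels & !array(eroded, dim = dim(mask$voxels))
  structure(list(voxels = surf, grid = mask$grid,
                 structure_name = mask$structure_name),
            class = "surface_set")
}

#' Directed surface distances
#'
#' For every voxel of surface `from`, the Euclidean distance in mm to the
#' nearest voxel of surface `to`, computed with an exact distance transform
#' whose per-axis sampling equals the voxel spacing. Distances are measured
#' between voxel centers.
#'
#' @param from,to `surface_set` objects on the same grid.
#' @return Numeric vector of distances (mm), one per voxel of `from`.
#' @export
directed_surface_distances <- function(from, to) {
  if (!same_grid(from$grid, to$grid))
    stop("surface sets are on different grids")
  if (!any(from$voxels) || !any(to$voxels)) stop("empty surface set")
  edt <- cpp_edt(to$voxels, dim(to$voxels), to$grid$spacing)
  edt <- array(edt, dim = dim(to$voxels))
  as.numeric(edt[from$voxels])
}

check_pair <- function(a, b) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  if (!same_grid(a$grid, b$grid))
    stop(sprintf("masks '%s' and '%s' are on different grids",
                 a$structure_name, b$structure_name))
}

#' Dice similarity coefficient
#'
#' Voxel-counting overlap `2|A intersect B| / (|A| + |B|)`; 1 means
#' identical occupancy, 0 disjoint.
#'
#' @param a,b [structure_mask()] objects on the same grid, not both empty.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_pair(a, b)
  na <- n_voxels(a); nb <- n_voxels(b)
  if (na + nb == 0L) stop("undefined DSC: both masks empty")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

surface_pair_distances <- function(a, b) {
  check_pair(a, b)
  if (is_empty_mask(a) || is_empty_mask(b)) stop("empty structure mask")
  cp <- crop_pair(a, b)
  sa <- surface_voxels(cp$a)
  sb <- surface_voxels(cp$b)
  list(ab = directed_surface_distances(sa, sb),
       ba = directed_surface_distances(sb, sa))
}

#' Hausdorff distance
#'
#' Symmetric maximum surface distance: the larger of the two directed
#' maxima of nearest-surface distances between the masks' surfaces.
#'
#' @inheritParams dice
#' @return Distance in mm.
#' @export
hausdorff <- function(a, b) {
  d <- surface_pair_distances(a, b)
  max(max(d$ab), max(d$ba))
}

#' Mean surface distance
#'
#' The average-symmetric-surface-distance convention: the mean of the two
#' directed mean nearest-surface distances,
#' `(mean(Sa -> Sb) + mean(Sb -> Sa)) / 2`.
#'
#' @inheritParams dice
#' @return Distance in mm.
#' @export
mean_surface_distance <- function(a, b) {
  d <- surface_pair_distances(a, b)
  (mean(d$ab) + mean(d$ba)) / 2
}

#' Signed volume difference
#'
#' `vd_cc = volume(test) - volume(ref)` in cc, and its relative form
#' `100 * vd_cc / volume(ref)` in percent. The reference volume is the
#' denominator; an empty reference leaves the relative form `NA`.
#'
#' @param test,ref [structure_mask()] objects on the same grid.
#' @return List with `vd_cc` and `vd_rel_pct`.
#' @export
volume_difference <- function(test, ref) {
  check_pair(test, ref)
  vt <- volume_cc(test); vr <- volume_cc(ref)
  list(vd_cc = vt - vr,
       vd_rel_pct = if (vr > 0) 100 * (vt - vr) / vr else NA_real_)
}

mask_centroid_mm <- function(mask) {
  cen <- cpp_centroid(mask$voxels, dim(mask$voxels))
  if (cen[4] == 0) stop("empty structure mask: centroid undefined")
  mask$grid$origin + cen[1:3] * mask$grid$spacing
}

#' Centre-of-mass difference
#'
#' Euclidean distance in mm between the occupancy centroids of the two
#' masks, in physical (spacing-scaled) coordinates.
#'
#' @inheritParams dice
#' @return Distance in mm.
#' @export
centre_of_mass_difference <- function(a, b) {
  check_pair(a, b)
  sqrt(sum((mask_centroid_mm(a) - mask_centroid_mm(b))^2))
}

#' Harmonize the caudal extent of tubular structures
#'
#' For structures such as the spinal cord whose caudal (inferior) extent is
#' delineation-dependent, surface metrics are only comparable over a common
#' longitudinal range. All masks in the comparison are truncated at the
#' caudal end of the structure that ends first, i.e. at the most cranial of
#' the masks' lowest occupied slices (z increases cranially). Slices at and
#' above the cut survive unchanged; the operation is idempotent.
#'
#' @param masks list of two or more non-empty [structure_mask()] objects on
#'   a common grid.
#' @return List of truncated masks, same order.
#' @export
apply_caudal_cutoff <- function(masks) {
  if (length(masks) < 2) stop("caudal cut-off needs >= 2 masks")
  for (m in masks)
    if (is_empty_mask(m)) stop("caudal cut-off on an empty mask")
  g <- masks[[1]]$grid
  for (m in masks) check_pair(masks[[1]], m)
  lowest <- vapply(masks, function(m) {
    occ <- which(apply(m$voxels, 3, any))
    occ[1]
  }, numeric(1))
  zstar <- max(lowest)
  lapply(masks, function(m) {
    if (zstar > 1) m$voxels[, , seq_len(zstar - 1)] <- FALSE
    m
  })
}

#' Full geometric comparison of a test mask against a reference
#'
#' Computes the five agreement metrics — mean surface distance, Dice
#' similarity coefficient, Hausdorff distance, signed volume difference
#' (absolute and relative) and centre-of-mass difference — with the
#' conventions of the individual metric functions. If either mask is empty
#' the metrics are returned as `NA` with a `reason` so a cohort run can
#' continue. Tubular structures must be passed through
#' [apply_caudal_cutoff()] beforehand; [run_study()] enforces this by
#' structure name.
#'
#' @param test,ref [structure_mask()] objects on the same grid.
#' @return A one-row data.frame with columns `msd_mm`, `dsc`, `hd_mm`,
#'   `vd_cc`, `vd_rel_pct`, `cmd_mm` and `reason` (`NA` when all metrics
#'   were computed).
#' @export
evaluate_pair <- function(test, ref) {
  as.data.frame(eval_pair_core(test, ref), stringsAsFactors = FALSE)
}

eval_pair_core <- function(test, ref) {
  check_pair(test, ref)
  if (is_empty_mask(test) || is_empty_mask(ref)) {
    reason <- if (is_empty_mask(ref)) "empty reference mask" else "empty test mask"
    return(list(msd_mm = NA_real_, dsc = NA_real_, hd_mm = NA_real_,
                vd_cc = NA_real_, vd_rel_pct = NA_real_, cmd_mm = NA_real_,
                reason = reason))
  }
  d <- surface_pair_distances(test, ref)
  vd <- volume_difference(test, ref)
  list(
    msd_mm = (mean(d$ab) + mean(d$ba)) / 2,
    dsc = dice(test, ref),
    hd_mm = max(max(d$ab), max(d$ba)),
    vd_cc = vd$vd_cc,
    vd_rel_pct = vd$vd_rel_pct,
    cmd_mm = centre_of_mass_difference(test, ref),
    reason = NA_character_)
}
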