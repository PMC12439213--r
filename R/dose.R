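#' Dose distribution on a voxel grid
#'
#' @param dose 3-D numeric array of absorbed dose in Gy, all values >= 0.
#' @param grid an [image_grid()] matching `dim(dose)`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(dose, grid) {
  if (!inherits(grid, "image_grid")) stop("grid must be an image_grid")
  dose <- array(as.numeric(dose), dim = dim(dose))
  if (!identical(as.integer(dim(dose)), grid$shape))
    stop("dose array shape does not match grid shape")
  if (anyNA(dose) || any(dose < 0)) stop("dose values must be non-negative")
  structure(list(dose = dose, grid = grid), class = "dose_grid")
}

#' Read a dose distribution from a NIfTI file
#'
#' Voxel values are interpreted as Gy; spacing and origin come from the
#' header as for [read_mask_volume()].
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [dose_grid()].
#' @export
read_dose_volume <- function(path) {
  vol <- read_volume(path)
  dose_grid(vol$data, vol$grid)
}

#' Write a dose distribution to a NIfTI file
#'
#' @param dose a [dose_grid()].
#' @param path output path.
#' @export
write_dose_volume <- function(dose, path) {
  write_volume(dose$dose, dose$grid, path)
}

# Crop (or verify) a dose grid onto a mask's grid. The mask grid must be an
# axis-aligned integer-voxel window of the dose grid.
dose_on_grid <- function(dose, grid) {
  if (same_grid(dose$grid, grid)) return(dose)
  if (any(abs(dose$grid$spacing - grid$spacing) > 1e-6))
    stop("dose grid and mask grid have different spacing; resampling is not supported")
  off <- (grid$origin - dose$grid$origin) / dose$grid$spacing
  if (any(abs(off - round(off)) > 1e-6))
    stop("mask grid is not voxel-aligned with the dose grid")
  lo <- as.integer(round(off)) + 1L
  hi <- lo + grid$shape - 1L
  if (any(lo < 1L) || any(hi > dose$grid$shape))
    stop("mask grid extends outside the dose grid")
  dose_grid(dose$dose[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE], grid)
}

#' DVH summary of a structure from a dose grid
#'
#' Computes Dmin, Dmax, Dmean and Dmedian over the voxels of the mask. Dmax
#' is the absolute maximum single-voxel dose within the structure (on a
#' 2.5 mm dose grid one voxel represents 0.0156 cc). Dmedian over an even
#' voxel count is the mean of the two central values.
#'
#' @param dose a [dose_grid()] on the mask's grid (or a larger grid the
#'   mask's grid is a voxel-aligned window of).
#' @param mask a non-empty [structure_mask()].
#' @return One-row data.frame: `structure_name`, `d_min`, `d_max`, `d_mean`,
#'   `d_median` (Gy).
#' @export
dvh_from_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "structure_mask"))
  if (is_empty_mask(mask)) stop("empty structure mask: DVH undefined")
  dose <- dose_on_grid(dose, mask$grid)
  vals <- dose$dose[mask$voxels]
  data.frame(structure_name = mask$structure_name,
             d_min = min(vals), d_max = max(vals),
             d_mean = mean(vals), d_median = stats::median(vals),
             stringsAsFactors = FALSE)
}

# Scalar dose metric over a mask, without the summary-table wrapper.
dose_metric_value <- function(dose, mask, metric) {
  dose <- dose_on_grid(dose, mask$grid)
  vals <- dose$dose[mask$voxels]
  switch(metric,
         d_min = min(vals), d_max = max(vals),
         d_mean = mean(vals), d_median = stats::median(vals),
         stop("unknown dose metric: ", metric))
}

#' Signed dose-metric difference between two DVH summaries
#'
#' @param test,ref one-row DVH summaries (as from [dvh_from_dose()] or rows
#'   of [read_dvh_export()]) for the same structure.
#' @param metric one of `"d_min"`, `"d_max"`, `"d_mean"`, `"d_median"`.
#' @return `test - ref` for the requested metric, in Gy.
#' @export
dose_difference <- function(test, ref, metric = c("d_mean", "d_max", "d_min", "d_median")) {
  metric <- match.arg(metric)
  if (!identical(as.character(test$structure_name), as.character(ref$structure_name)))
    stop(sprintf("structure name mismatch: '%s' vs '%s'",
                 test$structure_name, ref$structure_name))
  as.numeric(test[[metric]]) - as.numeric(ref[[metric]])
}

# Default clinical-goal mapping: serial organs and the mandible are judged
# by maximum dose, parallel organs by mean dose.
default_metric_policy <- c(
  brainstem = "d_max", spinalcord = "d_max", spinal_cord = "d_max",
  mandible = "d_max",
  parotid_l = "d_mean", parotid_r = "d_mean", parotid = "d_mean",
  larynx = "d_mean", oral_cavity = "d_mean", oralcavity = "d_mean",
  pcm = "d_mean", pharynx_constrictor = "d_mean",
  submandibular = "d_mean", submandibular_r = "d_mean",
  submandibular_l = "d_mean",
  thyroid = "d_mean", cochlea = "d_mean", cochlea_l = "d_mean",
  cochlea_r = "d_mean")

normalize_organ_name <- function(x) gsub("[^a-z0-9]+", "_", tolower(trimws(x)))

#' Clinical dose metric for an organ
#'
#' Maps a structure name to the dose metric it is judged by: `d_max` for
#' serial organs (brainstem, spinal cord) and the mandible, `d_mean` for
#' parallel organs (parotids, larynx, oral cavity, pharyngeal constrictors,
#' submandibular glands, thyroid, cochleas). The mapping can be extended or
#' overridden through `policy`; names are matched case-insensitively after
#' normalizing separators.
#'
#' @param structure_name structure name, e.g. `"Brainstem"` or
#'   `"Parotid_L"`.
#' @param policy optional named character vector mapping normalized organ
#'   names to `"d_max"` / `"d_mean"`, overriding the default.
#' @return `"d_max"` or `"d_mean"`.
#' @export
organ_metric_policy <- function(structure_name, policy = NULL) {
  key <- normalize_organ_name(structure_name)
  map <- default_metric_policy
  if (!is.null(policy)) {
    names(policy) <- normalize_organ_name(names(policy))
    map[names(policy)] <- policy
  }
  if (!is.na(map[key])) return(unname(map[key]))
  # fall back to the base organ name without laterality suffix
  base <- sub("_(l|r|left|right)$", "", key)
  if (!is.na(map[base])) return(unname(map[base]))
  stop(sprintf("no dose-metric policy for structure '%s'; add it to the policy map",
               structure_name))
}
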