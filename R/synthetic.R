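#' Digital head-and-neck phantom specification
#'
#' Defines a ground-truth anatomy of parametric organ-at-risk analogues on a
#' spacing-aware grid: ellipsoids for compact glands and cavities, elliptic
#' cylinders along z for the brainstem and spinal-cord analogues, and a
#' torus arc (horseshoe) for the mandible analogue. The default phantom has
#' the twelve structures of a typical head-and-neck OAR set on a 96 x 96 x
#' 64 grid at 2 mm isotropic spacing; z increases cranially. Every organ
#' must fit inside the grid with at least a 2-voxel margin, and the
#' spinal-cord analogue spans well over 10 slices.
#'
#' @param grid an [image_grid()]; default 96 x 96 x 64 at 2 mm.
#' @param organs list of organ definitions; each a list with `name`,
#'   `shape` (`"ellipsoid"`, `"cylinder"` or `"torus_arc"`), geometric
#'   parameters in mm, and flags `tubular` (caudal cut-off applies) and
#'   `present`. Defaults to the twelve-organ head-and-neck set.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = image_grid(c(96, 96, 64), spacing = c(2, 2, 2)),
                         organs = default_organs()) {
  spec <- structure(list(grid = grid, organs = organs), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @export
default_organs <- function() {
  list(
    list(name = "brainstem", shape = "cylinder", center = c(95, 80, NA),
         radii = c(10, 12), zrange = c(90, 120), tubular = TRUE, present = TRUE),
    list(name = "spinal_cord", shape = "cylinder", center = c(95, 80, NA),
         radii = c(6, 6), zrange = c(10, 88), tubular = TRUE, present = TRUE),
    list(name = "larynx", shape = "ellipsoid", center = c(95, 110, 55),
         radii = c(18, 15, 16), tubular = FALSE, present = TRUE),
    list(name = "mandible", shape = "torus_arc", center = c(95, 105, 78),
         major_radius = 32, minor_radius = 5, arc_open_frac = 0.4,
         tubular = FALSE, present = TRUE),
    list(name = "oral_cavity", shape = "ellipsoid", center = c(95, 118, 78),
         radii = c(22, 18, 12), tubular = FALSE, present = TRUE),
    list(name = "parotid_l", shape = "ellipsoid", center = c(140, 90, 85),
         radii = c(12, 14, 16), tubular = FALSE, present = TRUE),
    list(name = "parotid_r", shape = "ellipsoid", center = c(50, 90, 85),
         radii = c(12, 14, 16), tubular = FALSE, present = TRUE),
    list(name = "pcm", shape = "cylinder", center = c(95, 95, NA),
         radii = c(16, 6), zrange = c(50, 85), tubular = FALSE, present = TRUE),
    list(name = "cochlea_l", shape = "ellipsoid", center = c(125, 75, 104),
         radii = c(3.2, 3.2, 3.2), tubular = FALSE, present = TRUE),
    list(name = "cochlea_r", shape = "ellipsoid", center = c(65, 75, 104),
         radii = c(3.2, 3.2, 3.2), tubular = FALSE, present = TRUE),
    list(name = "submandibular_r", shape = "ellipsoid", center = c(70, 118, 62),
         radii = c(10, 10, 12), tubular = FALSE, present = TRUE),
    list(name = "thyroid", shape = "ellipsoid", center = c(95, 108, 28),
         radii = c(18, 10, 12), tubular = FALSE, present = TRUE)
  )
}

# Analytic (pre-rasterization) bounding box of an organ, in mm.
organ_bbox_mm <- function(org) {
  switch(org$shape,
    ellipsoid = list(lo = org$center - org$radii, hi = org$center + org$radii),
    cylinder = list(lo = c(org$center[1:2] - org$radii, org$zrange[1]),
                    hi = c(org$center[1:2] + org$radii, org$zrange[2])),
    torus_arc = {
      r <- org$major_radius + org$minor_radius
      list(lo = c(org$center[1:2] - r, org$center[3] - org$minor_radius),
           hi = c(org$center[1:2] + r, org$center[3] + org$minor_radius))
    },
    stop("unknown organ shape: ", org$shape))
}

validate_phantom_spec <- function(spec, margin_voxels = 2) {
  g <- spec$grid
  lo_mm <- g$origin + (margin_voxels - 1) * g$spacing
  hi_mm <- g$origin + (g$shape - margin_voxels) * g$spacing
  for (org in spec$organs) {
    if (!isTRUE(org$present)) next
    bb <- organ_bbox_mm(org)
    if (any(bb$lo < lo_mm) || any(bb$hi > hi_mm))
      stop(sprintf("organ '%s' does not fit inside the grid with a %d-voxel margin",
                   org$name, margin_voxels))
    if (isTRUE(org$tubular) && org$shape == "cylinder") {
      if (diff(org$zrange) / g$spacing[3] < 10)
        stop(sprintf("tubular organ '%s' spans fewer than 10 slices", org$name))
    }
  }
  invisible(spec)
}

# Rasterize one organ's implicit equation at voxel centers, on a cropped
# subgrid (bbox + pad voxels) or on the full grid.
rasterize_organ <- function(org, grid, crop = FALSE, pad_voxels = 0L) {
  if (crop) {
    bb <- organ_bbox_mm(org)
    lo <- pmax(1L, floor((bb$lo - grid$origin) / grid$spacing) + 1L - pad_voxels)
    hi <- pmin(grid$shape, ceiling((bb$hi - grid$origin) / grid$spacing) + 1L + pad_voxels)
    sub <- image_grid(hi - lo + 1L, grid$spacing, grid$origin + (lo - 1L) * grid$spacing)
  } else {
    sub <- grid
  }
  xs <- grid_axis_mm(sub, 1); ys <- grid_axis_mm(sub, 2); zs <- grid_axis_mm(sub, 3)
  vox <- switch(org$shape,
    ellipsoid = {
      q2 <- outer(((xs - org$center[1]) / org$radii[1])^2,
                  ((ys - org$center[2]) / org$radii[2])^2, "+")
      zt <- ((zs - org$center[3]) / org$radii[3])^2
      arr <- array(FALSE, sub$shape)
      for (k in seq_along(zs)) arr[, , k] <- q2 + zt[k] <= 1
      arr
    },
    cylinder = {
      q2 <- outer(((xs - org$center[1]) / org$radii[1])^2,
                  ((ys - org$center[2]) / org$radii[2])^2, "+") <= 1
      inz <- zs >= org$zrange[1] & zs <= org$zrange[2]
      arr <- array(FALSE, sub$shape)
      for (k in which(inz)) arr[, , k] <- q2
      arr
    },
    torus_arc = {
      dx <- xs - org$center[1]; dy <- ys - org$center[2]
      rho <- sqrt(outer(dx^2, dy^2, "+"))
      ring <- (rho - org$major_radius)^2
      # horseshoe: drop the posterior part of the ring (low y side)
      arc <- outer(rep(TRUE, length(dx)),
                   dy >= -org$arc_open_frac * org$major_radius, "&")
      arr <- array(FALSE, sub$shape)
      for (k in seq_along(zs)) {
        zt <- (zs[k] - org$center[3])^2
        arr[, , k] <- (ring + zt <= org$minor_radius^2) & arc
      }
      arr
    },
    stop("unknown organ shape: ", org$shape))
  structure_mask(vox, sub, org$name)
}

#' Rasterize a phantom specification to ground-truth masks
#'
#' Each organ is rasterized from its implicit equation at voxel centers;
#' the result is deterministic. With `crop = TRUE` each mask is returned on
#' its own bounding subgrid (origin-shifted, physically identical), which
#' all derived observer contours share — this is how [make_cohort()] keeps
#' full-cohort runs fast.
#'
#' @param spec a [phantom_spec()].
#' @param crop return per-organ bounding subgrids instead of full-grid
#'   masks.
#' @param pad_voxels padding around the analytic bounding box when
#'   cropping.
#' @return Named list of [structure_mask()], one per present organ.
#' @export
make_phantom <- function(spec, crop = FALSE, pad_voxels = 10L) {
  validate_phantom_spec(spec)
  organs <- Filter(function(o) isTRUE(o$present), spec$organs)
  masks <- lapply(organs, rasterize_organ, grid = spec$grid,
                  crop = crop, pad_voxels = pad_voxels)
  names(masks) <- vapply(organs, `[[`, character(1), "name")
  masks
}

#' Observer noise model for one contour group
#'
#' Observer variation is modeled as a smooth random displacement of the
#' ground-truth boundary: a white Gaussian field is smoothed with a ~6 mm
#' Gaussian kernel, rescaled to `radial_sd_mm`, added (together with a
#' systematic margin) to the signed distance function of the ground truth,
#' and re-thresholded at zero. Tubular organs additionally get a random
#' caudal-extent jitter. Default magnitudes encode the study conditions the
#' generator emulates: manual observers are noisiest (2.0 mm), adjusted AI
#' contours much tighter (0.8 mm), and raw AI output tightest (0.6 mm) but
#' with a +0.5 mm systematic expansion bias.
#'
#' @param group `"manual"`, `"adjusted"` or `"ai_only"`.
#' @param radial_sd_mm SD of the random boundary displacement (mm).
#' @param systematic_margin_mm signed uniform expansion (+) / contraction
#'   (-) bias in mm.
#' @param caudal_jitter_slices maximum caudal-end shift (slices) for
#'   tubular organs.
#' @param smooth_sigma_mm correlation length of the boundary noise.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(group = c("manual", "adjusted", "ai_only"),
                           radial_sd_mm = NULL, systematic_margin_mm = NULL,
                           caudal_jitter_slices = NULL, smooth_sigma_mm = 6) {
  group <- match.arg(group)
  defaults <- list(
    manual = list(sd = 2.0, margin = 0.0, jitter = 2L),
    adjusted = list(sd = 0.8, margin = 0.2, jitter = 1L),
    ai_only = list(sd = 0.6, margin = 0.5, jitter = 0L))[[group]]
  structure(list(
    group = group,
    radial_sd_mm = if (is.null(radial_sd_mm)) defaults$sd else radial_sd_mm,
    systematic_margin_mm = if (is.null(systematic_margin_mm)) defaults$margin else systematic_margin_mm,
    caudal_jitter_slices = if (is.null(caudal_jitter_slices)) defaults$jitter else as.integer(caudal_jitter_slices),
    smooth_sigma_mm = smooth_sigma_mm), class = "observer_model")
}

# Deterministic 32-bit sub-seed from a base seed and string labels.
derive_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(labels)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Perturb a ground-truth mask with observer noise
#'
#' Applies the [observer_model()] displacement model to a ground-truth
#' mask. The signed distance function of the mask (spacing-aware, voxel
#' centers) is shifted by a smooth random field scaled to `radial_sd_mm`
#' plus the systematic margin, and re-thresholded; tubular organs get
#' caudal jitter (positive shifts clear caudal slices, negative shifts
#' extend the caudal end by replicating the lowest occupied slice). The RNG
#' stream is derived deterministically from `(seed, observer_id,
#' patient_id, organ name)`, so the same identifiers always reproduce the
#' same contour. With zero noise, zero margin and zero jitter the ground
#' truth is returned unchanged. If the perturbation empties the mask it is
#' retried once with halved noise, then fails.
#'
#' @param gt non-empty ground-truth [structure_mask()].
#' @param model an [observer_model()].
#' @param observer_id,patient_id identifiers entering the RNG stream.
#' @param tubular apply caudal jitter.
#' @param seed base seed.
#' @param prep precomputed signed-distance preparation for `gt` (internal;
#'   lets a cohort generator share the ground-truth distance field across
#'   observers).
#' @return A [structure_mask()] on the same grid as `gt`.
#' @export
perturb_mask <- function(gt, model, observer_id = "obs1", patient_id = "p1",
                         tubular = FALSE, seed = 1, prep = NULL) {
  stopifnot(inherits(gt, "structure_mask"), inherits(model, "observer_model"))
  if (is_empty_mask(gt)) stop("cannot perturb an empty ground-truth mask")
  if (model$radial_sd_mm == 0 && model$systematic_margin_mm == 0 &&
      (model$caudal_jitter_slices == 0 || !tubular))
    return(gt)
  sub_seed <- derive_seed(seed, model$group, observer_id, patient_id,
                          gt$structure_name)
  if (is.null(prep)) prep <- perturb_prep(gt, model)
  with_local_seed(sub_seed, {
    out <- perturb_once(gt, model, model$radial_sd_mm, tubular, prep)
    if (is_empty_mask(out))
      out <- perturb_once(gt, model, model$radial_sd_mm / 2, tubular, prep)
    if (is_empty_mask(out))
      stop(sprintf("perturbation emptied structure '%s'", gt$structure_name))
    out
  })
}

# Padding (voxels) of the working crop around the ground-truth bounding box:
# wide enough for any plausible boundary excursion (margin + 3 SD) plus a
# voxel of slack.
perturb_pad <- function(gt, model) {
  pad_mm <- abs(model$systematic_margin_mm) + 3 * model$radial_sd_mm +
    mean(gt$grid$spacing)
  as.integer(ceiling(pad_mm / gt$grid$spacing)) + 1L
}

# Signed distance field of the ground truth on a padded crop; reusable
# across all observers drawn from the same ground truth.
perturb_prep <- function(gt, model) {
  g <- gt$grid
  pad <- perturb_pad(gt, model)
  bb <- mask_bbox(gt)
  lo <- pmax(bb$lo - pad, 1L); hi <- pmin(bb$hi + pad, g$shape)
  work <- crop_mask(gt, lo, hi)
  dims <- dim(work$voxels)
  d_out <- cpp_edt(work$voxels, dims, g$spacing)        # distance to structure
  d_in <- cpp_edt(!work$voxels, dims, g$spacing)        # distance to background
  # signed distance to the structure boundary, negative inside. Center-to-
  # center distances overshoot the boundary by about half a voxel on each
  # side, so re-reference by half the mean spacing: a voxel just outside a
  # 2 mm grid sits ~1 mm, not 2 mm, from the surface. Without this, boundary
  # noise below the voxel size could never flip a voxel.
  h <- mean(g$spacing) / 2
  raw <- d_out - d_in
  list(lo = lo, hi = hi, dims = dims, sdf = raw - h * sign(raw))
}

perturb_once <- function(gt, model, radial_sd, tubular, prep) {
  g <- gt$grid
  lo <- prep$lo; hi <- prep$hi; dims <- prep$dims
  sdf <- prep$sdf

  shift <- model$systematic_margin_mm
  if (radial_sd > 0) {
    noise <- stats::rnorm(length(sdf))
    noise <- cpp_smooth_gauss(noise, dims, model$smooth_sigma_mm / g$spacing)
    s <- stats::sd(noise)
    if (s > 0) shift <- shift + noise * (radial_sd / s)
  }
  new_vox <- array(sdf <= shift, dim = dims)

  if (tubular && model$caudal_jitter_slices > 0) {
    jit <- sample.int(2L * model$caudal_jitter_slices + 1L, 1L) -
      model$caudal_jitter_slices - 1L
    occ <- which(apply(new_vox, 3, any))
    if (length(occ)) {
      kmin <- occ[1]
      if (jit > 0) {
        drop <- seq(kmin, min(kmin + jit - 1L, dim(new_vox)[3]))
        new_vox[, , drop] <- FALSE
      } else if (jit < 0) {
        add <- seq(max(1L, kmin + jit), kmin - 1L)
        for (k in add) new_vox[, , k] <- new_vox[, , kmin]
      }
    }
  }

  out <- gt
  out$voxels[] <- FALSE
  out$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- new_vox
  out
}

#' Synthetic dose field with Gaussian target falloff
#'
#' A deterministic stand-in for a planned dose distribution:
#' `dose(v) = prescription * exp(-d(v, center)^2 / (2 * falloff^2))`, with
#' `d` the physical distance from the target center. The default
#' prescription of 68 Gy corresponds to a 2 Gy x 34 fraction schedule.
#'
#' @param grid an [image_grid()].
#' @param target_center_mm mm coordinates of the dose maximum.
#' @param prescription_gy dose at the target center.
#' @param falloff_mm Gaussian falloff length (> 0).
#' @return A [dose_grid()].
#' @export
make_dose <- function(grid, target_center_mm, prescription_gy = 68,
                      falloff_mm = 25) {
  if (falloff_mm <= 0) stop("falloff must be > 0")
  xs <- grid_axis_mm(grid, 1) - target_center_mm[1]
  ys <- grid_axis_mm(grid, 2) - target_center_mm[2]
  zs <- grid_axis_mm(grid, 3) - target_center_mm[3]
  q2 <- outer(xs^2, ys^2, "+")
  arr <- array(0, grid$shape)
  for (k in seq_along(zs))
    arr[, , k] <- prescription_gy * exp(-(q2 + zs[k]^2) / (2 * falloff_mm^2))
  dose_grid(arr, grid)
}

#' Timing model for contouring minutes
#'
#' Per-group log-normal distributions parameterized by their median and a
#' log-scale dispersion. Contouring times are right-skewed; the default
#' medians are 55 min (manual set), 17 min (review + adjustment) and 10 min
#' (AI processing + import), with dispersions that put the bulk of manual
#' times roughly between 20 and 150 minutes.
#'
#' @param manual_median_min,adjusted_median_min,processing_median_min group
#'   medians in minutes.
#' @param manual_sdlog,adjusted_sdlog,processing_sdlog log-normal
#'   dispersions.
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(manual_median_min = 55, adjusted_median_min = 17,
                         processing_median_min = 10,
                         manual_sdlog = 0.5, adjusted_sdlog = 0.4,
                         processing_sdlog = 0.25) {
  structure(list(
    manual = list(median = manual_median_min, sdlog = manual_sdlog),
    adjusted = list(median = adjusted_median_min, sdlog = adjusted_sdlog),
    processing = list(median = processing_median_min, sdlog = processing_sdlog)),
    class = "timing_model")
}

#' Draw a synthetic per-patient timing table
#'
#' One record per patient and timed group (`manual`, `adjusted`,
#' `processing`), drawn from the model's log-normals and rounded to the
#' nearest half minute.
#'
#' @param model a [timing_model()].
#' @param n_patients number of patients.
#' @param seed RNG seed.
#' @return data.frame with columns `patient_id`, `group`, `minutes`.
#' @export
make_timing <- function(model, n_patients, seed = 1) {
  stopifnot(n_patients >= 1)
  with_local_seed(derive_seed(seed, "timing"), {
    rows <- lapply(timing_groups, function(grp) {
      p <- model[[grp]]
      mins <- stats::rlnorm(n_patients, meanlog = log(p$median), sdlog = p$sdlog)
      data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
                 group = grp, minutes = round_half_minute(mins),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic multi-observer contouring study
#'
#' Builds the full study a contour-QA analysis consumes: per-patient
#' ground-truth anatomy (the phantom with small random per-patient
#' anatomical jitter of organ centers), observer contours for each group
#' (several noisy manual observers, a few tighter adjusted observers, one
#' deterministic-per-patient AI output), a dose-field specification per
#' patient, and a timing table. All masks of one (patient, organ) share a
#' common bounding subgrid, so every pairwise comparison is well-defined.
#' The study is fully reproducible from `seed`.
#'
#' @param phantom a [phantom_spec()].
#' @param n_patients number of patients.
#' @param n_manual,n_adjusted number of observers in the manual and
#'   adjusted groups (the AI-only group always has one output).
#' @param observer_models named list of [observer_model()]s for groups
#'   `manual`, `adjusted`, `ai_only`.
#' @param timing a [timing_model()].
#' @param anatomy_jitter_mm SD of the per-patient translation of organ
#'   centers.
#' @param missing optional data.frame with columns `patient_id`,
#'   `oar_name`, `group`, `observer_id` listing contours to omit
#'   (bookkept as exceptions).
#' @param seed master seed.
#' @return An object of class `contour_study`: list with `patients` (per
#'   patient: `gt` masks, `groups` of observer masks, `dose_spec`),
#'   `timing`, `organs` (name/tubular table), `config`, and `exceptions`.
#' @export
make_cohort <- function(phantom = phantom_spec(), n_patients = 10,
                        n_manual = 5, n_adjusted = 3,
                        observer_models = list(manual = observer_model("manual"),
                                               adjusted = observer_model("adjusted"),
                                               ai_only = observer_model("ai_only")),
                        timing = timing_model(), anatomy_jitter_mm = 2,
                        missing = NULL, seed = 1) {
  stopifnot(n_patients >= 1, n_manual >= 1, n_adjusted >= 1)
  organs_tbl <- do.call(rbind, lapply(
    Filter(function(o) isTRUE(o$present), phantom$organs),
    function(o) data.frame(oar_name = o$name, tubular = isTRUE(o$tubular),
                           stringsAsFactors = FALSE)))
  observers <- list(
    manual = sprintf("obs%02d", seq_len(n_manual)),
    adjusted = sprintf("adj%02d", seq_len(n_adjusted)),
    ai_only = "ai")

  patients <- list()
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%02d", p)
    jspec <- with_local_seed(derive_seed(seed, "anatomy", pid), {
      js <- phantom
      js$organs <- lapply(js$organs, function(o) {
        if (!isTRUE(o$present)) return(o)
        o$center <- o$center + stats::rnorm(3, sd = anatomy_jitter_mm)
        o
      })
      # target center follows the pharyngeal region of this patient
      js
    })
    validate_phantom_spec(jspec)
    gt <- make_phantom(jspec, crop = TRUE, pad_voxels = 6L)
    prep_cache <- new.env(parent = emptyenv())
    groups <- lapply(names(observers), function(grp) {
      masks <- lapply(observers[[grp]], function(obs) {
        out <- lapply(names(gt), function(organ) {
          if (is_excluded(missing, pid, organ, grp, obs)) return(NULL)
          model <- observer_models[[grp]]
          key <- paste(organ, paste(perturb_pad(gt[[organ]], model),
                                    collapse = ","))
          if (is.null(prep_cache[[key]]))
            prep_cache[[key]] <- perturb_prep(gt[[organ]], model)
          perturb_mask(gt[[organ]], model,
                       observer_id = obs, patient_id = pid,
                       tubular = organs_tbl$tubular[organs_tbl$oar_name == organ],
                       seed = seed, prep = prep_cache[[key]])
        })
        names(out) <- names(gt)
        Filter(Negate(is.null), out)
      })
      names(masks) <- observers[[grp]]
      masks
    })
    names(groups) <- names(observers)
    target <- with_local_seed(derive_seed(seed, "target", pid),
                              c(95, 100, 66) + stats::rnorm(3, sd = 3))
    patients[[pid]] <- list(gt = gt, groups = groups,
                            dose_spec = list(target_center_mm = target,
                                             prescription_gy = 68,
                                             falloff_mm = 25))
  }

  exceptions <- if (is.null(missing)) {
    data.frame(patient_id = character(), oar_name = character(),
               group = character(), observer_id = character(),
               reason = character(), stringsAsFactors = FALSE)
  } else {
    cbind(missing, reason = "omitted contour", stringsAsFactors = FALSE)
  }

  structure(list(
    grid = phantom$grid, patients = patients,
    timing = make_timing(timing, n_patients, seed = seed),
    organs = organs_tbl,
    exceptions = exceptions,
    config = list(seed = seed, n_patients = n_patients, n_manual = n_manual,
                  n_adjusted = n_adjusted, anatomy_jitter_mm = anatomy_jitter_mm)),
    class = "contour_study")
}

is_excluded <- function(missing, pid, organ, grp, obs) {
  if (is.null(missing) || nrow(missing) == 0) return(FALSE)
  any(missing$patient_id == pid & missing$oar_name == organ &
        missing$group == grp & missing$observer_id == obs)
}

#' Write a synthetic study to disk
#'
#' Emits the study in the formats the I/O layer reads: NIfTI mask volumes
#' (`gt/<patient>/<organ>.nii.gz`,
#' `<group>/<observer>/<patient>/<organ>.nii.gz`), one dose volume per
#' patient, `timing.csv`, and a `manifest.json` with the organ table,
#' generating configuration and exception list.
#'
#' @param study a `contour_study` from [make_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pid in names(study$patients)) {
    pat <- study$patients[[pid]]
    gtdir <- file.path(dir, "gt", pid)
    dir.create(gtdir, recursive = TRUE, showWarnings = FALSE)
    for (organ in names(pat$gt))
      write_mask_volume(pat$gt[[organ]], file.path(gtdir, paste0(organ, ".nii.gz")))
    for (grp in names(pat$groups)) {
      for (obs in names(pat$groups[[grp]])) {
        odir <- file.path(dir, grp, obs, pid)
        dir.create(odir, recursive = TRUE, showWarnings = FALSE)
        for (organ in names(pat$groups[[grp]][[obs]]))
          write_mask_volume(pat$groups[[grp]][[obs]][[organ]],
                            file.path(odir, paste0(organ, ".nii.gz")))
      }
    }
    ddir <- file.path(dir, "dose")
    dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
    ds <- pat$dose_spec
    write_dose_volume(make_dose(study$grid, ds$target_center_mm,
                                ds$prescription_gy, ds$falloff_mm),
                      file.path(ddir, paste0(pid, ".nii.gz")))
  }
  write_timing_csv(study$timing, file.path(dir, "timing.csv"))
  jsonlite::write_json(
    list(grid = list(shape = study$grid$shape, spacing = study$grid$spacing,
                     origin = study$grid$origin),
         organs = study$organs, config = study$config,
         exceptions = study$exceptions,
         dose_specs = lapply(study$patients, `[[`, "dose_spec"),
         patients = names(study$patients)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#'
#' @param dir study directory.
#' @return A `contour_study` (dose kept as per-patient specifications from
#'   the manifest; masks on their stored subgrids).
#' @export
read_study <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  organs_tbl <- as.data.frame(man$organs)
  patients <- list()
  for (pid in man$patients) {
    gtdir <- file.path(dir, "gt", pid)
    gtfiles <- list.files(gtdir, pattern = "\\.nii(\\.gz)?$")
    gt <- lapply(gtfiles, function(f) read_mask_volume(file.path(gtdir, f)))
    names(gt) <- sub("\\.nii(\\.gz)?$", "", gtfiles)
    groups <- list()
    for (grp in c("manual", "adjusted", "ai_only")) {
      gdir <- file.path(dir, grp)
      if (!dir.exists(gdir)) next
      obs_ids <- list.dirs(gdir, recursive = FALSE, full.names = FALSE)
      groups[[grp]] <- lapply(obs_ids, function(obs) {
        odir <- file.path(gdir, obs, pid)
        fs <- list.files(odir, pattern = "\\.nii(\\.gz)?$")
        ms <- lapply(fs, function(f) read_mask_volume(file.path(odir, f)))
        names(ms) <- sub("\\.nii(\\.gz)?$", "", fs)
        ms
      })
      names(groups[[grp]]) <- obs_ids
    }
    dose_spec <- man$dose_specs[[pid]]
    dose_spec$target_center_mm <- as.numeric(dose_spec$target_center_mm)
    patients[[pid]] <- list(gt = gt, groups = groups, dose_spec = dose_spec)
  }
  full_grid <- image_grid(as.integer(man$grid$shape),
                          as.numeric(man$grid$spacing),
                          as.numeric(man$grid$origin))
  structure(list(grid = full_grid, patients = patients,
                 timing = read_timing_csv(file.path(dir, "timing.csv")),
                 organs = organs_tbl,
                 exceptions = as.data.frame(man$exceptions),
                 config = man$config),
            class = "contour_study")
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a
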