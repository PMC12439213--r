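#' Read a planar contour set from JSON
#'
#' Reads the package's documented planar-contour dialect:
#' `{"structure": <name>, "slices": [{"z": <mm>, "polygons": [[[x,y], ...], ...]}, ...]}`.
#' Coordinates are patient coordinates in millimetres. Slices are returned
#' sorted by increasing z; polygon vertex order is preserved.
#'
#' @param path path to a JSON file in the contour dialect.
#' @return A `contour_set`: list with `structure_name` and `slices`, each
#'   slice a list with `z` (mm) and `polygons` (list of n x 2 matrices).
#' @export
read_contour_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed contour JSON: ", conditionMessage(e)))
  if (is.null(obj$structure) || is.null(obj$slices))
    stop("contour JSON must have 'structure' and 'slices' fields")
  slices <- lapply(obj$slices, function(sl) {
    z <- sl$z
    if (is.null(z) || !is.numeric(z))
      stop("contour slice without numeric z coordinate")
    polys <- lapply(sl$polygons, function(p) {
      m <- tryCatch(do.call(rbind, lapply(p, function(pt) {
        pt <- unlist(pt)
        if (length(pt) != 2 || !is.numeric(pt))
          stop("non-numeric coordinate")
        pt
      })), error = function(e)
        stop(sprintf("slice z=%g: %s", z, conditionMessage(e))))
      if (nrow(m) < 3)
        stop(sprintf("slice z=%g: polygon with %d vertices (need >= 3)", z, nrow(m)))
      dimnames(m) <- NULL
      m
    })
    list(z = as.numeric(z), polygons = polys)
  })
  zs <- vapply(slices, `[[`, numeric(1), "z")
  slices <- slices[order(zs)]
  structure(list(structure_name = as.character(obj$structure), slices = slices),
            class = "contour_set")
}

#' Write a contour set to the JSON contour dialect
#'
#' @param contours a `contour_set` as returned by [read_contour_json()].
#' @param path output file path.
#' @export
write_contour_json <- function(contours, path) {
  obj <- list(
    structure = contours$structure_name,
    slices = lapply(contours$slices, function(sl)
      list(z = sl$z,
           polygons = lapply(sl$polygons, function(m)
             lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Even-odd point-in-polygon test for a set of points against one polygon.
# Points whose center lies exactly on a polygon edge count as inside.
points_in_polygon <- function(x, y, poly, tol = 1e-9) {
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  inside <- logical(length(x))
  onedge <- logical(length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
    # edge membership: collinear and within the segment's bounding box
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    seg_len2 <- (xj - xi)^2 + (yj - yi)^2
    on <- abs(cross) <= tol * max(1, sqrt(seg_len2)) &
      x >= pmin(xi, xj) - tol & x <= pmax(xi, xj) + tol &
      y >= pmin(yi, yj) - tol & y <= pmax(yi, yj) + tol
    onedge <- onedge | on
    # crossing-number parity (half-open rule avoids double-counting vertices)
    crosses <- ((yi > y) != (yj > y)) &
      (x < xi + (xj - xi) * (y - yi) / (yj - yi))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onedge
}

#' Rasterize planar contours to a binary volumetric mask
#'
#' A voxel is set iff its center lies inside an odd number of polygons on its
#' slice (even-odd rule); a center exactly on a polygon edge counts as
#' inside. Each contour slice is assigned to the nearest grid slice; a
#' contour z farther than half a slice spacing from every grid slice is an
#' error.
#'
#' @param contours a `contour_set`.
#' @param grid target [image_grid()].
#' @return A [structure_mask()] on `grid`.
#' @export
rasterize <- function(contours, grid) {
  vox <- array(FALSE, dim = grid$shape)
  xs <- grid_axis_mm(grid, 1)
  ys <- grid_axis_mm(grid, 2)
  zs <- grid_axis_mm(grid, 3)
  for (sl in contours$slices) {
    k <- which.min(abs(zs - sl$z))
    if (abs(zs[k] - sl$z) > grid$spacing[3] / 2 + 1e-9)
      stop(sprintf("contour slice z=%g mm is farther than sz/2 from every grid slice", sl$z))
    parity <- matrix(0L, grid$shape[1], grid$shape[2])
    onedge <- matrix(FALSE, grid$shape[1], grid$shape[2])
    for (poly in sl$polygons) {
      # restrict the test to the polygon's bounding box
      irange <- which(xs >= min(poly[, 1]) - 1e-9 & xs <= max(poly[, 1]) + 1e-9)
      jrange <- which(ys >= min(poly[, 2]) - 1e-9 & ys <= max(poly[, 2]) + 1e-9)
      if (!length(irange) || !length(jrange)) next
      pts <- expand.grid(i = irange, j = jrange)
      hit <- points_in_polygon(xs[pts$i], ys[pts$j], poly)
      lin <- cbind(pts$i, pts$j)
      parity[lin[hit, , drop = FALSE]] <- parity[lin[hit, , drop = FALSE]] + 1L
    }
    vox[, , k] <- vox[, , k] | (parity %% 2L == 1L)
  }
  structure_mask(vox, grid, contours$structure_name)
}

#' Read a volumetric mask from a NIfTI file
#'
#' Non-zero voxels become `TRUE`. Voxel spacing is taken from the NIfTI
#' `pixdim` and the origin from the stored transform's translation; the
#' volume is assumed axis-aligned. A file whose spacing metadata is missing
#' or non-positive is rejected.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param structure_name name for the resulting structure; defaults to the
#'   file name without extension.
#' @return A [structure_mask()].
#' @export
read_mask_volume <- function(path, structure_name = NULL) {
  vol <- read_volume(path)
  if (is.null(structure_name))
    structure_name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  structure_mask(vol$data != 0, vol$grid, structure_name)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || anyNA(pd[1:3]) || any(pd[1:3] <= 0))
    stop("volume '", basename(path), "' has missing or non-positive voxel spacing metadata")
  dat <- as.array(img)
  if (length(dim(dat)) == 2L) dim(dat) <- c(dim(dat), 1L)
  if (length(dim(dat)) != 3L)
    stop("volume '", basename(path), "' is not 3-D")
  xf <- RNifti::xform(img)
  origin <- as.numeric(xf[1:3, 4])
  list(data = dat, grid = image_grid(dim(dat), pd[1:3], origin))
}

write_volume <- function(data, grid, path) {
  img <- RNifti::asNifti(data)
  img <- RNifti::`pixdim<-`(img, grid$spacing)
  aff <- diag(4)
  diag(aff)[1:3] <- grid$spacing
  aff[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a structure mask to a NIfTI file
#'
#' Round-trips through [read_mask_volume()]: occupancy, spacing and origin
#' are preserved.
#'
#' @param mask a [structure_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_mask_volume <- function(mask, path) {
  write_volume(array(as.integer(mask$voxels), dim = dim(mask$voxels)),
               mask$grid, path)
}

#' Read DVH summaries from a plain-text export
#'
#' Parses the package's minimal TPS-style block dialect: blocks separated by
#' blank lines, each beginning `Structure: <name>` followed by
#' `Min Dose [Gy]: <v>`, `Max Dose [Gy]: <v>`, `Mean Dose [Gy]: <v>` and
#' `Median Dose [Gy]: <v>` lines (any order). This dialect is a documented
#' stand-in for vendor exports, whose layouts vary; doses are in Gy.
#'
#' @param path path to the text export.
#' @return A data.frame with one row per structure block, in file order:
#'   columns `structure_name`, `d_min`, `d_max`, `d_mean`, `d_median` (Gy).
#' @export
read_dvh_export <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- split(lines, cumsum(trimws(lines) == ""))
  blocks <- lapply(blocks, function(b) b[trimws(b) != ""])
  blocks <- blocks[vapply(blocks, length, 1L) > 0]
  fields <- c(d_min = "Min Dose [Gy]", d_max = "Max Dose [Gy]",
              d_mean = "Mean Dose [Gy]", d_median = "Median Dose [Gy]")
  rows <- lapply(blocks, function(b) {
    sm <- grep("^Structure:", b, value = TRUE)
    if (length(sm) != 1)
      stop("DVH block without a single 'Structure:' line")
    name <- trimws(sub("^Structure:", "", sm))
    vals <- vapply(names(fields), function(f) {
      prefix <- paste0(fields[[f]], ":")
      ln <- b[startsWith(trimws(b), prefix)]
      if (length(ln) != 1)
        stop(sprintf("DVH block for structure '%s' is missing line '%s'",
                     name, fields[[f]]))
      v <- suppressWarnings(as.numeric(substring(trimws(ln), nchar(prefix) + 1)))
      if (is.na(v))
        stop(sprintf("DVH block for structure '%s': non-numeric '%s'",
                     name, fields[[f]]))
      v
    }, numeric(1))
    data.frame(structure_name = name, d_min = vals[["d_min"]],
               d_max = vals[["d_max"]], d_mean = vals[["d_mean"]],
               d_median = vals[["d_median"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write DVH summaries to the plain-text block dialect
#'
#' @param dvh data.frame as returned by [read_dvh_export()] or
#'   [dvh_from_dose()].
#' @param path output path.
#' @export
write_dvh_export <- function(dvh, path) {
  blocks <- vapply(seq_len(nrow(dvh)), function(i) {
    paste(sprintf("Structure: %s", dvh$structure_name[i]),
          sprintf("Min Dose [Gy]: %.6g", dvh$d_min[i]),
          sprintf("Max Dose [Gy]: %.6g", dvh$d_max[i]),
          sprintf("Mean Dose [Gy]: %.6g", dvh$d_mean[i]),
          sprintf("Median Dose [Gy]: %.6g", dvh$d_median[i]),
          sep = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Round minutes to the nearest half minute, ties rounding up
#'
#' Contouring times are registered at half-minute resolution; 17.25 rounds
#' to 17.5.
#'
#' @param minutes numeric vector of minutes.
#' @return Minutes rounded to the nearest 0.5.
#' @export
round_half_minute <- function(minutes) floor(minutes * 2 + 0.5) / 2

timing_groups <- c("manual", "adjusted", "processing")

#' Read a contouring timing table
#'
#' CSV with header `patient_id,group,minutes`. Groups must be one of
#' `manual`, `adjusted` (review + correction of AI output) or `processing`
#' (AI inference + import); AI contouring itself is not a timed human
#' activity. Minutes are rounded to the nearest half minute on ingest (ties
#' round up) and must be non-negative.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns `patient_id`, `group`, `minutes`.
#' @export
read_timing_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "group", "minutes")
  if (!all(need %in% names(df)))
    stop("timing CSV must have columns patient_id, group, minutes")
  bad <- setdiff(unique(df$group), timing_groups)
  if (length(bad))
    stop("unknown timing group(s): ", paste(bad, collapse = ", "),
         " (expected manual, adjusted or processing)")
  if (!is.numeric(df$minutes) || anyNA(df$minutes))
    stop("timing minutes must be numeric")
  if (any(df$minutes < 0)) stop("negative contouring minutes")
  df$minutes <- round_half_minute(df$minutes)
  df$patient_id <- as.character(df$patient_id)
  df[, need]
}

#' Write a contouring timing table
#'
#' @param timing data.frame with columns `patient_id`, `group`, `minutes`.
#' @param path output CSV path.
#' @export
write_timing_csv <- function(timing, path) {
  utils::write.csv(timing[, c("patient_id", "group", "minutes")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
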