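make_contour_json <- function(slices, structure = "roi") {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(structure = structure, slices = slices), path,
                       auto_unbox = TRUE, digits = NA)
  path
}

square <- function(x0, y0, x1, y1)
  list(list(x0, y0), list(x1, y0), list(x1, y1), list(x0, y1))

test_that("contour JSON round-trips and sorts slices by z", {
  p <- make_contour_json(list(
    list(z = 4, polygons = list(square(0, 0, 2, 2))),
    list(z = 2, polygons = list(square(0, 0, 3, 3)))))
  cs <- read_contour_json(p)
  expect_identical(cs$structure_name, "roi")
  expect_equal(vapply(cs$slices, `[[`, numeric(1), "z"), c(2, 4))
  expect_equal(nrow(cs$slices[[2]]$polygons[[1]]), 4)
  # vertex order preserved
  expect_equal(cs$slices[[1]]$polygons[[1]][1, ], c(0, 0))
  p2 <- tempfile(fileext = ".json")
  write_contour_json(cs, p2)
  expect_equal(read_contour_json(p2), cs)
})

test_that("degenerate contour files are rejected with informative errors", {
  p <- make_contour_json(list(
    list(z = 1, polygons = list(list(list(0, 0), list(1, 1))))))
  expect_error(read_contour_json(p), "z=1.*2 vertices")
  p2 <- make_contour_json(list(
    list(z = 3, polygons = list(list(list(0, 0), list("a", 1), list(1, 1))))))
  expect_error(read_contour_json(p2), "z=3")
  p3 <- tempfile(); writeLines("{not json", p3)
  expect_error(read_contour_json(p3), "malformed")
})

test_that("rasterization sets voxels whose centers are inside (even-odd)", {
  g <- image_grid(c(6, 6, 1))
  p <- make_contour_json(list(
    list(z = 0, polygons = list(square(0.5, 0.5, 3.5, 3.5)))))
  m <- rasterize(read_contour_json(p), g)
  expect_equal(sum(m$voxels), 9)
  idx <- which(m$voxels, arr.ind = TRUE)
  expect_setequal(unique(idx[, 1]), c(2, 3, 4))  # centers at 1, 2, 3 mm
  expect_setequal(unique(idx[, 2]), c(2, 3, 4))

  # interior hole via even-odd counting
  ph <- make_contour_json(list(
    list(z = 0, polygons = list(square(0.25, 0.25, 4.75, 4.75),
                                square(0.75, 0.75, 3.25, 3.25)))))
  mh <- rasterize(read_contour_json(ph), g)
  expect_false(mh$voxels[3, 3, 1])   # center (2,2) inside the hole
  expect_true(mh$voxels[5, 5, 1])    # center (4,4) in the ring
  expect_true(mh$voxels[5, 3, 1])    # center (4,2) in the ring

  # empty contour set
  pe <- make_contour_json(list())
  expect_equal(sum(rasterize(read_contour_json(pe), g)$voxels), 0)
})

test_that("contour slices must land within half a slice spacing", {
  g <- image_grid(c(6, 6, 2), spacing = c(1, 1, 2))
  p <- make_contour_json(list(
    list(z = 5.1, polygons = list(square(0.5, 0.5, 3.5, 3.5)))))
  expect_error(rasterize(read_contour_json(p), g), "5.1")
})

test_that("rasterizing a mask's bounding rectangle recovers the mask", {
  # round-trip at voxel resolution for convex (rectangular) shapes
  for (seed in 1:5) {
    set.seed(seed)
    lo <- sort(sample(1:5, 2)); hi <- lo + sample(1:3, 2)
    g <- image_grid(c(10, 10, 1))
    rect <- square(lo[1] - 0.49, lo[2] - 0.49, hi[1] + 0.49, hi[2] + 0.49)
    p <- make_contour_json(list(list(z = 0, polygons = list(rect))))
    m <- rasterize(read_contour_json(p), g)
    expect_equal(sum(m$voxels), (hi[1] - lo[1] + 1) * (hi[2] - lo[2] + 1))
    idx <- which(m$voxels, arr.ind = TRUE)
    # voxel centers are 0-based mm coords: indices are lo+1 .. hi+1
    expect_equal(range(idx[, 1]), c(lo[1], hi[1]) + 1)
  }
})

test_that("no voxel outside the polygon bounding boxes is ever set", {
  g <- image_grid(c(12, 12, 1))
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    poly <- lapply(seq_len(n), function(i) list(runif(1, 1, 9), runif(1, 1, 9)))
    p <- make_contour_json(list(list(z = 0, polygons = list(poly))))
    m <- rasterize(read_contour_json(p), g)
    xs <- vapply(poly, function(pt) pt[[1]], numeric(1))
    ys <- vapply(poly, function(pt) pt[[2]], numeric(1))
    idx <- which(m$voxels, arr.ind = TRUE)
    if (nrow(idx)) {
      expect_true(all(idx[, 1] - 1 >= min(xs) - 1e-9 & idx[, 1] - 1 <= max(xs) + 1e-9))
      expect_true(all(idx[, 2] - 1 >= min(ys) - 1e-9 & idx[, 2] - 1 <= max(ys) + 1e-9))
    }
  }
})

test_that("mask volumes round-trip through NIfTI with metadata intact", {
  g <- image_grid(c(10, 10, 10), spacing = c(1, 1, 2), origin = c(5, -3, 10))
  v <- array(FALSE, c(10, 10, 10)); v[2:3, 4:5, 6:7] <- TRUE
  m <- structure_mask(v, g, "roi")
  f <- tempfile(fileext = ".nii.gz")
  write_mask_volume(m, f)
  m2 <- read_mask_volume(f, "roi")
  expect_identical(m2$voxels, m$voxels)
  expect_equal(m2$grid$spacing, g$spacing)
  expect_equal(m2$grid$origin, g$origin)
  expect_equal(sum(m2$voxels), 8)

  # all-zero volume reads as an all-false mask, no error
  z <- structure_mask(array(FALSE, c(4, 4, 4)), image_grid(c(4, 4, 4)), "z")
  fz <- tempfile(fileext = ".nii.gz")
  write_mask_volume(z, fz)
  expect_false(any(read_mask_volume(fz)$voxels))

  suppressWarnings(expect_error(read_mask_volume(tempfile(fileext = ".nii"))))
})

test_that("DVH text exports parse blockwise with all four dose lines", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("Structure: Brainstem",
               "Min Dose [Gy]: 1.2",
               "Max Dose [Gy]: 52.3",
               "Mean Dose [Gy]: 20.5",
               "Median Dose [Gy]: 18.75",
               "",
               "Structure: Parotid_L",
               "Median Dose [Gy]: 22.0",
               "Min Dose [Gy]: 3.0",
               "Max Dose [Gy]: 60.1",
               "Mean Dose [Gy]: 24.9"), f)
  dvh <- read_dvh_export(f)
  expect_equal(nrow(dvh), 2)
  expect_equal(dvh$structure_name, c("Brainstem", "Parotid_L"))
  expect_equal(dvh$d_max[1], 52.3)
  expect_equal(dvh$d_median[2], 22.0)

  f2 <- tempfile(fileext = ".txt")
  write_dvh_export(dvh, f2)
  expect_equal(read_dvh_export(f2), dvh)

  fbad <- tempfile(fileext = ".txt")
  writeLines(c("Structure: Larynx",
               "Min Dose [Gy]: 1",
               "Mean Dose [Gy]: 2",
               "Median Dose [Gy]: 2"), fbad)
  expect_error(read_dvh_export(fbad), "Larynx.*Max Dose")
})

test_that("timing tables round to half minutes with ties up and valid groups", {
  expect_equal(round_half_minute(17.3), 17.5)
  expect_equal(round_half_minute(17.25), 17.5)  # tie rounds up
  expect_equal(round_half_minute(17.24), 17.0)
  expect_equal(round_half_minute(c(0, 0.2, 0.26)), c(0, 0, 0.5))

  f <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,group,minutes", "P1,manual,17.3",
               "P1,adjusted,8.25", "P1,processing,10"), f)
  tt <- read_timing_csv(f)
  expect_equal(tt$minutes, c(17.5, 8.5, 10))
  expect_true(all(tt$minutes * 2 == floor(tt$minutes * 2)))

  fbad <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,group,minutes", "P1,AI,5"), fbad)
  expect_error(read_timing_csv(fbad), "unknown timing group")
  fneg <- tempfile(fileext = ".csv")
  writeLines(c("patient_id,group,minutes", "P1,manual,-2"), fneg)
  expect_error(read_timing_csv(fneg), "negative")
})
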