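test_that("surface extraction matches the 6-neighbourhood definition", {
  # 3x3x3 solid cube: everything but the center voxel is surface
  cube <- mask_from_indices(as.matrix(expand.grid(2:4, 2:4, 2:4)), c(5, 5, 5))
  s <- surface_voxels(cube)
  expect_equal(sum(s$voxels), 26)
  expect_false(s$voxels[3, 3, 3])

  # a single voxel is its own surface
  one <- mask_from_indices(c(2, 2, 2), c(4, 4, 4))
  expect_equal(sum(surface_voxels(one)$voxels), 1)

  # a 1-voxel-thick plane is all surface (erosion empties it)
  plane <- mask_from_indices(as.matrix(cbind(expand.grid(1:4, 1:4), 2)), c(4, 4, 4))
  expect_equal(sum(surface_voxels(plane)$voxels), 16)

  empty <- structure_mask(array(FALSE, c(3, 3, 3)), image_grid(c(3, 3, 3)))
  expect_error(surface_voxels(empty), "empty")
})

test_that("directed surface distances honour anisotropic spacing", {
  a <- mask_from_indices(c(1, 1, 1), c(8, 8, 8))
  b <- mask_from_indices(c(4, 5, 1), c(8, 8, 8))
  expect_equal(directed_surface_distances(surface_voxels(a), surface_voxels(b)), 5)

  sa <- surface_voxels(a)
  expect_equal(directed_surface_distances(sa, sa), 0)

  az <- mask_from_indices(c(1, 1, 1), c(4, 4, 4), spacing = c(1, 1, 2))
  bz <- mask_from_indices(c(1, 1, 4), c(4, 4, 4), spacing = c(1, 1, 2))
  expect_equal(directed_surface_distances(surface_voxels(az), surface_voxels(bz)), 6)

  other <- mask_from_indices(c(1, 1, 1), c(8, 8, 8), spacing = c(2, 2, 2))
  expect_error(directed_surface_distances(surface_voxels(a), surface_voxels(other)),
               "different grids")
})

test_that("Dice counts voxel overlap", {
  # two 2x2x2 cubes sharing a 2x2x1 slab
  a <- mask_from_indices(as.matrix(expand.grid(1:2, 1:2, 1:2)), c(4, 4, 4))
  b <- mask_from_indices(as.matrix(expand.grid(1:2, 1:2, 2:3)), c(4, 4, 4))
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, a), 1)
  c2 <- mask_from_indices(c(4, 4, 4), c(4, 4, 4))
  expect_equal(dice(a, c2), 0)
  empty <- structure_mask(array(FALSE, c(4, 4, 4)), image_grid(c(4, 4, 4)))
  expect_equal(dice(a, empty), 0)
  expect_error(dice(empty, empty), "undefined DSC")
})

test_that("Hausdorff and MSD equal the brute-force pairwise oracle", {
  set.seed(97)
  for (i in 1:30) {
    sp <- sample(c(1, 1.5, 2, 2.5), 3, replace = TRUE)
    a <- random_mask(c(8, 8, 8), p = 0.2, spacing = sp)
    b <- random_mask(c(8, 8, 8), p = 0.2, spacing = sp)
    expect_equal(hausdorff(a, b), bf_hausdorff(a, b), tolerance = 1e-12)
    expect_equal(mean_surface_distance(a, b), bf_msd(a, b), tolerance = 1e-12)
  }
})

test_that("single-voxel pairs give exact Euclidean metrics", {
  a <- mask_from_indices(c(1, 1, 1), c(8, 8, 8))
  b <- mask_from_indices(c(4, 5, 1), c(8, 8, 8))
  expect_equal(hausdorff(a, b), 5)
  expect_equal(mean_surface_distance(a, b), 5)
  expect_equal(centre_of_mass_difference(a, b), 5)
  expect_equal(hausdorff(a, a), 0)
  expect_equal(mean_surface_distance(a, a), 0)
})

test_that("volume difference is signed, relative to the reference", {
  g <- image_grid(c(10, 10, 10))
  test <- structure_mask(array(c(rep(TRUE, 500), rep(FALSE, 500)), c(10, 10, 10)), g)
  ref <- structure_mask(array(TRUE, c(10, 10, 10)), g)
  vd <- volume_difference(test, ref)
  expect_equal(vd$vd_cc, -0.5)
  expect_equal(vd$vd_rel_pct, -50)
  expect_equal(volume_difference(ref, ref), list(vd_cc = 0, vd_rel_pct = 0))
  # antisymmetry of the absolute form
  expect_equal(volume_difference(ref, test)$vd_cc, -vd$vd_cc)
  empty <- structure_mask(array(FALSE, c(10, 10, 10)), g)
  expect_true(is.na(volume_difference(test, empty)$vd_rel_pct))
  expect_equal(volume_difference(test, empty)$vd_cc, 0.5)
})

test_that("centre-of-mass difference tracks whole-voxel shifts exactly", {
  m <- mask_from_indices(as.matrix(expand.grid(2:4, 2:4, 2:3)), c(8, 8, 10),
                         spacing = c(1, 1, 2))
  shifted <- m
  shifted$voxels <- array(FALSE, dim = dim(m$voxels))
  shifted$voxels[, , 4:10] <- m$voxels[, , 1:7]   # +3 slices at sz = 2 mm
  expect_equal(centre_of_mass_difference(m, shifted), 6)
  expect_equal(centre_of_mass_difference(m, m), 0)
})

test_that("caudal cut-off truncates at the most cranial caudal end", {
  span_mask <- function(lo, hi) mask_from_indices(
    as.matrix(cbind(4, 4, lo:hi)), c(8, 8, 24))
  cut <- apply_caudal_cutoff(list(span_mask(5, 20), span_mask(7, 20),
                                  span_mask(6, 20)))
  lows <- vapply(cut, function(m) min(which(apply(m$voxels, 3, any))), numeric(1))
  expect_equal(lows, c(7, 7, 7))
  # voxels at and above the cut untouched
  expect_equal(sum(cut[[2]]$voxels), 14)

  # no-op when all share the caudal end
  same <- list(span_mask(5, 20), span_mask(5, 15))
  expect_equal(apply_caudal_cutoff(same), same)

  # idempotent
  expect_equal(apply_caudal_cutoff(cut), cut)

  empty <- structure_mask(array(FALSE, c(8, 8, 24)), image_grid(c(8, 8, 24)))
  expect_error(apply_caudal_cutoff(list(span_mask(1, 3), empty)), "empty")
})

test_that("evaluate_pair composes the per-metric conventions", {
  m <- mask_from_indices(as.matrix(expand.grid(2:4, 2:4, 2:4)), c(6, 6, 6))
  self <- evaluate_pair(m, m)
  expect_equal(self$msd_mm, 0)
  expect_equal(self$dsc, 1)
  expect_equal(self$hd_mm, 0)
  expect_equal(self$vd_cc, 0)
  expect_equal(self$vd_rel_pct, 0)
  expect_equal(self$cmd_mm, 0)

  a <- mask_from_indices(as.matrix(expand.grid(1:2, 1:2, 1:2)), c(4, 4, 4))
  b <- mask_from_indices(as.matrix(expand.grid(1:2, 1:2, 2:3)), c(4, 4, 4))
  r <- evaluate_pair(a, b)
  expect_equal(r$dsc, 0.5)
  expect_equal(r$hd_mm, bf_hausdorff(a, b))
  expect_equal(r$msd_mm, bf_msd(a, b))
  expect_equal(r$cmd_mm, 1)
  expect_equal(r$vd_cc, 0)

  empty <- structure_mask(array(FALSE, c(4, 4, 4)), image_grid(c(4, 4, 4)))
  deg <- evaluate_pair(a, empty)
  expect_true(all(is.na(deg[c("msd_mm", "dsc", "hd_mm", "cmd_mm")])))
  expect_match(deg$reason, "empty reference")
})

test_that("metrics are symmetric (VD antisymmetric) and scale with spacing", {
  set.seed(301)
  for (i in 1:5) {
    a <- random_mask(c(8, 8, 8), p = 0.25)
    b <- random_mask(c(8, 8, 8), p = 0.25)
    expect_equal(hausdorff(a, b), hausdorff(b, a))
    expect_equal(mean_surface_distance(a, b), mean_surface_distance(b, a))
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(centre_of_mass_difference(a, b), centre_of_mass_difference(b, a))
    expect_equal(volume_difference(a, b)$vd_cc, -volume_difference(b, a)$vd_cc)
    expect_lte(mean_surface_distance(a, b), hausdorff(a, b))

    k <- 2.5
    a2 <- structure_mask(a$voxels, image_grid(c(8, 8, 8), spacing = rep(k, 3)))
    b2 <- structure_mask(b$voxels, image_grid(c(8, 8, 8), spacing = rep(k, 3)))
    expect_equal(dice(a2, b2), dice(a, b))
    expect_equal(hausdorff(a2, b2), k * hausdorff(a, b))
    expect_equal(mean_surface_distance(a2, b2), k * mean_surface_distance(a, b))
    expect_equal(centre_of_mass_difference(a2, b2), k * centre_of_mass_difference(a, b))
  }
})
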