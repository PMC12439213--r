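test_that("phantom organs match their analytic volumes", {
  ph <- make_phantom(phantom_spec())
  expect_setequal(names(ph), c("brainstem", "spinal_cord", "larynx", "mandible",
                               "oral_cavity", "parotid_l", "parotid_r", "pcm",
                               "cochlea_l", "cochlea_r", "submandibular_r",
                               "thyroid"))
  # ellipsoid: 4/3 pi a b c
  expect_equal(volume_cc(ph$larynx), 4 / 3 * pi * 18 * 15 * 16 / 1000,
               tolerance = 0.1)
  # elliptic cylinder: pi a b h (spinal cord analogue, 6 mm radii, 78 mm span)
  vol_sc <- volume_cc(ph$spinal_cord)
  expect_equal(vol_sc, pi * 6 * 6 * 80 / 1000, tolerance = 0.1)
  # determinism
  ph2 <- make_phantom(phantom_spec())
  expect_identical(lapply(ph, `[[`, "voxels"), lapply(ph2, `[[`, "voxels"))
  # spinal cord analogue spans >= 10 slices
  expect_gte(sum(apply(ph$spinal_cord$voxels, 3, any)), 10)
})

test_that("cropped and full-grid phantoms are physically identical", {
  full <- make_phantom(phantom_spec())
  cropped <- make_phantom(phantom_spec(), crop = TRUE)
  for (organ in names(full)) {
    expect_equal(volume_cc(full[[organ]]), volume_cc(cropped[[organ]]))
    expect_equal(contourqa:::mask_centroid_mm(full[[organ]]),
                 contourqa:::mask_centroid_mm(cropped[[organ]]))
  }
})

test_that("organs violating the grid margin are rejected", {
  orgs <- default_organs()
  orgs[[3]]$center <- c(10, 10, 10)  # larynx pushed outside the margin
  expect_error(phantom_spec(organs = orgs), "margin")
})

test_that("zero noise, zero margin perturbation is the identity", {
  ph <- make_phantom(phantom_spec(), crop = TRUE)
  om <- observer_model("manual", radial_sd_mm = 0, systematic_margin_mm = 0,
                       caudal_jitter_slices = 0)
  out <- perturb_mask(ph$larynx, om, "o1", "p1", seed = 1)
  expect_identical(out$voxels, ph$larynx$voxels)
})

test_that("a +2 mm margin dilates a sphere by the analytic volume ratio", {
  g <- image_grid(c(40, 40, 40), spacing = c(1, 1, 1))
  org <- list(name = "s", shape = "ellipsoid", center = c(19.5, 19.5, 19.5),
              radii = c(10, 10, 10), tubular = FALSE, present = TRUE)
  gt <- contourqa:::rasterize_organ(org, g)
  om <- observer_model("ai_only", radial_sd_mm = 0, systematic_margin_mm = 2,
                       caudal_jitter_slices = 0)
  dilated <- perturb_mask(gt, om, "o", "p", seed = 1)
  expect_equal(volume_cc(dilated) / volume_cc(gt), (12 / 10)^3, tolerance = 0.1)
})

test_that("perturbations are reproducible and observer-distinct", {
  ph <- make_phantom(phantom_spec(), crop = TRUE)
  om <- observer_model("manual")
  a1 <- perturb_mask(ph$parotid_l, om, "obs1", "P01", seed = 9)
  a2 <- perturb_mask(ph$parotid_l, om, "obs1", "P01", seed = 9)
  expect_identical(a1$voxels, a2$voxels)
  b <- perturb_mask(ph$parotid_l, om, "obs2", "P01", seed = 9)
  expect_false(identical(a1$voxels, b$voxels))
  c1 <- perturb_mask(ph$parotid_l, om, "obs1", "P02", seed = 9)
  expect_false(identical(a1$voxels, c1$voxels))
})

test_that("perturbation leaves the global RNG stream untouched", {
  ph <- make_phantom(phantom_spec(), crop = TRUE)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(perturb_mask(ph$larynx, observer_model("manual"), "o", "p", seed = 2))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("the dose field follows the Gaussian falloff exactly", {
  g <- image_grid(c(20, 20, 20), spacing = c(2, 2, 2))
  center <- c(10, 12, 14)  # a voxel center
  d <- make_dose(g, center, prescription_gy = 68, falloff_mm = 25)
  expect_equal(d$dose[6, 7, 8], 68)
  # at distance = falloff the dose is prescription * exp(-1/2)
  d2 <- make_dose(image_grid(c(30, 1, 1), spacing = c(1, 1, 1)), c(4, 0, 0),
                  prescription_gy = 68, falloff_mm = 25)
  expect_equal(d2$dose[30, 1, 1], 68 * exp(-0.5), tolerance = 1e-9)
  # monotone decrease with distance along an axis
  line <- d$dose[6:20, 7, 8]
  expect_true(all(diff(line) < 0))
  expect_error(make_dose(g, center, falloff_mm = 0), "falloff")
})

test_that("timing draws honour the model medians and seeding", {
  degenerate <- timing_model(manual_sdlog = 0, adjusted_sdlog = 0,
                             processing_sdlog = 0)
  t0 <- make_timing(degenerate, 5, seed = 1)
  expect_true(all(t0$minutes[t0$group == "manual"] == 55))
  expect_true(all(t0$minutes[t0$group == "adjusted"] == 17))
  expect_true(all(t0$minutes[t0$group == "processing"] == 10))

  t1 <- make_timing(timing_model(), 200, seed = 4)
  expect_equal(median(t1$minutes[t1$group == "manual"]), 55, tolerance = 5 / 55)
  expect_equal(median(t1$minutes[t1$group == "adjusted"]), 17, tolerance = 3 / 17)
  expect_true(all(t1$minutes * 2 == floor(t1$minutes * 2)))

  expect_identical(make_timing(timing_model(), 20, seed = 7),
                   make_timing(timing_model(), 20, seed = 7))
})

test_that("cohorts have the designed contour counts and reproduce from seed", {
  st <- make_cohort(n_patients = 2, n_manual = 3, n_adjusted = 1, seed = 5)
  n_manual_masks <- sum(vapply(st$patients, function(p)
    sum(vapply(p$groups$manual, length, integer(1))), integer(1)))
  expect_equal(n_manual_masks, 2 * 3 * 12)
  expect_equal(n_manual_masks, contour_count(2, 12, 3, 0))

  st2 <- make_cohort(n_patients = 2, n_manual = 3, n_adjusted = 1, seed = 5)
  expect_identical(st, st2)

  st3 <- make_cohort(n_patients = 2, n_manual = 3, n_adjusted = 1, seed = 6)
  expect_false(identical(st, st3))
})

test_that("omitted contours are bookkept as exceptions", {
  miss <- data.frame(patient_id = "P01", oar_name = "thyroid",
                     group = "manual", observer_id = "obs01",
                     stringsAsFactors = FALSE)
  st <- make_cohort(n_patients = 2, n_manual = 2, n_adjusted = 1,
                    missing = miss, seed = 5)
  expect_null(st$patients$P01$groups$manual$obs01$thyroid)
  expect_equal(nrow(st$exceptions), 1)
  n_manual_masks <- sum(vapply(st$patients, function(p)
    sum(vapply(p$groups$manual, length, integer(1))), integer(1)))
  expect_equal(n_manual_masks, contour_count(2, 12, 2, 1))
})

test_that("patients differ anatomically but share the organ set", {
  st <- make_cohort(n_patients = 2, n_manual = 1, n_adjusted = 1, seed = 5)
  expect_setequal(names(st$patients$P01$gt), names(st$patients$P02$gt))
  expect_false(identical(
    contourqa:::mask_centroid_mm(st$patients$P01$gt$larynx),
    contourqa:::mask_centroid_mm(st$patients$P02$gt$larynx)))
})
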