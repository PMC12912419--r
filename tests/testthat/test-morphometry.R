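# Morphometry: resampling, centerline, diameter, volume, calcium, QC.

test_that("resampling is the identity at the target spacing and preserves constants", {
  ph <- small_cylinder(r = 10, L = 40)
  rs <- resample_volume(ph$volume, ph$mask, c(1.5, 1.5, 3.0))
  expect_identical(rs$volume$values, ph$volume$values)
  expect_identical(rs$mask$values, ph$mask$values)
  const <- image_volume(array(42, c(8, 8, 8)), c(1, 1, 1))
  cm <- seg_mask(array(1, c(8, 8, 8)), c(1, 1, 1))
  rs2 <- resample_volume(const, cm, c(2, 2, 2))
  expect_true(all(abs(rs2$volume$values - 42) < 1e-9))
})

test_that("downsampling a fine cylinder changes its volume by at most 2%", {
  fine <- small_cylinder(r = 12, L = 40, spacing = c(0.75, 0.75, 3))
  rs <- resample_volume(fine$volume, fine$mask, c(1.5, 1.5, 3))
  v_before <- compute_volume(fine$mask)
  v_after <- compute_volume(rs$mask)
  expect_lt(abs(v_after - v_before) / v_before, 0.02)
  expect_lt(abs(v_after - fine$truth$true_volume_ml) / fine$truth$true_volume_ml,
            0.02)
  expect_equal(rs$mask$spacing_mm, c(1.5, 1.5, 3))
})

test_that("centerline of a straight cylinder is collinear with its axis", {
  ph <- small_cylinder(r = 12, L = 80)
  cl <- extract_centerline(ph$mask)
  # the analytic axis is x = y = 0
  expect_lt(max(abs(cl$points_mm[, 1])), max(ph$mask$spacing_mm) / 2)
  expect_lt(max(abs(cl$points_mm[, 2])), max(ph$mask$spacing_mm) / 2)
  expect_true(all(abs(sqrt(rowSums(cl$tangents^2)) - 1) < 1e-6))
  # consecutive samples at the requested spacing within 10%
  steps <- sqrt(rowSums(diff(cl$points_mm)^2))
  expect_true(all(abs(steps - cl$sample_spacing_mm) <
                    0.1 * cl$sample_spacing_mm + 1e-9))
})

test_that("half-torus centerline arc length is within 5% of the analytic value", {
  ph <- generate_phantom(phantom_spec("torus_arc", lumen_radius_mm = 10,
                                      bend_radius_mm = 60))
  cl <- extract_centerline(ph$mask)
  expect_lt(abs(cl$arc_length_mm - pi * 60) / (pi * 60), 0.05)
})

test_that("centerline is equivariant under axis flips", {
  ph <- generate_phantom(phantom_spec("candy_cane", lumen_radius_mm = 10,
                                      segment_length_mm = 30,
                                      bend_radius_mm = 35))
  cl <- extract_centerline(ph$mask)
  d <- dim(ph$mask$values)
  for (axis in 1:3) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[axis]] <- d[axis]:1
    flipped <- do.call(`[`, c(list(ph$mask$values), idx))
    clf <- extract_centerline(seg_mask(flipped, ph$mask$spacing_mm,
                                       ph$mask$origin_mm))
    mirrored <- clf$points_mm
    mirrored[, axis] <- ph$mask$origin_mm[axis] +
      (d[axis] - 1) * ph$mask$spacing_mm[axis] -
      (mirrored[, axis] - ph$mask$origin_mm[axis])
    expect_lt(hausdorff_mm(cl$points_mm, mirrored),
              2 * max(ph$mask$spacing_mm))
  }
})

test_that("degenerate and pathological masks are rejected", {
  tiny <- seg_mask(array(c(rep(1, 50), rep(0, 950)), c(10, 10, 10)), c(1, 1, 1))
  expect_error(extract_centerline(tiny), "100 foreground")
  # hollow box: cavity inside the foreground
  arr <- array(0L, c(12, 12, 12))
  arr[3:10, 3:10, 3:10] <- 1L
  arr[5:8, 5:8, 5:8] <- 0L
  expect_error(extract_centerline(seg_mask(arr, c(1, 1, 1))), "cavity")
  # two components: largest kept, with a warning
  ph <- small_cylinder(r = 10, L = 50)
  arr2 <- ph$mask$values
  arr2[1:3, 1:3, 1:2] <- 1L
  expect_warning(extract_centerline(seg_mask(arr2, ph$mask$spacing_mm)),
                 "largest")
})

test_that("maximum diameter recovers cylinder and cone calibers", {
  ph <- small_cylinder(r = 18, L = 100)
  cl <- extract_centerline(ph$mask)
  dm <- measure_max_diameter(ph$mask, cl)
  expect_lt(abs(dm$max_diameter_cm - 3.6), 0.15)
  expect_equal(dm$max_diameter_cm, max(dm$diameter_profile$diameter_cm))
  # diameter is insensitive to the end trim between 5 and 20 mm
  d5 <- measure_max_diameter(ph$mask, cl, end_trim_mm = 5,
                             angular_step_deg = 3)$max_diameter_cm
  d20 <- measure_max_diameter(ph$mask, cl, end_trim_mm = 20,
                              angular_step_deg = 3)$max_diameter_cm
  expect_lt(abs(d5 - d20), 0.1)
  # tapered tube: the maximum sits at the trimmed wide end (~2 x r(L - trim))
  cone <- generate_phantom(phantom_spec("straight_cylinder",
                                        lumen_radius_mm = c(10, 20),
                                        segment_length_mm = 100))
  clc <- extract_centerline(cone$mask)
  dmc <- measure_max_diameter(cone$mask, clc)
  expect_lt(abs(dmc$max_diameter_cm - 3.8), 0.15)
})

test_that("volume is exact arithmetic on the foreground count", {
  arr <- array(0L, c(20, 20, 10))
  arr[sample(length(arr), 1000)] <- 1L
  m <- seg_mask(arr, c(1.5, 1.5, 3))
  expect_equal(compute_volume(m), 1000 * 6.75 / 1000)
  expect_error(compute_volume(seg_mask(array(0L, c(5, 5, 5)), c(1, 1, 1))),
               "empty")
})

test_that("calcium is zero on clean phantoms and matches the fine-grid oracle", {
  clean <- small_cylinder(r = 12, L = 60)
  expect_identical(quantify_calcium(clean$volume, clean$mask), 0)
  blob <- list(list(position = 0.5, radius_mm = 4, hu = 800))
  ph <- small_cylinder(r = 15, L = 60, calcifications = blob)
  ca <- quantify_calcium(ph$volume, ph$mask)
  fine <- generate_phantom(phantom_spec("straight_cylinder",
                                        lumen_radius_mm = 15,
                                        segment_length_mm = 60,
                                        calcifications = blob,
                                        voxel_spacing_mm = c(0.5, 0.5, 0.5)))
  sm <- filter_smooth_oracle(fine$volume$values, c(0.5, 0.5, 0.5), 3.0)
  oracle <- sum(sm >= 130 & fine$mask$values != 0) * 0.125
  expect_lt(abs(ca - oracle) / oracle, 0.10)
})

test_that("calcium is monotone in threshold and FWHM for a compact blob", {
  blob <- list(list(position = 0.5, radius_mm = 4, hu = 800))
  ph <- small_cylinder(r = 12, L = 60, calcifications = blob)
  thr <- c(90, 130, 300, 700)
  vals <- sapply(thr, function(t) quantify_calcium(ph$volume, ph$mask,
                                                   threshold_hu = t))
  expect_true(all(diff(vals) <= 0))
  # once the kernel is wider than the blob, more smoothing only dilutes it
  fw <- c(8, 12, 16)
  vals2 <- sapply(fw, function(f) quantify_calcium(ph$volume, ph$mask,
                                                   fwhm_mm = f))
  expect_true(all(diff(vals2) <= 0))
  expect_error(quantify_calcium(ph$volume, ph$mask, fwhm_mm = 0), "positive")
})

test_that("QC applies strict < thresholds and flags non-finite features", {
  f <- function(d, v) qc_plausibility(list(max_diameter_cm = d, volume_ml = v))
  expect_false(f(1.9, 200)$qc_pass)
  expect_equal(f(1.9, 200)$qc_reasons, "diameter_below_minimum")
  expect_false(f(3.6, 69)$qc_pass)
  expect_equal(f(3.6, 69)$qc_reasons, "volume_below_minimum")
  expect_true(f(2.0, 70)$qc_pass)   # boundary values pass (strict <)
  expect_equal(f(2.0, 70)$qc_reasons, character(0))
  expect_false(f(NaN, 100)$qc_pass)
  expect_equal(f(NaN, 100)$qc_reasons, "non_finite")
  expect_false(f(1.5, 50)$qc_pass)
  expect_length(f(1.5, 50)$qc_reasons, 2L)
})

test_that("features are equivariant under voxel translations and axis permutation", {
  blob <- list(list(position = 0.5, radius_mm = 4, hu = 800))
  ph <- small_cylinder(r = 12, L = 50, calcifications = blob)
  # whole-voxel translation: pad two background planes in front of each axis
  d <- dim(ph$mask$values)
  pad <- c(2, 2, 2)
  arr_v <- array(-950, d + pad); arr_m <- array(0L, d + pad)
  arr_v[pad[1] + 1:d[1], pad[2] + 1:d[2], pad[3] + 1:d[3]] <- ph$volume$values
  arr_m[pad[1] + 1:d[1], pad[2] + 1:d[2], pad[3] + 1:d[3]] <- ph$mask$values
  v2 <- image_volume(arr_v, ph$volume$spacing_mm)
  m2 <- seg_mask(arr_m, ph$mask$spacing_mm)
  f1 <- measure_aorta(ph$volume, ph$mask, resample = FALSE, angular_step_deg = 3)
  f2 <- measure_aorta(v2, m2, resample = FALSE, angular_step_deg = 3)
  expect_equal(f1$volume_ml, f2$volume_ml, tolerance = 1e-12)
  expect_equal(f1$calcium_mm3, f2$calcium_mm3, tolerance = 1e-12)
  expect_equal(f1$max_diameter_cm, f2$max_diameter_cm, tolerance = 1e-6)
  # 90-degree rotation: permute axes together with their spacings
  v3 <- image_volume(aperm(ph$volume$values, c(3, 2, 1)),
                     ph$volume$spacing_mm[c(3, 2, 1)])
  m3 <- seg_mask(aperm(ph$mask$values, c(3, 2, 1)),
                 ph$mask$spacing_mm[c(3, 2, 1)])
  f3 <- measure_aorta(v3, m3, resample = FALSE, angular_step_deg = 3)
  expect_equal(f3$volume_ml, f1$volume_ml, tolerance = 0.02)
  expect_lt(abs(f3$max_diameter_cm - f1$max_diameter_cm) / f1$max_diameter_cm,
            0.02)
})

test_that("NIfTI round trip preserves values and spacing", {
  ph <- small_cylinder(r = 10, L = 40, noise = 10, seed = 3)
  tf <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$volume, tf)
  back <- read_volume_nifti(tf)
  expect_equal(back$spacing_mm, ph$volume$spacing_mm, tolerance = 1e-6)
  expect_equal(back$values, ph$volume$values, tolerance = 1e-6,
               ignore_attr = TRUE)
  tfm <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$mask, tfm)
  backm <- read_volume_nifti(tfm, mask = TRUE)
  expect_equal(sum(backm$values), sum(ph$mask$values))
  unlink(c(tf, tfm))
})
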