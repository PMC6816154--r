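test_that("a rasterised disk recovers its area", {
  # dark disk (suppressed lumen) embedded in brighter tissue; 4x analytic
  # partial-volume rasterisation
  vox <- 1.3
  n <- 48L
  coords <- ((1:n) - (n + 1) / 2) * vox
  sub <- seq(-0.375, 0.375, by = 0.25) * vox
  S <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    yy <- coords[a] + sub; zz <- coords[b] + sub
    inside <- outer(yy^2, zz^2, `+`) < 15^2
    S[a, b] <- 0.3 * mean(inside) + 1.0 * (1 - mean(inside))
  }
  img <- array(rep(S, 3), c(n, n, 3))
  img <- aperm(img, c(3, 1, 2))
  secs <- extract_cross_sections(img, vox)
  s <- secs[[2]]
  expect_true(s$valid)
  expect_false(s$valid_outer)   # no outer interface in this image
  expect_equal(s$lumen_area_cm2, pi * 1.5^2, tolerance = 0.02)
})

test_that("background-only slices are flagged invalid", {
  setup <- default_phantom_setup(ilt_type = 1L)
  img <- reference_image(setup)
  img[5, , ] <- img[5, 1, 1]   # wipe one slice to uniform background
  secs <- extract_cross_sections(img, 1.3)
  expect_false(secs[[5]]$valid)
  expect_true(secs[[24]]$valid)
})

test_that("phantom measurements recover analytic truth on the reference arm", {
  for (ty in c(2L, 4L)) {
    setup <- default_phantom_setup(ilt_type = ty)
    img <- reference_image(setup)
    truth <- setup$phantom$truth
    m <- suppressWarnings(measure_volume(img, 1.3, setup$muscle))
    expect_lt(abs(m$max_diameter_cm - truth$max_outer_diameter_cm), 0.13)
    expect_lt(abs(m$lumen_area_cm2 / truth$lumen_area_cm2 - 1), 0.05)
    expect_identical(m$ilt_type, ty)
    if (ty != 4L) {
      expect_lt(abs(m$ilt_wall_area_cm2 / truth$ilt_wall_area_cm2 - 1), 0.05)
      expect_lt(abs(m$ilt_muscle_ratio / truth$ilt_muscle_ratio - 1), 0.03)
    }
  }
})

test_that("max_diameter takes the largest valid section", {
  mk <- function(slice, d, valid = TRUE) {
    structure(list(slice = slice, valid = valid, valid_outer = valid,
                   outer_diameter_cm = d, voxel_size = 1.3),
              class = "cross_section")
  }
  got <- max_diameter(list(mk(1, 3.8), mk(2, 4.2)))
  expect_equal(got$diameter_cm, 4.2)
  expect_identical(got$slice, 2)
  expect_error(max_diameter(list(mk(1, 3.8, valid = FALSE))), "no valid")
  # a single-slice detection failure does not leak into the maximum
  ds <- c(3.0, 3.2, 3.4, 3.5, 5.4, 3.5, 3.4, 3.2, 3.0)
  got2 <- max_diameter(mapply(mk, seq_along(ds), ds, SIMPLIFY = FALSE))
  expect_lt(got2$diameter_cm, 4)
})

test_that("circular outer boundary gives 2r within polygon tolerance", {
  theta <- 2 * pi * (0:63) / 64
  sec <- structure(list(slice = 1, valid = TRUE, valid_outer = TRUE,
                        theta = theta,
                        r_inner_mm = rep(10, 64), r_outer_mm = rep(20, 64),
                        center_vox = c(17.5, 17.5),
                        lumen_area_cm2 = pi, ilt_wall_area_cm2 = 2 * pi,
                        outer_diameter_cm = NA, voxel_size = 1.3),
                   class = "cross_section")
  y <- 20 * cos(theta); z <- 20 * sin(theta)
  expect_equal(max(dist(cbind(y, z))) / 10, 4, tolerance = 0.01)
  expect_equal(csaaa:::polar_area(rep(20, 64), theta) / 100, pi * 4,
               tolerance = 0.01)
})

test_that("signal ratios follow their definitions and scale invariance", {
  setup <- default_phantom_setup(ilt_type = 1L)
  img <- reference_image(setup)
  secs <- extract_cross_sections(img, 1.3)
  r <- signal_ratios(img, secs, setup$muscle)
  expect_equal(r$ilt_muscle_ratio, r$mean_ilt / r$mean_muscle)
  expect_equal(r$ilt_lumen_contrast_ratio, r$mean_ilt / r$mean_lumen)
  expect_gt(r$ilt_lumen_contrast_ratio, 1)
  r2 <- signal_ratios(7 * img, secs, setup$muscle)
  expect_equal(r2$ilt_muscle_ratio, r$ilt_muscle_ratio, tolerance = 1e-12)
  expect_error(signal_ratios(img, secs, setup$muscle & FALSE), "muscle ROI")
})

test_that("ILT typing follows the bright-fraction rule", {
  for (ty in 1:4) {
    setup <- default_phantom_setup(ilt_type = ty)
    img <- reference_image(setup)
    secs <- extract_cross_sections(img, 1.3)
    expect_identical(classify_ilt(img, secs, setup$muscle), ty)
  }
  # scaling intensities leaves the type unchanged
  setup <- default_phantom_setup(ilt_type = 2L)
  img <- reference_image(setup)
  secs <- extract_cross_sections(img, 1.3)
  expect_identical(classify_ilt(0.5 * img, secs, setup$muscle), 2L)
})

test_that("growth rate implements the endpoint formula", {
  d0 <- as.Date("2018-01-01")
  expect_equal(growth_rate(c(4, 4), c(d0, d0 + 237)), 0)
  expect_equal(growth_rate(c(4.0, 4.5), c(d0, d0 + 365.25)), 5.0,
               tolerance = 1e-10)
  # 2 mm over 237 days with a 365.25-day year
  expect_equal(growth_rate(c(4.0, 4.2), c(d0, d0 + 237)),
               2 / (237 / 365.25), tolerance = 1e-10)
  expect_equal(growth_rate(c(4.0, 4.2), c(d0, d0 + 237)), 3.082,
               tolerance = 1e-3)
  # intermediate time points are ignored by design
  expect_equal(growth_rate(c(4.0, 9.9, 4.2), c(d0, d0 + 100, d0 + 237)),
               growth_rate(c(4.0, 4.2), c(d0, d0 + 237)))
  expect_error(growth_rate(4, d0), "2 time points")
  expect_error(growth_rate(c(4, 4.2), c(d0, d0)), "strictly increasing")
})

test_that("measurements are invariant under intensity scaling", {
  setup <- default_phantom_setup(ilt_type = 2L)
  img <- reference_image(setup)
  m1 <- suppressWarnings(measure_volume(img, 1.3, setup$muscle))
  m2 <- suppressWarnings(measure_volume(img * 4.2, 1.3, setup$muscle))
  expect_equal(m1$max_diameter_cm, m2$max_diameter_cm, tolerance = 1e-9)
  expect_equal(m1$lumen_area_cm2, m2$lumen_area_cm2, tolerance = 1e-9)
  expect_equal(m1$ilt_muscle_ratio, m2$ilt_muscle_ratio, tolerance = 1e-9)
  expect_identical(m1$ilt_type, m2$ilt_type)
  expect_equal(m1$sharpness_avg, m2$sharpness_avg, tolerance = 1e-9)
})
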