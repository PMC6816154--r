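test_that("analytic truth matches simple geometries", {
  # constant lumen radius 15 mm, no ILT, wall 2 mm -> outer diameter 3.4 cm
  sp <- tiny_spec(ny = 40L, nz = 40L,
                  lumen = function(z) rep(15, length(z)),
                  ilt = function(z) rep(0, length(z)),
                  ilt_type = 4L)
  ph <- build_phantom(sp)
  expect_equal(ph$truth$max_outer_diameter_cm, 3.4, tolerance = 1e-10)
  expect_equal(ph$truth$lumen_area_cm2, pi * 1.5^2, tolerance = 1e-10)
  # type 4: no ILT-labelled voxels
  expect_identical(sum(ph$labels %in% c(2L, 3L)), 0L)

  # Gaussian bulge: apex outer diameter 2 * (12 + 8 + 6 + 2) mm = 5.6 cm;
  # shrink to fit the test grid: r(z) = 8 + 4 exp(-z^2 / (2 sigma^2)),
  # ILT 3, wall 2 -> 2 * (8 + 4 + 3 + 2) = 3.4 cm at the apex
  sp2 <- tiny_spec(nx = 16L, ny = 40L, nz = 40L,
                   lumen = function(z) 8 + 4 * exp(-z^2 / (2 * 36)),
                   ilt = function(z) 3 * exp(-z^2 / (2 * 36)) * 0 + 3,
                   ilt_type = 1L)
  ph2 <- build_phantom(sp2)
  expect_equal(ph2$truth$max_outer_diameter_cm, 3.4, tolerance = 1e-6)
  expect_equal(ph2$truth$slice_of_max, 8L)  # apex at the volume centre
  expect_equal(ph2$truth$ilt_muscle_ratio, 1.5)  # all-bright ILT vs muscle 1.0
})

test_that("labels partition the grid and the raster agrees with truth", {
  ph <- build_phantom(tiny_spec(ilt_type = 2L))
  expect_true(all(ph$labels %in% 0:6))
  # raster-measured outer diameter within one voxel of analytic truth
  outer_lab <- matrix(ph$labels[4, , ] %in% 1:4, dim(ph$labels)[2])
  ys <- which(rowSums(outer_lab) > 0)
  d_raster <- (max(ys) - min(ys) + 1) * ph$voxel_size / 10
  expect_lt(abs(d_raster - ph$truth$max_outer_diameter_cm), ph$voxel_size / 10)
  # type 2 assigns both bright and iso ILT
  expect_gt(sum(ph$labels == 2L), 0)
  expect_gt(sum(ph$labels == 3L), 0)
})

test_that("phantoms are bit-identical under a fixed seed", {
  a <- build_phantom(tiny_spec(ilt_type = 2L, seed = 42L))
  b <- build_phantom(tiny_spec(ilt_type = 2L, seed = 42L))
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$labels, b$labels)
})

test_that("geometry exceeding the grid names the offending slice", {
  sp <- tiny_spec(ny = 24L, nz = 24L)   # half extent 15.6 mm < 14 + 3.9
  expect_error(build_phantom(sp), "slice 1")
})

test_that("type-4 consistency is enforced", {
  expect_error(build_phantom(tiny_spec(ilt_type = 4L)), "zero ILT")
  sp <- tiny_spec(ilt = function(z) rep(0, length(z)), ilt_type = 4L)
  expect_true(is.na(build_phantom(sp)$truth$ilt_muscle_ratio))
})

test_that("coil maps are RSS-normalised, smooth, seeded", {
  expect_error(coil_sensitivities(c(4, 8, 8), 0), "n_coils")
  m1 <- coil_sensitivities(c(4, 16, 16), 1, seed = 9)
  expect_lt(max(Mod(m1$maps - 1)), 1e-12)
  m4 <- coil_sensitivities(c(4, 16, 16), 4, seed = 9)
  rss <- sqrt(apply(Mod(m4$maps)^2, 1:3, sum))
  expect_lt(max(abs(rss - 1)), 1e-6)
  m4b <- coil_sensitivities(c(4, 16, 16), 4, seed = 9)
  expect_identical(m4$maps, m4b$maps)
  # smoothness: neighbouring-voxel increments are small
  d <- Mod(m4$maps[, -1, , ] - m4$maps[, -16, , ])
  expect_lt(max(d), 0.15)
})

test_that("noiseless full-mask acquisition inverts to the phantom", {
  ph <- build_phantom(tiny_spec())
  maps <- coil_sensitivities(dim(ph$intensity), 1, seed = 2)
  fm <- full_mask(36, 36)
  acq <- simulate_acquisition(ph, maps, fm, noise_sd = 0, seed = 1)
  rec <- Mod(ifftc(acq$data[, , , 1]))
  expect_lt(max(abs(rec - ph$intensity)) / max(ph$intensity), 1e-6)
})

test_that("unsampled k-space entries are exactly zero", {
  ph <- build_phantom(tiny_spec())
  maps <- coil_sensitivities(dim(ph$intensity), 2, seed = 2)
  mask <- poisson_disc_mask(36, 36, 3, seed = 5)
  acq <- simulate_acquisition(ph, maps, mask, noise_sd = 0.05, seed = 1)
  m3 <- csaaa:::broadcast_mask(mask$grid, dim(ph$intensity)[1])
  expect_true(all(acq$data[!m3] == 0i))
  expect_error(simulate_acquisition(ph, maps, poisson_disc_mask(24, 24, 2, seed = 1)),
               "mask shape")
})

test_that("acquisition satisfies Parseval against a brute-force DFT", {
  set.seed(8)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  # single uniform coil so the acquisition is the plain transform
  maps <- structure(list(maps = array(1 + 0i, c(8, 8, 4, 1)),
                         support = array(TRUE, c(8, 8, 4))),
                    class = "sense_maps")
  fm <- full_mask(8, 4)
  acq <- simulate_acquisition(x, maps, fm, noise_sd = 0, seed = 1)
  # k-space energy equals image energy (unitary transform)
  expect_equal(sum(Mod(acq$data)^2), sum(x^2), tolerance = 1e-10)
  # and the k-space itself matches the explicit summation oracle
  brute <- dft3_brute(x)
  expect_lt(max(Mod(acq$data[, , , 1] - brute)), 1e-8)
})

test_that("added complex noise is calibrated", {
  x <- array(0, c(8, 48, 48))
  maps <- structure(list(maps = array(1 + 0i, c(8, 48, 48, 1)),
                         support = array(TRUE, c(8, 48, 48))),
                    class = "sense_maps")
  acq <- simulate_acquisition(x, maps, full_mask(48, 48), noise_sd = 0.05,
                              seed = 3)
  draws <- c(Re(acq$data), Im(acq$data))
  expect_equal(sd(draws), 0.05, tolerance = 0.05)  # relative 5%
})
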