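# small complex test instance builders ---------------------------------------

rand_acq <- function(nx = 8L, ny = 8L, nz = 4L, n_coils = 1L, accel = 1,
                     seed = 1L) {
  set.seed(seed)
  x <- array(complex(real = rnorm(nx * ny * nz),
                     imaginary = rnorm(nx * ny * nz)), c(nx, ny, nz))
  maps_arr <- array(0i, c(nx, ny, nz, n_coils))
  if (n_coils == 1L) {
    maps_arr[, , , 1] <- 1 + 0i
  } else {
    raw <- array(complex(real = rnorm(nx * ny * nz * n_coils),
                         imaginary = rnorm(nx * ny * nz * n_coils)),
                 c(nx, ny, nz, n_coils))
    rss <- sqrt(apply(Mod(raw)^2, 1:3, sum))
    maps_arr <- raw / array(rep(rss, n_coils), dim(raw))
  }
  maps <- structure(list(maps = maps_arr, support = array(TRUE, c(nx, ny, nz))),
                    class = "sense_maps")
  mask <- if (accel == 1) {
    full_mask(ny, nz)
  } else {
    # hand-built random mask: operator tests need a projection, not the
    # Poisson-disc structure (tiny grids cannot calibrate a fraction)
    grid <- matrix(runif(ny * nz) < 1 / accel, ny, nz)
    grid[ny %/% 2 + 0:1, nz %/% 2 + 0:1] <- TRUE
    calib <- matrix(FALSE, ny, nz)
    calib[ny %/% 2 + 0:1, nz %/% 2 + 0:1] <- TRUE
    csaaa:::new_sampling_mask(grid, calib, matrix(TRUE, ny, nz),
                              accel, calib_fraction = 4 / (ny * nz),
                              density_decay = 0, r0 = NA_real_, tol = 0.5,
                              seed = seed)
  }
  m3 <- csaaa:::broadcast_mask(mask$grid, nx)
  data <- array(0i, c(nx, ny, nz, n_coils))
  for (ci in seq_len(n_coils)) {
    cm <- maps_arr[, , , ci]
    dim(cm) <- c(nx, ny, nz)
    k <- csaaa:::fftc(cm * x)
    k[!m3] <- 0i
    data[, , , ci] <- k
  }
  acq <- structure(list(data = data, mask = mask, n_coils = n_coils,
                        noise_sd = 0), class = "kspace_acquisition")
  list(x = x, maps = maps, acq = acq, m3 = m3)
}

test_that("objective matches a brute-force term-by-term summation", {
  # 4 x 4 single-coil instance (one readout sample so the plane is 4 x 4)
  set.seed(2)
  inst <- rand_acq(1L, 4L, 4L, 1L, accel = 1, seed = 2)
  x_try <- array(complex(real = rnorm(16), imaginary = rnorm(16)), c(1, 4, 4))
  lambda <- 0.17
  got <- objective(x_try, inst$acq, inst$maps, lambda, wavelet_levels = 3L)

  # oracle written without the operator abstractions: explicit DFT sums
  brute_k <- array(0i, c(1, 4, 4))
  for (k2 in 1:4) for (k3 in 1:4) {
    s <- 0i
    for (n2 in 1:4) for (n3 in 1:4) {
      s <- s + x_try[1, n2, n3] *
        exp(-2i * pi * ((k2 - 3) * (n2 - 1) / 4 + (k3 - 3) * (n3 - 1) / 4))
    }
    brute_k[1, k2, k3] <- s / 4
  }
  fid <- 0.5 * sum(Mod(as.vector(brute_k) - as.vector(inst$acq$data[, , , 1]))^2)
  # l1 of the orthogonal wavelet coefficients via the cached matrix applied
  # by explicit row sums
  W4 <- csaaa:::wavelet_matrix(4L, 3L)
  co <- matrix(0i, 4, 4)
  xm <- matrix(x_try[1, , ], 4, 4)
  for (a in 1:4) for (b in 1:4) {
    s <- 0i
    for (p in 1:4) for (q in 1:4) s <- s + W4[a, p] * W4[b, q] * xm[p, q]
    co[a, b] <- s
  }
  spars <- sum(Mod(co))
  expect_equal(got$fidelity, fid, tolerance = 1e-12)
  expect_equal(got$sparsity, spars, tolerance = 1e-12)
  expect_equal(got$total, fid + lambda * spars, tolerance = 1e-12)
})

test_that("objective limits: ground truth gives zero, x = 0 gives data energy", {
  inst <- rand_acq(4L, 8L, 8L, 2L, accel = 1, seed = 5)
  f <- objective(inst$x, inst$acq, inst$maps, lambda = 0)
  expect_lt(f$total / sum(Mod(inst$acq$data)^2), 1e-10)
  f0 <- objective(array(0i, dim(inst$x)), inst$acq, inst$maps, lambda = 0.3)
  expect_equal(f0$fidelity, 0.5 * sum(Mod(inst$acq$data)^2), tolerance = 1e-12)
  expect_equal(f0$sparsity, 0)
})

test_that("forward and adjoint operators pass the inner-product test", {
  for (seed in 1:3) {
    inst <- rand_acq(8L, 8L, 4L, 3L, accel = 2, seed = seed)
    set.seed(seed + 100)
    d <- dim(inst$acq$data)
    y <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
    Ax <- csaaa:::forward_op(inst$x, inst$maps$maps, inst$m3)
    Aty <- csaaa:::adjoint_op(y, inst$maps$maps, inst$m3)
    lhs <- sum(Ax * Conj(y))
    rhs <- sum(inst$x * Conj(Aty))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
  }
})

test_that("sensitivity estimation recovers smooth maps", {
  # single uniform coil, noiseless: estimated map is 1 on support
  n <- c(8L, 32L, 32L)
  blob <- array(0, n)
  y <- csaaa:::axis_mm(n[2], 2 / n[2]); z <- csaaa:::axis_mm(n[3], 2 / n[3])
  b2 <- exp(-outer(y^2, z^2, `+`) / 0.5)
  for (i in seq_len(n[1])) blob[i, , ] <- b2
  maps1 <- structure(list(maps = array(1 + 0i, c(n, 1)), support = array(TRUE, n)),
                     class = "sense_maps")
  acq <- simulate_acquisition(blob, maps1, full_mask(n[2], n[3]), 0, seed = 1)
  est <- estimate_sensitivities(acq)
  expect_lt(max(Mod(est$maps[, , , 1][est$support] - 1)), 1e-3)
  rss <- sqrt(apply(Mod(est$maps)^2, 1:3, sum))
  expect_lt(max(rss), 1 + 1e-6)

  # four smooth coils on a smooth object: per-voxel error < 0.05 on the
  # supported interior (band-limited calibration cannot represent the
  # non-periodic coil field across the wrap boundary; the contaminated rind
  # spans the calibration kernel width, ~8 voxels, and imaged anatomy never
  # sits there)
  n2 <- c(8L, 64L, 64L)
  blob2 <- array(0, n2)
  y2 <- csaaa:::axis_mm(n2[2], 2 / n2[2]); z2 <- csaaa:::axis_mm(n2[3], 2 / n2[3])
  p2 <- 0.2 + exp(-outer(y2^2, z2^2, `+`) / 0.8)
  for (i in seq_len(n2[1])) blob2[i, , ] <- p2
  maps4 <- coil_sensitivities(n2, 4L, seed = 3)
  acq4 <- simulate_acquisition(blob2, maps4, full_mask(n2[2], n2[3]), 0, seed = 1)
  est4 <- estimate_sensitivities(acq4)
  err <- Mod(est4$maps - maps4$maps)
  interior <- est4$support
  interior[, c(1:8, 57:64), ] <- FALSE
  interior[, , c(1:8, 57:64)] <- FALSE
  expect_lt(max(err[rep(interior, 4)]), 0.05)

  bad <- acq
  bad$mask$calib[] <- FALSE
  expect_error(estimate_sensitivities(bad), "calibration region")
})

test_that("fully sampled, lambda = 0: reconstruction equals the inverse transform", {
  inst <- rand_acq(4L, 16L, 16L, 1L, accel = 1, seed = 7)
  rec <- reconstruct_cs(inst$acq, inst$maps,
                        recon_config(lambda = 0, iterations = 5))
  direct <- csaaa:::ifftc(inst$acq$data[, , , 1])
  expect_lt(max(Mod(rec$image - direct)) / max(Mod(direct)), 1e-6)
  # fixed point: the zero-filled solution is already optimal
  expect_equal(rec$cost_trace$total[1], rec$cost_trace$total[6], tolerance = 1e-8)
})

test_that("cost trace is recorded, consistent and non-increasing", {
  ph <- build_phantom(tiny_spec(ilt_type = 2L))
  maps <- coil_sensitivities(dim(ph$intensity), 3L, seed = 2)
  mask <- poisson_disc_mask(36, 36, 3, seed = 4)
  acq <- simulate_acquisition(ph, maps, mask, noise_sd = 0.03, seed = 6)
  cfg <- recon_config(lambda = 0.002, iterations = 8)
  rec <- reconstruct_cs(acq, estimate_sensitivities(acq), cfg)
  tr <- rec$cost_trace
  expect_identical(nrow(tr), 9L)  # iterations + initial point
  expect_true(all(diff(tr$total) <= 1e-10))
  expect_lt(max(abs(tr$total - (tr$fidelity + cfg$lambda * tr$sparsity))) /
              max(tr$total), 1e-8)
  expect_error(reconstruct_cs(structure(list(data = acq$data * NaN,
                                             mask = acq$mask,
                                             n_coils = acq$n_coils),
                                        class = "kspace_acquisition"),
                              estimate_sensitivities(acq), cfg),
               "non-finite")
})

test_that("undersampled CS beats zero-filling on the small phantom", {
  wins <- 0L
  for (s in 1:3) {
    ph <- build_phantom(tiny_spec(ilt_type = 2L, seed = s))
    maps <- coil_sensitivities(dim(ph$intensity), 3L, seed = s + 10)
    mask <- poisson_disc_mask(36, 36, 3, seed = s + 20)
    acq <- simulate_acquisition(ph, maps, mask, noise_sd = 0.03, seed = s + 30)
    est <- estimate_sensitivities(acq)
    rec <- reconstruct_cs(acq, est, recon_config(lambda = 0.002, iterations = 10))
    m3 <- csaaa:::broadcast_mask(mask$grid, dim(ph$intensity)[1])
    zf <- Mod(csaaa:::adjoint_op(acq$data, est$maps, m3))
    if (nrmse(Mod(rec$image), ph$intensity) < nrmse(zf, ph$intensity)) {
      wins <- wins + 1L
    }
  }
  expect_identical(wins, 3L)
})

test_that("reference reconstruction unmixes coils exactly", {
  inst <- rand_acq(4L, 16L, 16L, 1L, accel = 1, seed = 3)
  ref <- reconstruct_reference(inst$acq, inst$maps)
  expect_lt(max(abs(ref - Mod(inst$x))) / max(Mod(inst$x)), 1e-6)
  inst4 <- rand_acq(4L, 16L, 16L, 4L, accel = 1, seed = 3)
  ref4 <- reconstruct_reference(inst4$acq, inst4$maps)
  # with true maps the coil combination inverts the weighting on support
  expect_lt(max(abs(ref4 - Mod(inst4$x))) / max(Mod(inst4$x)), 1e-6)
  under <- rand_acq(4L, 16L, 16L, 1L, accel = 2, seed = 3)
  expect_error(reconstruct_reference(under$acq, under$maps), "fully sampled")
})

test_that("reference background noise scales with Parseval", {
  # noiseless signal 0; per-component k-space noise sd maps through the
  # unitary transform to image noise of the same sd (Monte-Carlo, 20 seeds)
  n <- c(4L, 24L, 24L)
  maps <- structure(list(maps = array(1 + 0i, c(n, 1)), support = array(TRUE, n)),
                    class = "sense_maps")
  sds <- vapply(1:20, function(s) {
    acq <- simulate_acquisition(array(0, n), maps, full_mask(n[2], n[3]),
                                noise_sd = 0.04, seed = s)
    im <- csaaa:::ifftc(acq$data[, , , 1])
    sd(c(Re(im), Im(im)))
  }, numeric(1))
  expect_equal(mean(sds), 0.04, tolerance = 0.1)
})

test_that("lambda -> 0 at full sampling approaches least squares monotonically", {
  inst <- rand_acq(4L, 16L, 16L, 1L, accel = 1, seed = 9)
  truth <- Mod(inst$x)
  errs <- vapply(c(0, 0.01, 0.05), function(lam) {
    rec <- reconstruct_cs(inst$acq, inst$maps,
                          recon_config(lambda = lam, iterations = 6))
    nrmse(Mod(rec$image), truth)
  }, numeric(1))
  expect_true(all(diff(errs) >= -1e-10))
})

test_that("parameter sweep evaluates the full grid with snapshots", {
  ph <- build_phantom(tiny_spec(ilt_type = 3L))
  maps <- coil_sensitivities(dim(ph$intensity), 2L, seed = 2)
  mask <- poisson_disc_mask(36, 36, 3, seed = 4)
  acq <- simulate_acquisition(ph, maps, mask, noise_sd = 0.02, seed = 6)
  tab <- sweep_recon_params(acq, estimate_sensitivities(acq), ph$intensity,
                            lambdas = c(0.001, 0.002),
                            iteration_counts = c(2L, 5L))
  expect_identical(nrow(tab), 4L)
  expect_identical(sort(unique(tab$iterations)), c(2L, 5L))
  expect_true(all(is.finite(tab$nrmse)))
})

test_that("reconstruction is deterministic given fixed inputs", {
  inst <- rand_acq(4L, 16L, 16L, 2L, accel = 2, seed = 12)
  r1 <- reconstruct_cs(inst$acq, inst$maps, recon_config(iterations = 4))
  r2 <- reconstruct_cs(inst$acq, inst$maps, recon_config(iterations = 4))
  expect_identical(r1$image, r2$image)
  expect_identical(r1$cost_trace, r2$cost_trace)
})
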