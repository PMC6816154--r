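# Small fixtures shared across tests; everything is generated in code.

# compact phantom that fits a 36 x 36 in-plane grid (half extent 23.4 mm)
tiny_spec <- function(nx = 8L, ny = 36L, nz = 36L,
                      lumen = function(z) rep(9, length(z)),
                      ilt = function(z) rep(3, length(z)),
                      wall = 2, ilt_type = 1L, noise_sd = 0, seed = 1L,
                      supersample = 2L, ...) {
  phantom_spec(grid_shape = c(nx, ny, nz),
               lumen_radius_profile = lumen,
               ilt_thickness_profile = ilt,
               wall_thickness = wall, ilt_type = ilt_type,
               noise_sd = noise_sd, seed = seed, supersample = supersample,
               muscle_center_mm = c(14, 14), muscle_radius_mm = 4,
               spine_center_mm = c(0, -17), spine_radius_mm = 3, ...)
}

# default-geometry phantom + both-arm reconstructions (noiseless unless set)
default_phantom_setup <- function(ilt_type = 2L, outer_diameter_cm = 4.85,
                                  noise_sd = 0, seed = 5L) {
  seeds <- csaaa:::derive_seeds(seed, 4L)
  spec <- aaa_phantom_spec(outer_diameter_cm = outer_diameter_cm,
                           ilt_type = ilt_type, noise_sd = noise_sd,
                           seed = seeds[1])
  ph <- build_phantom(spec)
  maps <- coil_sensitivities(dim(ph$intensity), 4L, seed = seeds[2])
  list(phantom = ph, maps = maps, seeds = seeds,
       muscle = csaaa:::erode_mask(ph$labels == 5L))
}

reference_image <- function(setup, noise_sd = 0) {
  fm <- full_mask(dim(setup$phantom$intensity)[2], dim(setup$phantom$intensity)[3])
  acq <- simulate_acquisition(setup$phantom, setup$maps, fm,
                              noise_sd = noise_sd, seed = setup$seeds[3])
  reconstruct_reference(acq, estimate_sensitivities(acq))
}

# brute-force centred unitary DFT of a 3D array by explicit summation
dft3_brute <- function(x) {
  d <- dim(x)
  out <- array(0i, d)
  cen <- d %/% 2 + 1
  for (k1 in seq_len(d[1])) for (k2 in seq_len(d[2])) for (k3 in seq_len(d[3])) {
    f1 <- k1 - cen[1]; f2 <- k2 - cen[2]; f3 <- k3 - cen[3]
    ph <- 0
    s <- 0i
    for (n1 in seq_len(d[1])) for (n2 in seq_len(d[2])) for (n3 in seq_len(d[3])) {
      ph <- -2 * pi * (f1 * (n1 - 1) / d[1] + f2 * (n2 - 1) / d[2] +
                         f3 * (n3 - 1) / d[3])
      s <- s + x[n1, n2, n3] * exp(1i * ph)
    }
    out[k1, k2, k3] <- s / sqrt(prod(d))
  }
  out
}
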