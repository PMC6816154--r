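# Digital AAA phantoms: a straight, axially aligned abdominal aorta with a
# fusiform aneurysm bulge, an intraluminal thrombus (ILT) layer of one of
# four signal types, a thin wall, a psoas-muscle reference disc and a spine
# disc, all rasterised on an isotropic grid. Geometry is analytic (radius
# profiles as functions of axial position), so every phantom carries an
# exact truth record that measurements can be checked against.
#
# Tissue classes and default intensities (arbitrary units): background 0.2,
# lumen 0.3 (flow-suppressed blood), iso-intense ILT 1.0, bright ILT 1.5,
# wall 0.9, muscle 1.0, spine 1.1. The bright/iso split realises the 1.2
# ILT-to-muscle threshold used for thrombus typing.

.tissue_levels <- c(background = 0L, lumen = 1L, ilt_iso = 2L,
                    ilt_bright = 3L, wall = 4L, muscle = 5L, spine = 6L)

.default_intensities <- c(background = 0.2, lumen = 0.3, ilt_iso = 1.0,
                          ilt_bright = 1.5, wall = 0.9, muscle = 1.0,
                          spine = 1.1)

#' Phantom specification
#'
#' Full parametrisation of a digital AAA phantom. Most users will prefer
#' [aaa_phantom_spec()], which builds the radius profiles of a fusiform
#' aneurysm from a target outer diameter.
#'
#' @param grid_shape integer vector `(nx, ny, nz)`; the vessel axis runs
#'   along the first (readout) dimension, cross-sections live in the
#'   (ny, nz) phase-encode plane.
#' @param voxel_size isotropic voxel size in mm (default 1.3).
#' @param lumen_radius_profile function of axial position (mm, centred on
#'   the volume) returning the lumen radius in mm; must be positive.
#' @param ilt_thickness_profile function of axial position returning the ILT
#'   thickness in mm (identically 0 for `ilt_type = 4`).
#' @param wall_thickness wall thickness in mm (> 0).
#' @param ilt_type thrombus signal type: 1 all bright, 2 mixed
#'   bright/iso-intense (a contiguous angular sector of size
#'   `bright_fraction` is bright), 3 all iso-intense, 4 no ILT.
#' @param tissue_intensities named numeric vector of mean signals for
#'   `background, lumen, ilt_iso, ilt_bright, wall, muscle, spine`.
#' @param bright_fraction fraction of ILT voxels assigned the bright
#'   intensity for type 2 (default 0.5).
#' @param noise_sd per-component standard deviation of the complex k-space
#'   noise added by [simulate_acquisition()].
#' @param seed integer seed (fixes the type-2 bright-sector orientation and
#'   downstream noise draws).
#' @param supersample rasterisation supersampling factor; intensities are
#'   averaged over `supersample^3` subvoxels (partial-volume effect), labels
#'   are assigned by voxel-centre membership.
#' @param muscle_center_mm,muscle_radius_mm,spine_center_mm,spine_radius_mm
#'   in-plane placement (mm offsets from the vessel axis) and radii of the
#'   psoas-muscle and spine discs.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(48L, 64L, 64L), voxel_size = 1.3,
                         lumen_radius_profile, ilt_thickness_profile,
                         wall_thickness = 2, ilt_type = 1L,
                         tissue_intensities = .default_intensities,
                         bright_fraction = 0.5, noise_sd = 0.03, seed = 1L,
                         supersample = 2L,
                         muscle_center_mm = c(24.7, 24.7),
                         muscle_radius_mm = 6,
                         spine_center_mm = c(0, -35),
                         spine_radius_mm = 5) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            voxel_size > 0, wall_thickness > 0,
            ilt_type %in% 1:4, bright_fraction >= 0, bright_fraction <= 1,
            noise_sd >= 0, supersample >= 1)
  need <- names(.tissue_levels)
  if (!all(need %in% names(tissue_intensities))) {
    stop("tissue_intensities must name: ", paste(need, collapse = ", "))
  }
  if (any(tissue_intensities < 0)) stop("tissue intensities must be >= 0")
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
    lumen_radius_profile = lumen_radius_profile,
    ilt_thickness_profile = ilt_thickness_profile,
    wall_thickness = wall_thickness, ilt_type = as.integer(ilt_type),
    tissue_intensities = tissue_intensities[need],
    bright_fraction = bright_fraction, noise_sd = noise_sd,
    seed = as.integer(seed), supersample = as.integer(supersample),
    muscle_center_mm = muscle_center_mm, muscle_radius_mm = muscle_radius_mm,
    spine_center_mm = spine_center_mm, spine_radius_mm = spine_radius_mm
  ), class = "phantom_spec")
}

#' Fusiform-aneurysm phantom specification
#'
#' Convenience constructor: a straight aorta whose outer radius follows a
#' Gaussian bulge, `r_out(z) = r_neck + (D/2 - r_neck) * exp(-z^2 / (2
#' sigma^2))`, with a constant wall and an ILT layer concentrated at the
#' bulge. The maximal outer diameter is therefore exactly
#' `outer_diameter_cm` at the bulge apex.
#'
#' @param outer_diameter_cm maximal outer diameter in cm (surveillance range
#'   roughly 3-5.5; default 4.85, a typical study mean).
#' @param ilt_type thrombus type 1-4; type 4 forces zero ILT thickness.
#' @param ilt_apex_mm ILT thickness at the bulge apex in mm (default 8).
#' @param neck_outer_radius_mm outer radius of the non-aneurysmal neck (mm).
#' @param bulge_sigma_mm axial standard deviation of the Gaussian bulge (mm).
#' @param wall_thickness wall thickness in mm.
#' @param ... further arguments passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
aaa_phantom_spec <- function(outer_diameter_cm = 4.85, ilt_type = 1L,
                             ilt_apex_mm = 8, neck_outer_radius_mm = 12,
                             bulge_sigma_mm = 12, wall_thickness = 2, ...) {
  r_apex <- outer_diameter_cm * 10 / 2
  if (r_apex <= neck_outer_radius_mm) neck_outer_radius_mm <- 0.8 * r_apex
  if (ilt_type == 4L) ilt_apex_mm <- 0
  bulge <- function(z) exp(-z^2 / (2 * bulge_sigma_mm^2))
  r_out <- function(z) neck_outer_radius_mm + (r_apex - neck_outer_radius_mm) * bulge(z)
  ilt <- function(z) ilt_apex_mm * bulge(z)
  lumen <- function(z) r_out(z) - wall_thickness - ilt(z)
  phantom_spec(lumen_radius_profile = lumen, ilt_thickness_profile = ilt,
               wall_thickness = wall_thickness, ilt_type = ilt_type, ...)
}

# centred mm coordinates of voxel centres along an axis
axis_mm <- function(n, voxel) (seq_len(n) - (n + 1) / 2) * voxel

# label one cross-sectional plane given scalar radii (vectorised over the
# precomputed in-plane distance maps)
label_plane <- function(geom, r_lumen, r_ilt_outer, r_outer, bright_sector) {
  lab <- matrix(.tissue_levels[["background"]], nrow(geom$R), ncol(geom$R))
  lab[geom$Rm < geom$muscle_r] <- .tissue_levels[["muscle"]]
  lab[geom$Rs < geom$spine_r] <- .tissue_levels[["spine"]]
  lab[geom$R < r_outer] <- .tissue_levels[["wall"]]
  in_ilt <- geom$R < r_ilt_outer
  if (any(in_ilt)) {
    bright <- switch(as.character(geom$ilt_type),
      "1" = in_ilt,
      "2" = in_ilt & bright_sector,
      in_ilt & FALSE)
    lab[in_ilt] <- .tissue_levels[["ilt_iso"]]
    lab[bright] <- .tissue_levels[["ilt_bright"]]
  }
  lab[geom$R < r_lumen] <- .tissue_levels[["lumen"]]
  lab
}

rasterize_labels <- function(spec, y_mm, z_mm, x_mm, theta0) {
  geom <- list(
    R = sqrt(outer(y_mm^2, z_mm^2, `+`)),
    Rm = sqrt(outer((y_mm - spec$muscle_center_mm[1])^2,
                    (z_mm - spec$muscle_center_mm[2])^2, `+`)),
    Rs = sqrt(outer((y_mm - spec$spine_center_mm[1])^2,
                    (z_mm - spec$spine_center_mm[2])^2, `+`)),
    muscle_r = spec$muscle_radius_mm, spine_r = spec$spine_radius_mm,
    ilt_type = spec$ilt_type
  )
  theta <- atan2(rep(z_mm, each = length(y_mm)),
                 rep(y_mm, times = length(z_mm)))
  dim(theta) <- c(length(y_mm), length(z_mm))
  bright_sector <- ((theta - theta0) %% (2 * pi)) < 2 * pi * spec$bright_fraction

  r_l <- spec$lumen_radius_profile(x_mm)
  r_i <- r_l + spec$ilt_thickness_profile(x_mm)
  r_o <- r_i + spec$wall_thickness
  lab <- array(0L, c(length(x_mm), length(y_mm), length(z_mm)))
  for (i in seq_along(x_mm)) {
    lab[i, , ] <- label_plane(geom, r_l[i], r_i[i], r_o[i], bright_sector)
  }
  lab
}

#' Build a digital phantom
#'
#' Rasterises a [phantom_spec()] into an intensity volume (with optional
#' supersampled partial-volume averaging) and a label volume (voxel-centre
#' membership), and fills the analytic truth record: maximal outer diameter
#' and its slice, lumen and ILT+wall areas at that slice, the ILT-to-muscle
#' intensity ratio of the construction, and the thrombus type. The truth is
#' computed from the radius profiles, not by re-measuring the raster.
#'
#' @param spec a `phantom_spec`.
#' @return A `digital_phantom`: `intensity` and `labels` arrays
#'   `(nx, ny, nz)`, `truth` list, `voxel_size`, and the `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_shape; vox <- spec$voxel_size
  x_mm <- axis_mm(n[1], vox)
  y_mm <- axis_mm(n[2], vox)
  z_mm <- axis_mm(n[3], vox)

  # analytic truth on a fine axial grid spanning the volume
  zf <- seq(min(x_mm) - vox / 2, max(x_mm) + vox / 2, length.out = 2001L)
  r_l <- spec$lumen_radius_profile(zf)
  r_i <- r_l + spec$ilt_thickness_profile(zf)
  r_o <- r_i + spec$wall_thickness
  if (any(r_l <= 0)) stop("lumen radius profile must be positive everywhere")
  if (spec$ilt_type == 4L && any(spec$ilt_thickness_profile(zf) > 1e-9)) {
    stop("ilt_type = 4 requires a zero ILT thickness profile")
  }
  half_extent <- min((n[2] / 2) * vox, (n[3] / 2) * vox)
  r_slice <- spec$lumen_radius_profile(x_mm) +
    spec$ilt_thickness_profile(x_mm) + spec$wall_thickness
  bad <- which(r_slice + 3 * vox > half_extent)
  if (length(bad)) {
    stop(sprintf(
      "phantom geometry exceeds the grid at axial slice %d (outer radius %.1f mm, half extent %.1f mm, margin 3 voxels)",
      bad[1], r_slice[bad[1]], half_extent))
  }

  i_max <- which.max(r_o)
  z_star <- zf[i_max]
  truth <- list(
    max_outer_diameter_cm = 2 * r_o[i_max] / 10,
    slice_of_max = which.min(abs(x_mm - z_star)),
    lumen_area_cm2 = pi * r_l[i_max]^2 / 100,
    ilt_wall_area_cm2 = pi * (r_o[i_max]^2 - r_l[i_max]^2) / 100,
    ilt_muscle_ratio = NA_real_,
    ilt_type = spec$ilt_type
  )

  set.seed(spec$seed)
  theta0 <- runif(1, 0, 2 * pi)

  # labels at voxel centres
  labels <- rasterize_labels(spec, y_mm, z_mm, x_mm, theta0)

  # intensities with supersampled partial-volume averaging
  s <- spec$supersample
  ti <- spec$tissue_intensities
  lut <- ti[match(names(.tissue_levels), names(ti))]
  if (s == 1L) {
    intensity <- array(lut[labels + 1L], dim = n)
    fine_max <- labels[truth$slice_of_max, , ]
  } else {
    offs <- ((seq_len(s) - (s + 1) / 2) / s) * vox
    fx <- as.vector(outer(offs, x_mm, `+`))
    fy <- as.vector(outer(offs, y_mm, `+`))
    fz <- as.vector(outer(offs, z_mm, `+`))
    flab <- rasterize_labels(spec, fy, fz, fx, theta0)
    fint <- array(lut[flab + 1L], dim = dim(flab))
    dim(fint) <- c(s, n[1], s, n[2], s, n[3])
    fint <- aperm(fint, c(1, 3, 5, 2, 4, 6))
    dim(fint) <- c(s^3, prod(n))
    intensity <- array(colMeans(fint), dim = n)
    fsl <- (truth$slice_of_max - 1L) * s + seq_len(s)
    fine_max <- flab[fsl, , ]
  }

  ilt_sel <- fine_max == .tissue_levels[["ilt_iso"]] |
    fine_max == .tissue_levels[["ilt_bright"]]
  if (any(ilt_sel)) {
    mean_ilt <- mean(lut[fine_max[ilt_sel] + 1L])
    truth$ilt_muscle_ratio <- mean_ilt / ti[["muscle"]]
  }

  structure(list(intensity = intensity, labels = labels, truth = truth,
                 voxel_size = vox, spec = spec),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf(
    "<digital_phantom> %s voxels @ %.2f mm; max outer diameter %.2f cm (slice %d); ILT type %d\n",
    paste(dim(x$intensity), collapse = " x "), x$voxel_size,
    x$truth$max_outer_diameter_cm, x$truth$slice_of_max, x$truth$ilt_type))
  invisible(x)
}

#' Smooth complex coil sensitivity maps
#'
#' Generates `n_coils` spatially smooth complex sensitivity fields (one
#' Gaussian bump per coil placed on a ring around the field of view, with a
#' smooth linear phase), root-sum-of-squares normalised to 1 at every voxel
#' and phase-aligned to the first coil. For `n_coils = 1` this yields a map
#' of exact ones. Only smoothness and RSS normalisation matter to the
#' reconstruction contract; the coil count is configurable (small values
#' keep simulations light; a clinical body array has many more elements).
#'
#' @param grid_shape integer `(nx, ny, nz)`.
#' @param n_coils number of receive channels (>= 1).
#' @param smoothness_scale bump width as a fraction of the half field of
#'   view (default 0.8; larger = smoother).
#' @param seed integer seed.
#' @return A `sense_maps` object: `maps` complex `(nx, ny, nz, n_coils)`
#'   array, `support` logical array (all `TRUE` for generated maps).
#' @export
coil_sensitivities <- function(grid_shape, n_coils = 4L,
                               smoothness_scale = 0.8, seed = 1L) {
  if (n_coils < 1) stop("n_coils must be >= 1")
  n <- as.integer(grid_shape)
  stopifnot(length(n) == 3)
  set.seed(as.integer(seed))
  xn <- axis_mm(n[1], 2 / n[1])   # normalised [-1, 1) coords
  yn <- axis_mm(n[2], 2 / n[2])
  zn <- axis_mm(n[3], 2 / n[3])
  maps <- array(0i, c(n, n_coils))
  for (c_i in seq_len(n_coils)) {
    ang <- 2 * pi * (c_i - 1) / n_coils + runif(1, -0.2, 0.2)
    cy <- 1.2 * cos(ang); cz <- 1.2 * sin(ang)
    sig <- smoothness_scale
    bump <- 0.05 + exp(-outer((yn - cy)^2, (zn - cz)^2, `+`) / (2 * sig^2))
    py <- runif(1, -1, 1); pz <- runif(1, -1, 1); p0 <- runif(1, 0, 2 * pi)
    phase <- exp(1i * (outer(py * yn, pz * zn, `+`) + p0))
    plane <- bump * phase
    tilt <- 1 + 0.1 * runif(1, -1, 1) * xn
    m <- array(rep(as.vector(plane), each = n[1]), n) *
      array(rep(tilt, times = n[2] * n[3]), n)
    maps[, , , c_i] <- m
  }
  mm <- Mod(maps)^2
  dim(mm) <- c(prod(n), n_coils)
  rss <- array(sqrt(rowSums(mm)), n)
  maps <- maps / array(rep(rss, n_coils), dim = dim(maps))
  ph1 <- maps[, , , 1, drop = FALSE]
  ph1 <- ph1 / Mod(ph1)
  maps <- maps * array(rep(Conj(ph1), n_coils), dim = dim(maps))
  structure(list(maps = maps, support = array(TRUE, n)),
            class = "sense_maps")
}

#' Simulate a multi-coil undersampled acquisition
#'
#' Forward model of the acquisition: for each coil `n`, the centred unitary
#' Fourier transform of the coil-weighted image `CSM_n * x`, restricted to
#' the sampled phase-encode locations, plus i.i.d. complex Gaussian noise at
#' the sampled locations. Unsampled locations are stored as exactly zero and
#' the mask is retained. The readout dimension (first array dimension) is
#' always fully sampled.
#'
#' @param phantom a `digital_phantom`, or a real/complex `(nx, ny, nz)`
#'   image array.
#' @param maps a `sense_maps` object of matching shape.
#' @param mask a `sampling_mask` on the `(ny, nz)` phase-encode plane.
#' @param noise_sd per-component SD of the added complex noise; defaults to
#'   the phantom spec's `noise_sd` (0 for a plain array input).
#' @param seed integer seed for the noise draw.
#' @return A `kspace_acquisition`: `data` complex `(nx, ny, nz, n_coils)`,
#'   `mask`, `n_coils`, `noise_sd`.
#' @export
simulate_acquisition <- function(phantom, maps, mask, noise_sd = NULL,
                                 seed = 1L) {
  x <- if (inherits(phantom, "digital_phantom")) phantom$intensity else phantom
  if (is.null(noise_sd)) {
    noise_sd <- if (inherits(phantom, "digital_phantom")) phantom$spec$noise_sd else 0
  }
  stopifnot(inherits(maps, "sense_maps"), inherits(mask, "sampling_mask"))
  n <- dim(x)
  if (!all(dim(maps$maps)[1:3] == n)) stop("coil map shape does not match the image")
  if (mask$ny != n[2] || mask$nz != n[3]) stop("mask shape does not match the phase-encode plane")
  n_coils <- dim(maps$maps)[4]
  m3 <- broadcast_mask(mask$grid, n[1])
  set.seed(as.integer(seed))
  data <- array(0i, c(n, n_coils))
  for (c_i in seq_len(n_coils)) {
    cm <- maps$maps[, , , c_i]
    dim(cm) <- n
    k <- fftc(cm * x)
    k[!m3] <- 0i
    ns <- sum(m3)
    if (noise_sd > 0) k[m3] <- k[m3] + complex_noise(ns, noise_sd)
    data[, , , c_i] <- k
  }
  structure(list(data = data, mask = mask, n_coils = n_coils,
                 noise_sd = noise_sd),
            class = "kspace_acquisition")
}
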