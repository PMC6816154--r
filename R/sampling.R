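# Variable-density Poisson-disc undersampling of the phase-encode plane.
#
# The acquisition undersamples only the two phase-encode directions, so a
# mask is a boolean (ny x nz) matrix. Sampling is restricted to the inscribed
# ellipse (elliptical k-space coverage); a central elliptical calibration
# region is always fully sampled so coil sensitivities can be estimated from
# it. The local minimum-distance radius grows linearly with normalised
# elliptical radius, r(rho) = r0 * (1 + density_decay * rho), giving denser
# sampling near the k-space centre. r0 is calibrated by bisection so the
# fraction of in-ellipse points that is sampled matches 1/target_accel.

# normalised elliptical radius of every grid point; centre at the
# centred-k-space DC position, semi-axes ny/2 and nz/2
ellipse_rho <- function(ny, nz) {
  cy <- ny %/% 2L + 1L  # DC index in the centred-FFT convention
  cz <- nz %/% 2L + 1L
  ry <- (seq_len(ny) - cy) / (ny / 2)
  rz <- (seq_len(nz) - cz) / (nz / 2)
  sqrt(outer(ry^2, rz^2, `+`))
}

new_sampling_mask <- function(grid, calib, in_ellipse, target_accel,
                              calib_fraction, density_decay, r0, tol, seed) {
  structure(list(
    grid = grid,
    calib = calib,
    in_ellipse = in_ellipse,
    ny = nrow(grid),
    nz = ncol(grid),
    ellipse_semi_axes = c(nrow(grid) / 2, ncol(grid) / 2),
    target_accel = target_accel,
    achieved_fraction = sum(grid & in_ellipse) / sum(in_ellipse),
    calib_fraction = calib_fraction,
    density_decay = density_decay,
    r0 = r0,
    tol = tol,
    seed = seed
  ), class = "sampling_mask")
}

#' Variable-density Poisson-disc undersampling mask
#'
#' Generates a boolean undersampling mask for the (ny, nz) phase-encode plane
#' with elliptical k-space coverage and a fully sampled central calibration
#' region. Outside the calibration region, samples form a variable-density
#' Poisson-disc pattern: any two sampled points at normalised elliptical
#' radii rho_1, rho_2 are at least `min(r(rho_1), r(rho_2))` apart, with
#' `r(rho) = r0 * (1 + density_decay * rho)`. The base radius `r0` is
#' calibrated by bisection until the sampled fraction of the ellipse is
#' within `tol` of `1/target_accel`.
#'
#' @param ny,nz phase-encode matrix size.
#' @param target_accel target acceleration factor (>= 1); the mask samples
#'   `1/target_accel` of the in-ellipse locations.
#' @param calib_fraction fraction of the in-ellipse area occupied by the
#'   fully sampled central calibration ellipse (default 0.04).
#' @param density_decay slope of the minimum-distance radius with normalised
#'   elliptical radius (default 2); 0 gives a uniform-density pattern.
#' @param seed integer seed; the candidate visiting order is drawn from R's
#'   RNG so masks are reproducible.
#' @param tol tolerance on `|achieved_fraction - 1/target_accel|`
#'   (default 0.005).
#' @param max_iter maximum bisection steps for the radius calibration.
#' @return A `sampling_mask` object: fields `grid` (logical ny x nz),
#'   `calib`, `in_ellipse`, `achieved_fraction`, `target_accel`, `r0`,
#'   `seed`, and the generation parameters.
#' @seealso [full_mask()], [sampling_fraction()], [mask_diagnostics()]
#' @export
poisson_disc_mask <- function(ny, nz, target_accel, calib_fraction = 0.04,
                              density_decay = 2, seed = 1L, tol = 0.005,
                              max_iter = 30L) {
  stopifnot(ny >= 4, nz >= 4)
  if (target_accel < 1) stop("target_accel must be >= 1")
  rho <- ellipse_rho(ny, nz)
  in_ellipse <- rho <= 1
  calib <- rho <= sqrt(calib_fraction)
  n_ell <- sum(in_ellipse)
  target <- 1 / target_accel
  if (sum(calib) / n_ell > target + tol) {
    stop(sprintf(
      "infeasible: calibration region (%.3f of ellipse) exceeds the sampling budget 1/%g",
      sum(calib) / n_ell, target_accel))
  }
  if (target_accel == 1) {
    return(new_sampling_mask(in_ellipse, calib, in_ellipse, target_accel,
                             calib_fraction, density_decay, NA_real_, tol, seed))
  }

  cand <- which(in_ellipse & !calib, arr.ind = TRUE)
  set.seed(as.integer(seed))
  ord <- sample.int(nrow(cand))
  cand <- cand[ord, , drop = FALSE]
  rho_cand <- rho[in_ellipse & !calib][ord]
  pts <- matrix(as.numeric(cand), ncol = 2)

  frac_at <- function(r0) {
    radii <- r0 * (1 + density_decay * rho_cand)
    acc <- pd_darts(pts, radii, cell = r0, rmax = max(radii))
    (sum(acc) + sum(calib)) / n_ell
  }

  # at the lower bracket every local radius is below the grid spacing, so
  # every candidate is accepted and the fraction is 1
  lo <- min(0.5, 0.9 / (1 + density_decay))
  hi <- 2
  f_hi <- frac_at(hi)
  grow <- 0L
  while (f_hi > target && grow < 20L) {
    hi <- hi * 2
    f_hi <- frac_at(hi)
    grow <- grow + 1L
  }
  best_r <- hi; best_f <- f_hi
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f <- frac_at(mid)
    if (abs(f - target) < abs(best_f - target)) {
      best_f <- f; best_r <- mid
    }
    if (abs(best_f - target) <= tol / 2) break
    if (f > target) lo <- mid else hi <- mid
  }
  if (abs(best_f - target) > tol) {
    stop(sprintf(
      "radius calibration did not reach tolerance: best fraction %.4f vs target %.4f (tol %.4f)",
      best_f, target, tol))
  }

  radii <- best_r * (1 + density_decay * rho_cand)
  acc <- pd_darts(pts, radii, cell = best_r, rmax = max(radii))
  grid <- calib
  grid[pts[acc, , drop = FALSE]] <- TRUE
  new_sampling_mask(grid, calib, in_ellipse, target_accel, calib_fraction,
                    density_decay, best_r, tol, seed)
}

#' Fully sampled mask
#'
#' Mask sampling every phase-encode location (rectangular coverage); used for
#' the fully sampled reference acquisition. A central calibration region is
#' still delineated so sensitivity estimation treats both arms identically.
#'
#' @inheritParams poisson_disc_mask
#' @return A `sampling_mask` with `grid` and `in_ellipse` all `TRUE`.
#' @export
full_mask <- function(ny, nz, calib_fraction = 0.04) {
  rho <- ellipse_rho(ny, nz)
  grid <- matrix(TRUE, ny, nz)
  new_sampling_mask(grid, rho <= sqrt(calib_fraction), grid,
                    target_accel = 1, calib_fraction = calib_fraction,
                    density_decay = 0, r0 = NA_real_, tol = 0, seed = NA_integer_)
}

#' Sampled fraction of the elliptical k-space footprint
#'
#' @param mask a `sampling_mask`.
#' @return `(# sampled points inside the ellipse) / (# points inside the
#'   ellipse)`.
#' @export
sampling_fraction <- function(mask) {
  stopifnot(inherits(mask, "sampling_mask"))
  sum(mask$grid & mask$in_ellipse) / sum(mask$in_ellipse)
}

#' Mask diagnostics: minimum distances by annulus and point-spread function
#'
#' Verifies the two structural claims about a mask: (i) the variable-density
#' Poisson-disc property, via the minimum pairwise distance among sampled
#' points in concentric elliptical annuli (with the generation-time lower
#' bound `r0 * (1 + density_decay * rho_lo)` for reference), and (ii) the
#' incoherence of the pattern, via the point-spread function (inverse
#' transform of the mask): its peak and the largest sidelobe outside a small
#' exclusion window around the peak.
#'
#' @param mask a `sampling_mask`, or a plain logical matrix (treated as a
#'   mask with no calibration region and full elliptical support).
#' @param n_annuli number of annuli between the calibration edge and the
#'   ellipse boundary.
#' @param exclude_radius half-width (in pixels) of the window around the PSF
#'   peak excluded from the sidelobe search.
#' @return A list: `annuli` (data frame with `rho_lo`, `rho_hi`, `n`,
#'   `min_dist`, `bound`), `psf_peak`, `psf_max_sidelobe`,
#'   `psf_sidelobe_ratio`.
#' @export
mask_diagnostics <- function(mask, n_annuli = 4L, exclude_radius = 2L) {
  if (is.matrix(mask) && !inherits(mask, "sampling_mask")) {
    grid <- mask
    rho <- ellipse_rho(nrow(grid), ncol(grid))
    calib <- matrix(FALSE, nrow(grid), ncol(grid))
    rho_lo0 <- 0; r0 <- NA_real_; decay <- 0
  } else {
    stopifnot(inherits(mask, "sampling_mask"))
    grid <- mask$grid
    rho <- ellipse_rho(mask$ny, mask$nz)
    calib <- mask$calib
    rho_lo0 <- sqrt(mask$calib_fraction)
    r0 <- mask$r0; decay <- mask$density_decay
  }

  psf <- fftshift(ifftc(grid * (1 + 0i)))
  mag <- Mod(psf)
  pk <- which(mag == max(mag), arr.ind = TRUE)[1, ]
  excl <- outer(abs(seq_len(nrow(grid)) - pk[1]) <= exclude_radius,
                abs(seq_len(ncol(grid)) - pk[2]) <= exclude_radius, `&`)
  sidelobe <- if (all(excl)) 0 else max(mag[!excl])

  edges <- seq(rho_lo0, 1, length.out = n_annuli + 1L)
  rows <- lapply(seq_len(n_annuli), function(a) {
    sel <- grid & !calib & rho > edges[a] & rho <= edges[a + 1L]
    idx <- which(sel, arr.ind = TRUE)
    md <- if (nrow(idx) >= 2) min(dist(idx)) else NA_real_
    data.frame(rho_lo = edges[a], rho_hi = edges[a + 1L], n = nrow(idx),
               min_dist = md,
               bound = if (is.na(r0)) NA_real_ else r0 * (1 + decay * edges[a]))
  })
  list(annuli = do.call(rbind, rows),
       psf_peak = max(mag),
       psf_max_sidelobe = sidelobe,
       psf_sidelobe_ratio = sidelobe / max(mag))
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf(
    "<sampling_mask> %d x %d, target R = %g, sampled %.1f%% of ellipse (calib %.1f%%), seed %s\n",
    x$ny, x$nz, x$target_accel, 100 * x$achieved_fraction,
    100 * x$calib_fraction, format(x$seed)))
  invisible(x)
}
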