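# Morphometry of magnitude volumes: per-slice inner (lumen-thrombus) and
# outer (wall-background) boundaries by sub-voxel radial max-gradient
# search, areas by polygon integration, maximal diameter as the Feret width
# of the outer contour, thrombus signal ratios against a psoas-muscle
# reference region, thrombus typing by the bright-voxel fraction, and the
# endpoint growth-rate formula.

# shoelace area of a polygon given polar radii at equally spaced angles
polar_area <- function(r, theta) {
  y <- r * cos(theta); z <- r * sin(theta)
  j <- c(seq_along(r)[-1], 1L)
  abs(sum(y * z[j] - y[j] * z)) / 2
}

# circular linear interpolation of per-angle radii over failed rays
fill_circular <- function(r, theta) {
  ok <- is.finite(r)
  if (all(ok)) return(r)
  if (!any(ok)) return(r)
  th <- theta[ok]
  rv <- r[ok]
  out <- approx(x = c(th - 2 * pi, th, th + 2 * pi), y = rep(rv, 3),
                xout = theta, rule = 2)$y
  ifelse(ok, r, out)
}

# low-pass a per-angle radius function by truncating its Fourier series;
# suppresses voxel-phase oscillation while preserving genuine ovality
smooth_radii <- function(r, harmonics) {
  n <- length(r)
  if (!all(is.finite(r)) || harmonics >= n %/% 2) return(r)
  co <- fft(r)
  k <- c(0:(n - 1))
  k <- pmin(k, n - k)
  co[k > harmonics] <- 0i
  Re(fft(co, inverse = TRUE)) / n
}

# sub-sample refinement of a gradient extremum at index k: centroid (first
# moment) of the positive part of the peak over a small window; varies
# smoothly with the sub-voxel phase of the edge, unlike a 3-point parabola
# on piecewise-linear interpolated profiles
refine_peak <- function(g, k, halfwidth = 3L) {
  idx <- max(1L, k - halfwidth):min(length(g), k + halfwidth)
  w <- g[idx] - min(g[idx])
  if (sum(w) == 0) return(0)
  d <- sum(w * (idx - k)) / sum(w)
  max(min(d, halfwidth), -halfwidth)
}

locate_edges_on_ray <- function(p, gr, pos, r_mid, gthr, edge_frac, min_sep,
                                low_level, max_annulus, sustain_n) {
  # p: intensity profile at positions `pos` (mm); gr: radial gradient at the
  # interior positions `r_mid`.
  #
  # Inner interface (lumen-thrombus): innermost qualifying rising gradient
  # peak, refined to sub-sample precision.
  #
  # Outer interface (outer wall surface): the first sustained fall of the
  # profile below `low_level` (a level between the wall and the background)
  # beyond the inner edge, located by linear interpolation of the level
  # crossing. A level crossing moves continuously with the sub-voxel phase
  # of the geometry even when the thin wall is only marginally resolved
  # against a bright thrombus, where competing gradient peaks would make the
  # detection bistable. The search stops at `max_annulus` beyond the inner
  # edge, which keeps unrelated structures (muscle, spine) out of reach.
  n <- length(gr)
  inner <- NA_real_; outer <- NA_real_
  loc_max <- which(gr >= c(-Inf, gr[-n]) & gr >= c(gr[-1], Inf))
  cand <- loc_max[gr[loc_max] >= max(edge_frac * max(gr), gthr)]
  if (length(cand)) {
    k <- cand[1]
    inner <- r_mid[k] + refine_peak(gr, k) * (r_mid[2] - r_mid[1])
  }
  if (is.finite(inner)) {
    win <- which(pos > inner + min_sep & pos <= inner + max_annulus)
    if (length(win) > 1) {
      below <- p[win] < low_level
      runs <- rle(below)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      hit <- which(runs$values &
                     (runs$lengths >= sustain_n | ends == length(below)))
      if (length(hit)) {
        k <- win[starts[hit[1]]]
        if (k > 1 && p[k - 1L] >= low_level && p[k - 1L] > p[k]) {
          outer <- pos[k - 1L] + (p[k - 1L] - low_level) / (p[k - 1L] - p[k]) *
            (pos[k] - pos[k - 1L])
        } else {
          outer <- pos[k]
        }
      }
    }
  }
  c(inner, outer)
}

#' Extract vessel cross-sections from a magnitude volume
#'
#' For every slice along the vessel (first array) dimension, casts `n_rays`
#' radial rays from the lumen centre hint, samples the intensity profile at
#' quarter-voxel spacing by bilinear interpolation, and locates the inner
#' (lumen-thrombus, rising) and outer (wall-background, falling) interfaces
#' at sub-voxel precision by max-gradient search with parabolic refinement.
#' The inner edge is the innermost qualifying rising edge; the outer edge is
#' the outermost qualifying falling edge beyond it. Rays without a
#' detectable edge are interpolated circularly from their neighbours; a
#' slice with more than `max_failed_frac` failed rays for an interface is
#' flagged invalid for that interface. Areas are polygon integrals of the
#' boundary points.
#'
#' @param image real 3D magnitude array, vessel axis along dimension 1.
#' @param voxel_size isotropic voxel size in mm.
#' @param center lumen centre hint `(y, z)` in voxel index units (default:
#'   grid centre, correct for generated phantoms).
#' @param n_rays number of radial rays (default 64).
#' @param max_radius_mm outer limit of the radial search (default: half the
#'   smaller in-plane extent minus 2 voxels).
#' @param smooth_sigma Gaussian smoothing (in voxels) applied to each slice
#'   before gradient search (default 0.35; light, so closely spaced
#'   interfaces across the thin wall stay separable).
#' @param contour_harmonics highest angular Fourier harmonic kept when
#'   regularising the per-angle boundary radii (default 6); suppresses
#'   voxel-phase oscillation of the detected contour while preserving
#'   genuine ovality.
#' @param upsample Fourier (sinc) upsampling factor applied to each slice
#'   before profile sampling (default 2); magnitude MR images are
#'   band-limited, so this is the natural sub-voxel interpolant.
#' @param max_annulus_mm maximum distance of the outer boundary beyond the
#'   inner boundary (default 14, generous for a thrombus layer plus wall);
#'   keeps unrelated structures out of the outer-boundary search.
#' @param edge_frac a gradient peak qualifies if it reaches this fraction of
#'   the ray's strongest peak (default 0.5).
#' @param detect_frac absolute gradient threshold as a fraction of the
#'   volume's robust intensity range (default 0.04).
#' @param max_failed_frac maximum tolerated fraction of failed rays.
#' @return A list of `cross_section` records: `slice`, `valid`
#'   (inner boundary found), `valid_outer`, `theta`, `r_inner_mm`,
#'   `r_outer_mm`, `center_vox`, `lumen_area_cm2`, `ilt_wall_area_cm2`,
#'   `outer_diameter_cm`, `voxel_size`.
#' @export
extract_cross_sections <- function(image, voxel_size, center = NULL,
                                   n_rays = 64L, max_radius_mm = NULL,
                                   smooth_sigma = 0.35, edge_frac = 0.5,
                                   detect_frac = 0.04,
                                   max_failed_frac = 0.25,
                                   contour_harmonics = 6L,
                                   upsample = 2L,
                                   max_annulus_mm = 14) {
  dm <- dim(image)
  stopifnot(length(dm) == 3)
  ny <- dm[2]; nz <- dm[3]
  if (is.null(center)) center <- c((ny + 1) / 2, (nz + 1) / 2)
  if (is.null(max_radius_mm)) {
    max_radius_mm <- (min(ny, nz) / 2 - 2) * voxel_size
  }
  step <- 0.25   # voxels
  r_grid_vox <- seq(0.5, max_radius_mm / voxel_size, by = step)
  theta <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  yy <- outer(cos(theta), r_grid_vox) + center[1]
  zz <- outer(sin(theta), r_grid_vox) + center[2]
  qs <- quantile(image, c(0.001, 0.999), names = FALSE)
  gthr <- detect_frac * (qs[2] - qs[1])
  low_level <- qs[1] + 0.35 * (qs[2] - qs[1])
  nk <- length(r_grid_vox)
  pos_mm <- r_grid_vox * voxel_size
  r_mid <- pos_mm[-c(1L, nk)]
  sustain_n <- max(2L, round(1.5 / (0.25 * voxel_size)))  # ~1.5 mm

  lapply(seq_len(dm[1]), function(i) {
    S <- fourier_upsample2(image[i, , ], upsample, smooth_sigma)
    P <- matrix(bilinear(S, (as.vector(yy) - 1) * upsample + 1,
                         (as.vector(zz) - 1) * upsample + 1), n_rays, nk)
    G <- (P[, -c(1L, 2L), drop = FALSE] - P[, -c(nk - 1L, nk), drop = FALSE]) / 2
    edges <- t(vapply(seq_len(n_rays), function(j) {
      locate_edges_on_ray(P[j, ], G[j, ], pos_mm, r_mid, gthr, edge_frac,
                          min_sep = voxel_size, low_level = low_level,
                          max_annulus = max_annulus_mm, sustain_n = sustain_n)
    }, numeric(2)))
    r_in <- edges[, 1]; r_out <- edges[, 2]
    fail_in <- mean(!is.finite(r_in))
    fail_out <- mean(!is.finite(r_out))
    valid <- fail_in <= max_failed_frac
    valid_outer <- valid && fail_out <= max_failed_frac
    r_in <- smooth_radii(fill_circular(r_in, theta), contour_harmonics)
    r_out <- smooth_radii(fill_circular(r_out, theta), contour_harmonics)
    lumen_area <- if (valid) polar_area(r_in, theta) / 100 else NA_real_
    outer_area <- if (valid_outer) polar_area(r_out, theta) / 100 else NA_real_
    od <- if (valid_outer) {
      y <- r_out * cos(theta); z <- r_out * sin(theta)
      max(dist(cbind(y, z))) / 10
    } else NA_real_
    structure(list(slice = i, valid = valid, valid_outer = valid_outer,
                   theta = theta, r_inner_mm = r_in, r_outer_mm = r_out,
                   center_vox = center, lumen_area_cm2 = lumen_area,
                   ilt_wall_area_cm2 = if (valid_outer) outer_area - lumen_area else NA_real_,
                   outer_diameter_cm = od, voxel_size = voxel_size),
              class = "cross_section")
  })
}

#' Maximal aneurysm diameter over cross-sections
#'
#' Per-slice outer diameter is the maximal caliper (Feret) width of the
#' outer boundary polygon; the result is the maximum over valid slices.
#' Two robustness passes exploit the anatomy of a fusiform aneurysm:
#' slices whose diameter deviates from the running 5-slice median by more
#' than `outlier_frac` are treated as detection failures, and the diameter
#' profile is required to be unimodal walking outward from the apex
#' (slices that bounce back above the running minimum by more than
#' `outlier_frac` are dropped). When at least five valid slices surround
#' the apex, the reported maximum comes from a local quadratic fit of the
#' diameter profile (sub-slice interpolation, as in multi-planar reading),
#' which suppresses single-slice noise.
#'
#' @param sections list of `cross_section` records.
#' @param outlier_frac relative tolerance of the two robustness passes
#'   (default 0.15).
#' @return A list `diameter_cm`, `slice`.
#' @export
max_diameter <- function(sections, outlier_frac = 0.15) {
  od <- vapply(sections, function(s) {
    if (isTRUE(s$valid_outer)) s$outer_diameter_cm else NA_real_
  }, numeric(1))
  slices <- vapply(sections, function(s) s$slice, numeric(1))
  if (!any(is.finite(od))) stop("no valid cross-sections")
  if (sum(is.finite(od)) >= 3) {
    idx <- which(is.finite(od))
    v <- od[idx]
    n <- length(v)
    med5 <- vapply(seq_len(n), function(i) {
      w <- max(1L, min(i - 2L, n - 4L)):min(n, max(i + 2L, 5L))
      median(v[w])
    }, numeric(1))
    keep <- abs(v - med5) <= outlier_frac * med5
    # unimodality: walking from the apex outward the calibre cannot grow.
    # The apex itself is located by the windowed minimum, which a short run
    # of corrupted slices cannot inflate.
    if (any(keep)) {
      win_min <- vapply(seq_len(n), function(i) {
        min(v[max(1L, min(i - 2L, n - 4L)):min(n, max(i + 2L, 5L))])
      }, numeric(1))
      win_min[!keep] <- -Inf
      k_apex <- which.max(win_min)
      for (dir in c(-1L, 1L)) {
        runmin <- v[k_apex]
        i <- k_apex + dir
        while (i >= 1L && i <= n) {
          if (keep[i]) {
            if (v[i] > runmin * (1 + outlier_frac)) keep[i] <- FALSE
            else runmin <- min(runmin, v[i])
          }
          i <- i + dir
        }
      }
    }
    od[idx[!keep]] <- NA_real_
    if (!any(is.finite(od))) stop("no valid cross-sections after outlier rejection")
  }
  k <- which.max(od)
  out <- list(diameter_cm = od[k], slice = sections[[k]]$slice)
  near <- which(is.finite(od) & abs(slices - out$slice) <= 6)
  if (length(near) >= 5) {
    fit <- lm(y ~ x + I(x^2), data.frame(x = slices[near], y = od[near]))
    cf <- coef(fit)
    if (is.finite(cf[3]) && cf[3] < 0) {
      xv <- -cf[2] / (2 * cf[3])
      xv <- min(max(xv, min(slices[near])), max(slices[near]))
      out$diameter_cm <- unname(cf[1] + cf[2] * xv + cf[3] * xv^2)
      out$slice <- slices[near][which.min(abs(slices[near] - xv))]
    }
  }
  out
}

# per-pixel membership of the thrombus annulus / lumen at one slice, from
# the per-angle boundary radii; margins in mm keep partial-volume edges and
# the thin wall out of the signal regions
slice_regions <- function(section, dims, wall_margin_mm, edge_margin_mm) {
  ny <- dims[1]; nz <- dims[2]
  vox <- section$voxel_size
  y <- (seq_len(ny) - section$center_vox[1]) * vox
  z <- (seq_len(nz) - section$center_vox[2]) * vox
  R <- sqrt(outer(y^2, z^2, `+`))
  TH <- atan2(rep(z, each = ny), rep(y, times = nz)) %% (2 * pi)
  dim(TH) <- c(ny, nz)
  th <- section$theta
  rin_f <- approx(c(th, th[1] + 2 * pi), c(section$r_inner_mm, section$r_inner_mm[1]),
                  xout = as.vector(TH), rule = 2)$y
  rout_f <- approx(c(th, th[1] + 2 * pi), c(section$r_outer_mm, section$r_outer_mm[1]),
                   xout = as.vector(TH), rule = 2)$y
  rin <- array(rin_f, c(ny, nz))
  rout <- array(rout_f, c(ny, nz))
  list(lumen = R <= rin - edge_margin_mm,
       ilt = R >= rin + edge_margin_mm &
         R <= rout - wall_margin_mm - edge_margin_mm)
}

#' Thrombus and lumen signal ratios at the maximal-diameter slice
#'
#' Computes the ILT-to-muscle signal-intensity ratio and the ILT-to-lumen
#' contrast ratio from mean intensities: the thrombus region is the annulus
#' between the detected inner contour and the outer contour shrunk by a wall
#' margin (default 2 mm, excluding the thin wall) with half-voxel edge
#' margins; the lumen region is inside the inner contour; the muscle region
#' is supplied as a mask (for phantoms, the eroded muscle label).
#'
#' @param image real 3D magnitude array.
#' @param sections output of [extract_cross_sections()].
#' @param muscle_mask logical array like `image` (or a 2D mask applied at
#'   the measured slice).
#' @param wall_margin_mm outer margin excluded as wall (default 2).
#' @param edge_margin_mm margin around each contour (default 0.65, half a
#'   protocol voxel).
#' @return List `ilt_muscle_ratio`, `ilt_lumen_contrast_ratio`,
#'   `mean_ilt`, `mean_lumen`, `mean_muscle`, `slice`. Ratios are `NA` when
#'   the thrombus region is empty (no ILT).
#' @export
signal_ratios <- function(image, sections, muscle_mask,
                          wall_margin_mm = 2, edge_margin_mm = 0.65) {
  md <- max_diameter(sections)
  sec <- sections[[md$slice]]
  S <- image[md$slice, , ]
  msk <- if (length(dim(muscle_mask)) == 3) muscle_mask[md$slice, , ] else muscle_mask
  if (!any(msk)) stop("muscle ROI is empty")
  reg <- slice_regions(sec, dim(S), wall_margin_mm, edge_margin_mm)
  mean_muscle <- mean(S[msk])
  if (mean_muscle <= 0) stop("muscle mean intensity is not positive")
  if (!any(reg$lumen)) stop("lumen region is empty")
  mean_lumen <- mean(S[reg$lumen])
  if (mean_lumen <= 0) stop("lumen mean intensity is not positive")
  mean_ilt <- if (any(reg$ilt)) mean(S[reg$ilt]) else NA_real_
  list(ilt_muscle_ratio = mean_ilt / mean_muscle,
       ilt_lumen_contrast_ratio = mean_ilt / mean_lumen,
       mean_ilt = mean_ilt, mean_lumen = mean_lumen,
       mean_muscle = mean_muscle, slice = md$slice)
}

#' Classify the intraluminal thrombus type
#'
#' Voxel-wise ILT-to-muscle ratios are computed over the thrombus annulus at
#' the maximal-diameter slice; a voxel is bright if its ratio exceeds
#' `bright_threshold` (1.2 by convention). With `f` the bright fraction:
#' type 4 if the thrombus area is below `area_floor_cm2`; type 1
#' (dominantly bright) if `f >= frac_bright`; type 2 (mixed) if
#' `frac_iso <= f < frac_bright`; type 3 (all iso-intense) otherwise.
#'
#' @inheritParams signal_ratios
#' @param bright_threshold ILT-to-muscle ratio above which a voxel counts as
#'   bright (default 1.2).
#' @param frac_bright,frac_iso bright-fraction cutoffs for types 1/2/3
#'   (defaults 0.7 and 0.3).
#' @param area_floor_cm2 thrombus area below which type 4 (no ILT) is
#'   declared (default 0.5).
#' @return Integer type in 1:4.
#' @export
classify_ilt <- function(image, sections, muscle_mask,
                         bright_threshold = 1.2, frac_bright = 0.7,
                         frac_iso = 0.3, area_floor_cm2 = 0.5,
                         wall_margin_mm = 2, edge_margin_mm = 0.65) {
  md <- max_diameter(sections)
  sec <- sections[[md$slice]]
  if (!isTRUE(sec$valid)) stop("maximal-diameter cross-section is invalid")
  S <- image[md$slice, , ]
  msk <- if (length(dim(muscle_mask)) == 3) muscle_mask[md$slice, , ] else muscle_mask
  if (!any(msk)) stop("muscle ROI is empty")
  mean_muscle <- mean(S[msk])
  reg <- slice_regions(sec, dim(S), wall_margin_mm, edge_margin_mm)
  area <- sum(reg$ilt) * sec$voxel_size^2 / 100
  if (area < area_floor_cm2) return(4L)
  f <- mean(S[reg$ilt] / mean_muscle > bright_threshold)
  if (f >= frac_bright) 1L else if (f >= frac_iso) 2L else 3L
}

#' Aneurysm growth rate (endpoint formula)
#'
#' `(diameter at the latest time point - diameter at baseline) / follow-up
#' duration`, with the duration in 365.25-day years and the result in
#' mm/year. Intermediate time points are ignored by design.
#'
#' @param diameters_cm diameters in cm, one per time point.
#' @param dates calendar dates (`Date` or coercible), strictly increasing.
#' @return Growth rate in mm/year.
#' @export
growth_rate <- function(diameters_cm, dates) {
  if (length(diameters_cm) < 2 || length(dates) != length(diameters_cm)) {
    stop("need >= 2 time points with one diameter per date")
  }
  dates <- as.Date(dates)
  if (any(diff(as.numeric(dates)) <= 0)) stop("dates must be strictly increasing")
  dd_mm <- (diameters_cm[length(diameters_cm)] - diameters_cm[1]) * 10
  years <- as.numeric(dates[length(dates)] - dates[1]) / 365.25
  dd_mm / years
}

# 1-voxel in-plane erosion of a 3D logical mask (used for the muscle ROI)
erode_mask <- function(mask) {
  out <- mask
  n <- dim(mask)
  sh <- function(m, dy, dz) {
    p <- array(FALSE, dim(m))
    ys <- seq_len(n[2] - abs(dy)); zs <- seq_len(n[3] - abs(dz))
    p[, ys + max(dy, 0), zs + max(dz, 0)] <- m[, ys + max(-dy, 0), zs + max(-dz, 0)]
    p
  }
  out & sh(mask, 1, 0) & sh(mask, -1, 0) & sh(mask, 0, 1) & sh(mask, 0, -1)
}

#' Measure a reconstructed volume
#'
#' Runs the full per-volume morphometry: cross-section extraction, maximal
#' diameter, areas at the maximal slice, thrombus signal ratios and type,
#' and inner/outer boundary sharpness at the maximal slice.
#'
#' @inheritParams extract_cross_sections
#' @param muscle_mask logical array delineating the reference muscle.
#' @param ... further arguments passed to [extract_cross_sections()].
#' @return An `aneurysm_measures` list: `max_diameter_cm`, `max_slice`,
#'   `lumen_area_cm2`, `ilt_wall_area_cm2`, `ilt_muscle_ratio`,
#'   `ilt_lumen_contrast_ratio`, `ilt_type`, `sharpness_inner`,
#'   `sharpness_outer`, `sharpness_avg`.
#' @export
measure_volume <- function(image, voxel_size, muscle_mask, ...) {
  sections <- extract_cross_sections(image, voxel_size, ...)
  md <- max_diameter(sections)
  sec <- sections[[md$slice]]
  ratios <- signal_ratios(image, sections, muscle_mask)
  type <- classify_ilt(image, sections, muscle_mask)
  sh <- boundary_sharpness(image, sec)
  structure(list(
    max_diameter_cm = md$diameter_cm, max_slice = md$slice,
    lumen_area_cm2 = sec$lumen_area_cm2,
    ilt_wall_area_cm2 = sec$ilt_wall_area_cm2,
    ilt_muscle_ratio = ratios$ilt_muscle_ratio,
    ilt_lumen_contrast_ratio = ratios$ilt_lumen_contrast_ratio,
    ilt_type = type,
    sharpness_inner = sh$sharpness_inner,
    sharpness_outer = sh$sharpness_outer,
    sharpness_avg = sh$sharpness_avg
  ), class = "aneurysm_measures")
}

#' @export
print.aneurysm_measures <- function(x, ...) {
  cat(sprintf(
    "<aneurysm_measures> D = %.2f cm (slice %d); lumen %.2f cm^2, ILT/wall %.2f cm^2; ILT/muscle %.2f, type %d; sharpness %.2f mm^-1\n",
    x$max_diameter_cm, x$max_slice, x$lumen_area_cm2, x$ilt_wall_area_cm2,
    x$ilt_muscle_ratio, x$ilt_type, x$sharpness_avg))
  invisible(x)
}
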