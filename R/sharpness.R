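# Boundary sharpness: inverse of the 20%-80% transition distance of the
# intensity profile across an interface, in 1/mm. For a linear ramp of
# width w the metric is 1/(0.6 w); for a step blurred by a Gaussian of
# standard deviation sigma it is 1/(2 * qnorm(0.8) * sigma) = 1/(1.683 sigma).

#' Sharpness of a sampled edge profile
#'
#' Measures the 20%-80% transition of a 1D intensity profile. The widest
#' monotone segment around the maximum-slope sample defines the edge; the
#' plateau levels flanking that segment are taken as medians and set the
#' edge amplitude; the 20% and 80% amplitude crossings are located by
#' linear interpolation between samples and the sharpness is the inverse of
#' their distance. The transition distance is floored at the sample
#' spacing.
#'
#' @param positions sample positions in mm (strictly increasing, ideally at
#'   quarter-voxel spacing or finer).
#' @param values intensity samples.
#' @param rising `TRUE` for a rising edge (e.g. lumen to thrombus),
#'   `FALSE` for a falling edge (wall to background).
#' @param min_amplitude minimum plateau-to-plateau amplitude; profiles below
#'   it yield `NA` sharpness.
#' @return A `sharpness_profile` list: `sharpness` (1/mm),
#'   `transition_distance` (mm), `amplitude`, `p20`, `p80`.
#' @export
edge_sharpness <- function(positions, values, rising = TRUE,
                           min_amplitude = 0) {
  stopifnot(length(positions) == length(values), length(values) >= 4)
  v <- if (rising) values else -values
  n <- length(v)
  g <- diff(v)
  i0 <- which.max(g)
  tolg <- 0.05 * max(g[i0], .Machine$double.eps)
  l <- i0
  while (l > 1L && g[l - 1L] > -tolg) l <- l - 1L
  r <- i0
  while (r < n - 1L && g[r + 1L] > -tolg) r <- r + 1L
  lo <- if (l > 1L) median(v[1:l]) else v[1]
  hi <- if (r < n - 1L) median(v[(r + 1L):n]) else v[n]
  amp <- hi - lo
  fail <- list(sharpness = NA_real_, transition_distance = NA_real_,
               amplitude = if (rising) amp else -amp,
               p20 = NA_real_, p80 = NA_real_)
  if (amp <= max(min_amplitude, 0)) return(structure(fail, class = "sharpness_profile"))
  v20 <- lo + 0.2 * amp
  v80 <- lo + 0.8 * amp

  k20 <- suppressWarnings(max(which(v[1:i0] <= v20)))
  k80cand <- which(v >= v80)
  k80cand <- k80cand[k80cand > i0 - 1L]
  if (!is.finite(k20) || !length(k80cand)) {
    return(structure(fail, class = "sharpness_profile"))
  }
  k80 <- min(k80cand)
  interp_cross <- function(k, level) {
    # crossing of `level` between samples k and k+1
    if (k >= n) return(positions[n])
    dv <- v[k + 1L] - v[k]
    if (dv == 0) return(positions[k])
    positions[k] + (level - v[k]) / dv * (positions[k + 1L] - positions[k])
  }
  p20 <- interp_cross(k20, v20)
  p80 <- if (k80 == 1L) positions[1L] else interp_cross(k80 - 1L, v80)
  spacing <- min(diff(positions))
  d <- max(p80 - p20, spacing)
  structure(list(sharpness = 1 / d, transition_distance = d,
                 amplitude = if (rising) amp else -amp,
                 p20 = p20, p80 = p80),
            class = "sharpness_profile")
}

#' Boundary sharpness of a cross-section
#'
#' Samples intensity profiles through the section centre along the two
#' orthogonal in-plane directions (both senses: left/right and
#' anterior/posterior), extracts a window around each detected interface
#' radius, and measures the 20%-80% sharpness of the inner (rising) and
#' outer (falling) interfaces with [edge_sharpness()]. Per-interface values
#' are means over the available direction profiles; profiles whose edge
#' amplitude is below 10% of the slice intensity range are dropped with a
#' warning.
#'
#' @param image real 3D magnitude array.
#' @param section one `cross_section` from [extract_cross_sections()].
#' @param window_mm length of the profile window centred on each interface
#'   (default 8).
#' @return A list: `sharpness_inner`, `sharpness_outer`, `sharpness_avg`
#'   (1/mm), and `profiles` (per direction and interface).
#' @export
boundary_sharpness <- function(image, section, window_mm = 8) {
  stopifnot(inherits(section, "cross_section"))
  if (!isTRUE(section$valid)) stop("cannot measure sharpness on an invalid section")
  vox <- section$voxel_size
  S <- image[section$slice, , ]
  rng <- diff(range(S))
  dirs <- c(0, pi / 2, pi, 3 * pi / 2)
  step <- 0.25 * vox
  profiles <- list()
  inner_v <- c(); outer_v <- c()
  for (a in dirs) {
    j <- which.min(abs(((section$theta - a + pi) %% (2 * pi)) - pi))
    for (iface in c("inner", "outer")) {
      r0 <- if (iface == "inner") section$r_inner_mm[j] else section$r_outer_mm[j]
      if (!is.finite(r0)) next
      pos <- seq(max(r0 - window_mm / 2, step), r0 + window_mm / 2, by = step)
      yv <- section$center_vox[1] + (pos / vox) * cos(a)
      zv <- section$center_vox[2] + (pos / vox) * sin(a)
      vals <- bilinear(S, yv, zv)
      pr <- edge_sharpness(pos, vals, rising = iface == "inner",
                           min_amplitude = 0.1 * rng)
      key <- sprintf("%s_%d", iface, round(a * 180 / pi))
      profiles[[key]] <- pr
      if (is.na(pr$sharpness)) {
        warning(sprintf("sharpness profile dropped (%s): edge amplitude too small", key))
      } else if (iface == "inner") {
        inner_v <- c(inner_v, pr$sharpness)
      } else {
        outer_v <- c(outer_v, pr$sharpness)
      }
    }
  }
  si <- if (length(inner_v)) mean(inner_v) else NA_real_
  so <- if (length(outer_v)) mean(outer_v) else NA_real_
  list(sharpness_inner = si, sharpness_outer = so,
       sharpness_avg = mean(c(si, so), na.rm = TRUE),
       profiles = profiles)
}
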