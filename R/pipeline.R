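# Orchestration of the synthetic study: a cohort of phantoms is acquired
# with both protocol arms (fully sampled reference vs Poisson-disc
# undersampled + CS reconstruction), measured, and compared with the
# agreement statistics, mirroring a surveillance method-comparison design.

#' Experiment configuration
#'
#' @param n_phantoms cohort size (default 20).
#' @param diameter_range_cm range of maximal outer diameters sampled
#'   uniformly across the cohort (default 3-5.5, the surveillance range).
#' @param ilt_types thrombus types cycled across the cohort.
#' @param noise_sd per-component k-space noise SD (default 0.03).
#' @param target_accel acceleration factor of the CS arm (default 5);
#'   1 makes both arms fully sampled.
#' @param calib_fraction calibration-region fraction (default 0.04).
#' @param grid_shape,voxel_size,n_coils phantom grid (default 48 x 64 x 64
#'   at 1.3 mm, a cropped field of view around the aorta) and coil count.
#' @param recon a [recon_config()].
#' @param seed master seed; per-phantom seeds are derived from it.
#' @param outdir optional output directory for intermediates (NIfTI
#'   volumes, mask text files, CSV tables, JSON report).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_phantoms = 20L,
                              diameter_range_cm = c(3, 5.5),
                              ilt_types = 1:4, noise_sd = 0.03,
                              target_accel = 5, calib_fraction = 0.04,
                              grid_shape = c(48L, 64L, 64L),
                              voxel_size = 1.3, n_coils = 4L,
                              recon = recon_config(), seed = 1L,
                              outdir = NULL) {
  stopifnot(n_phantoms >= 1, target_accel >= 1,
            all(ilt_types %in% 1:4), length(diameter_range_cm) == 2)
  structure(list(n_phantoms = as.integer(n_phantoms),
                 diameter_range_cm = diameter_range_cm,
                 ilt_types = as.integer(ilt_types), noise_sd = noise_sd,
                 target_accel = target_accel,
                 calib_fraction = calib_fraction,
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, n_coils = as.integer(n_coils),
                 recon = recon, seed = as.integer(seed), outdir = outdir),
            class = "experiment_config")
}

log_stage <- function(phantom, stage, status, detail = "") {
  message(sprintf("phantom=%s stage=%s status=%s%s", format(phantom), stage,
                  status, if (nzchar(detail)) paste0(" ", detail) else ""))
}

# acquire + reconstruct + measure one phantom with both arms
process_phantom <- function(ph, config, seeds) {
  n <- dim(ph$intensity)
  maps_true <- coil_sensitivities(n, config$n_coils, seed = seeds[["coil"]])
  muscle <- erode_mask(ph$labels == .tissue_levels[["muscle"]])

  fm <- full_mask(n[2], n[3], config$calib_fraction)
  acq_ref <- simulate_acquisition(ph, maps_true, fm,
                                  noise_sd = config$noise_sd,
                                  seed = seeds[["ref_noise"]])
  img_ref <- reconstruct_reference(acq_ref, estimate_sensitivities(acq_ref))
  meas_ref <- measure_volume(img_ref, config$voxel_size, muscle)

  if (config$target_accel == 1) {
    mask <- fm
    acq_cs <- simulate_acquisition(ph, maps_true, mask,
                                   noise_sd = config$noise_sd,
                                   seed = seeds[["cs_noise"]])
    img_cs <- reconstruct_reference(acq_cs, estimate_sensitivities(acq_cs))
  } else {
    mask <- poisson_disc_mask(n[2], n[3], config$target_accel,
                              config$calib_fraction, seed = seeds[["mask"]])
    acq_cs <- simulate_acquisition(ph, maps_true, mask,
                                   noise_sd = config$noise_sd,
                                   seed = seeds[["cs_noise"]])
    rec <- reconstruct_cs(acq_cs, estimate_sensitivities(acq_cs), config$recon)
    img_cs <- Mod(rec$image)
  }
  meas_cs <- measure_volume(img_cs, config$voxel_size, muscle)
  list(reference = meas_ref, cs = meas_cs, mask = mask,
       img_ref = img_ref, img_cs = img_cs)
}

measures_row <- function(id, arm, m, truth) {
  data.frame(phantom = id, arm = arm,
             max_diameter_cm = m$max_diameter_cm,
             lumen_area_cm2 = m$lumen_area_cm2,
             ilt_wall_area_cm2 = m$ilt_wall_area_cm2,
             ilt_muscle_ratio = m$ilt_muscle_ratio,
             ilt_lumen_contrast_ratio = m$ilt_lumen_contrast_ratio,
             ilt_type = m$ilt_type,
             sharpness_inner = m$sharpness_inner,
             sharpness_outer = m$sharpness_outer,
             sharpness_avg = m$sharpness_avg,
             truth_diameter_cm = truth$max_outer_diameter_cm,
             truth_ilt_type = truth$ilt_type)
}

#' Run the full synthetic study
#'
#' Builds the cohort, acquires and reconstructs both arms per phantom,
#' measures every volume, and tabulates per-metric agreement between the
#' arms (Bland-Altman, ICC, CV) plus Cohen's kappa for the thrombus types.
#' A failing phantom is flagged and excluded; the run aborts if more than
#' half fail. Deterministic under a fixed master seed.
#'
#' @param config an [experiment_config()].
#' @return A `study_report`: `measures` (one row per phantom and arm),
#'   `agreement` (one row per metric), `ilt_kappa`, `failed`, `config`,
#'   `seeds`, `version`.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  n <- config$n_phantoms
  seed_mat <- matrix(derive_seeds(config$seed, 5L * n), ncol = 5L)
  colnames(seed_mat) <- c("phantom", "coil", "mask", "ref_noise", "cs_noise")
  set.seed(derive_seeds(config$seed + 1L, 1L))
  diam <- runif(n, config$diameter_range_cm[1], config$diameter_range_cm[2])
  types <- rep_len(config$ilt_types, n)

  rows <- list(); masks <- list(); failed <- integer(0)
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(n)) {
    res <- tryCatch({
      spec <- aaa_phantom_spec(outer_diameter_cm = diam[i], ilt_type = types[i],
                               grid_shape = config$grid_shape,
                               voxel_size = config$voxel_size,
                               noise_sd = config$noise_sd,
                               seed = seed_mat[i, "phantom"])
      ph <- build_phantom(spec)
      log_stage(i, "phantom", "ok", sprintf("D=%.2fcm type=%d", diam[i], types[i]))
      out <- process_phantom(ph, config, seed_mat[i, ])
      log_stage(i, "measure", "ok")
      if (!is.null(outdir)) {
        write_phantom(ph, file.path(outdir, sprintf("phantom_%02d", i)))
        write_mask(out$mask, file.path(outdir, sprintf("mask_%02d.txt", i)))
        write_nifti_volume(out$img_ref, file.path(outdir, sprintf("recon_ref_%02d.nii", i)),
                           config$voxel_size)
        write_nifti_volume(out$img_cs, file.path(outdir, sprintf("recon_cs_%02d.nii", i)),
                           config$voxel_size)
      }
      rbind(measures_row(i, "reference", out$reference, ph$truth),
            measures_row(i, "cs", out$cs, ph$truth))
    }, error = function(e) {
      log_stage(i, "pipeline", "failed", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, i) else rows[[length(rows) + 1L]] <- res
  }
  if (length(failed) > n / 2) {
    stop(sprintf("more than half of the cohort failed (%d of %d)", length(failed), n))
  }
  measures <- do.call(rbind, rows)

  metrics <- c("max_diameter_cm", "lumen_area_cm2", "ilt_wall_area_cm2",
               "ilt_muscle_ratio", "ilt_lumen_contrast_ratio", "sharpness_avg")
  ref <- measures[measures$arm == "reference", ]
  cs <- measures[measures$arm == "cs", ]
  agr <- lapply(metrics, function(mt) {
    a <- ref[[mt]]; b <- cs[[mt]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) {
      return(data.frame(metric = mt, n = sum(ok), bias = NA_real_,
                        loa_low = NA_real_, loa_high = NA_real_,
                        icc = NA_real_, cv_percent = NA_real_))
    }
    r <- agreement_report(a[ok], b[ok])
    data.frame(metric = mt, n = r$n, bias = r$bias, loa_low = r$loa_low,
               loa_high = r$loa_high, icc = r$icc, cv_percent = r$cv_percent)
  })
  agreement <- do.call(rbind, agr)
  kap <- tryCatch(cohen_kappa(ref$ilt_type, cs$ilt_type), error = function(e) NA_real_)

  report <- structure(list(measures = measures, agreement = agreement,
                           ilt_kappa = kap, failed = failed,
                           config = config, seeds = seed_mat,
                           version = as.character(utils::packageVersion("csaaa"))),
                      class = "study_report")
  if (!is.null(outdir)) {
    write.csv(measures, file.path(outdir, "measures.csv"), row.names = FALSE)
    write.csv(agreement, file.path(outdir, "agreement.csv"), row.names = FALSE)
    jsonlite::write_json(list(agreement = agreement, ilt_kappa = kap,
                              failed = failed, version = report$version),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d phantoms (%d failed); ILT kappa %.2f\n",
              x$config$n_phantoms, length(x$failed), x$ilt_kappa))
  print(x$agreement, row.names = FALSE)
  invisible(x)
}

#' Reconstruction-parameter sweep over a small phantom set
#'
#' Runs [sweep_recon_params()] on acquisitions of several phantoms and
#' aggregates the NRMSE per (lambda, iterations) cell as mean and SD.
#'
#' @param config an [experiment_config()]; its first `n_phantoms` cohort
#'   members (at the CS acceleration) are used.
#' @param n_phantoms number of phantoms to aggregate over (default 3).
#' @param lambdas,iteration_counts the sweep grid (defaults: the protocol
#'   sweep).
#' @return Data frame `lambda`, `iterations`, `mean_nrmse`, `sd_nrmse`.
#' @export
run_sweep <- function(config = experiment_config(), n_phantoms = 3L,
                      lambdas = c(0.0005, 0.001, 0.002, 0.004),
                      iteration_counts = c(10L, 20L, 40L)) {
  if (n_phantoms < 1) stop("empty phantom set")
  seed_mat <- matrix(derive_seeds(config$seed, 5L * n_phantoms), ncol = 5L)
  colnames(seed_mat) <- c("phantom", "coil", "mask", "ref_noise", "cs_noise")
  set.seed(derive_seeds(config$seed + 1L, 1L))
  diam <- runif(n_phantoms, config$diameter_range_cm[1], config$diameter_range_cm[2])
  types <- rep_len(config$ilt_types, n_phantoms)
  tabs <- lapply(seq_len(n_phantoms), function(i) {
    spec <- aaa_phantom_spec(outer_diameter_cm = diam[i], ilt_type = types[i],
                             grid_shape = config$grid_shape,
                             voxel_size = config$voxel_size,
                             noise_sd = config$noise_sd,
                             seed = seed_mat[i, "phantom"])
    ph <- build_phantom(spec)
    n <- dim(ph$intensity)
    maps <- coil_sensitivities(n, config$n_coils, seed = seed_mat[i, "coil"])
    mask <- poisson_disc_mask(n[2], n[3], config$target_accel,
                              config$calib_fraction, seed = seed_mat[i, "mask"])
    acq <- simulate_acquisition(ph, maps, mask, noise_sd = config$noise_sd,
                                seed = seed_mat[i, "cs_noise"])
    sweep_recon_params(acq, estimate_sensitivities(acq), ph$intensity,
                       lambdas, iteration_counts, config$recon)
  })
  all <- do.call(rbind, tabs)
  agg <- aggregate(nrmse ~ lambda + iterations, all,
                   function(v) c(mean = mean(v), sd = sd(v)))
  data.frame(lambda = agg$lambda, iterations = agg$iterations,
             mean_nrmse = agg$nrmse[, "mean"], sd_nrmse = agg$nrmse[, "sd"])
}

#' Longitudinal growth-rate simulation
#'
#' Simulates subjects whose maximal diameter grows linearly at a
#' subject-specific true rate drawn around `true_growth`, images each time
#' point with both arms, measures the diameters, and recovers the endpoint
#' growth rates per arm. Reports per-subject recovery errors and the
#' CS-vs-reference agreement of the growth rates.
#'
#' @param config an [experiment_config()] (noise, grid, recon, seed).
#' @param n_subjects number of simulated subjects (default 9).
#' @param n_timepoints time points per subject (default 2, >= 2).
#' @param true_growth mean true growth rate in mm/year (default 3.3).
#' @param growth_sd between-subject SD of the true rate in mm/year
#'   (default 3.1).
#' @param interval_days spacing between time points (default 365).
#' @param baseline_range_cm range of baseline diameters (default 3.5-5).
#' @return A list: `table` (per subject: true and recovered rates per arm
#'   and their errors), `icc_growth` (CS vs reference), `dates`.
#' @export
longitudinal_series <- function(config = experiment_config(),
                                n_subjects = 9L, n_timepoints = 2L,
                                true_growth = 3.3, growth_sd = 3.1,
                                interval_days = 365,
                                baseline_range_cm = c(3.5, 5)) {
  if (n_timepoints < 2) stop("need at least 2 time points")
  seed_mat <- matrix(derive_seeds(config$seed, n_subjects * (2L + 4L * n_timepoints)),
                     nrow = n_subjects)
  set.seed(derive_seeds(config$seed + 2L, 1L))
  d0 <- runif(n_subjects, baseline_range_cm[1], baseline_range_cm[2])
  g <- rnorm(n_subjects, true_growth, growth_sd)
  dates <- as.Date("2020-01-01") + (seq_len(n_timepoints) - 1L) * interval_days
  years <- as.numeric(dates - dates[1]) / 365.25
  # keep every diameter inside the feasible phantom range
  for (i in seq_len(n_subjects)) {
    dmax <- d0[i] + g[i] * max(years) / 10
    if (dmax > 5.4) g[i] <- (5.4 - d0[i]) * 10 / max(years)
    if (dmax < 3.0) g[i] <- (3.0 - d0[i]) * 10 / max(years)
  }
  types <- rep_len(config$ilt_types, n_subjects)

  rows <- lapply(seq_len(n_subjects), function(i) {
    d_ref <- numeric(n_timepoints); d_cs <- numeric(n_timepoints)
    for (j in seq_len(n_timepoints)) {
      s0 <- 2L + (j - 1L) * 4L
      seeds <- c(phantom = seed_mat[i, s0 + 1L], coil = seed_mat[i, 1L],
                 mask = seed_mat[i, s0 + 2L], ref_noise = seed_mat[i, s0 + 3L],
                 cs_noise = seed_mat[i, s0 + 4L])
      d_true <- d0[i] + g[i] * years[j] / 10
      spec <- aaa_phantom_spec(outer_diameter_cm = d_true, ilt_type = types[i],
                               grid_shape = config$grid_shape,
                               voxel_size = config$voxel_size,
                               noise_sd = config$noise_sd,
                               seed = seeds[["phantom"]])
      ph <- build_phantom(spec)
      out <- process_phantom(ph, config, seeds)
      d_ref[j] <- out$reference$max_diameter_cm
      d_cs[j] <- out$cs$max_diameter_cm
      log_stage(sprintf("%d.%d", i, j), "longitudinal", "ok",
                sprintf("Dtrue=%.2f ref=%.2f cs=%.2f", d_true, d_ref[j], d_cs[j]))
    }
    data.frame(subject = i, true_growth = g[i],
               growth_ref = growth_rate(d_ref, dates),
               growth_cs = growth_rate(d_cs, dates))
  })
  tab <- do.call(rbind, rows)
  tab$err_ref <- tab$growth_ref - tab$true_growth
  tab$err_cs <- tab$growth_cs - tab$true_growth
  list(table = tab,
       icc_growth = if (n_subjects >= 3) icc(tab$growth_cs, tab$growth_ref) else NA_real_,
       dates = dates)
}
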