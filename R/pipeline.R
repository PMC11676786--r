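#' Default run configuration
#'
#' Nested list of every module's parameters with the acquisition defaults of
#' the full-scale system: 32x32 elements at 0.3 mm pitch and 3.6 MHz, five
#' diverging-wave transmits at PRF 4200 Hz (840 volumes/s compounded), a 90
#' degree sector at one line per degree with 32.1 um axial sampling, 4.9 mm /
#' 90% overlap RF tracking, and 200 sampled voxels for activation mapping.
#'
#' @return Named nested list; see [read_config()] for YAML overrides.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    acquisition = list(
      probe = list(n_x = 32L, n_y = 32L, pitch = 0.3e-3,
                   center_frequency = 3.6e6),
      scheme = list(config_name = "fullaperture_steered",
                    source_depth = 10e-3, subaperture_source_depth = 4.8e-3,
                    steer_deg = 16, prf = 4200),
      medium = list(speed_of_sound = 1540, attenuation = 0),
      pulse = list(fractional_bandwidth = 0.6),
      fs = 14.4e6
    ),
    grid = list(depth_min = 10e-3, depth_max = 110e-3, axial_step = 32.1e-6,
                sector_deg = 90, lines_per_degree = 1),
    phantom = list(
      density = 1, reflectivity_sd = 1,
      shells = list(
        list(label = 4L, center = c(0, 0, 50e-3),
             semi_axes = c(30e-3, 30e-3, 30e-3), wall = 10e-3),
        list(label = 1L, center = c(0, 0, 98e-3),
             semi_axes = c(22e-3, 22e-3, 16e-3), wall = 8e-3))
    ),
    activation_truth = list(
      p_onset = 8e-3, av_delay = 80e-3, v_vent = 1.5, v_atrial = 1.0,
      tau = 60e-3, s_es_vent = -0.15, s_es_atrial = 0.25,
      atrial_stretch_delay = 10e-3, atrial_tau = 60e-3,
      vent_origin = NULL, atrial_origin = NULL
    ),
    simulator = list(n_volumes = 160L, frozen = FALSE, noise_snr_db = Inf,
                     spreading = FALSE),
    tracking = list(window_length = 4.9e-3, overlap = 0.90, max_lag = 1.0e-3,
                    subsample = "cosine", min_correlation = 0.5),
    strain = list(sg_window = 3.2e-3, lagrangian = FALSE),
    activation = list(n_sample_voxels = 200L, ventricular_window = 0.250,
                      fallback_drop_factor = 4.0, crossing_significance = 4.0,
                      confirm_samples = 8L),
    chamber = list(manual_systole = NULL)
  )
}

#' Scaled-down validation-study configuration
#'
#' The desk-scale study conditions used by the package's recovery tests:
#' an 8x8 aperture at 0.9 mm pitch (7.2 mm aperture, ~3 mm lateral resolution
#' at 50 mm, grating lobes outside the sector for every in-sector scatterer),
#' a 20 degree sector at one line per degree with the
#' axial grid at the native RF sampling c/(2 fs), a two-chamber thick-walled
#' phantom whose walls accommodate the 4.9 mm tracking window, a ventricular
#' conduction velocity of 1 m/s and 160 volumes at 840 volumes/s. All
#' processing parameters keep their full-scale defaults.
#'
#' @param seed integer seed for phantom sampling and voxel selection.
#' @export
validation_config <- function(seed = 1L) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$acquisition$probe$n_x <- 8L
  cfg$acquisition$probe$n_y <- 8L
  cfg$acquisition$probe$pitch <- 0.9e-3
  cfg$acquisition$scheme$steer_deg <- 8
  fs <- cfg$acquisition$fs
  c0 <- cfg$acquisition$medium$speed_of_sound
  cfg$grid <- list(depth_min = 24e-3, depth_max = 72e-3,
                   axial_step = c0 / (2 * fs), sector_deg = 20,
                   lines_per_degree = 1)
  cfg$phantom$shells <- list(
    list(label = 4L, center = c(0, 0, 40e-3),
         semi_axes = c(7e-3, 7e-3, 13e-3), wall = 5.5e-3),
    list(label = 1L, center = c(0, 0, 61e-3),
         semi_axes = c(6.2e-3, 6.2e-3, 7.5e-3), wall = 5e-3))
  cfg$activation_truth$v_vent <- 1.0
  cfg$simulator$n_volumes <- 160L
  cfg
}

#' Minimal smoke-test configuration
#'
#' A seconds-scale end-to-end setup (4x4 elements, 10 degree sector, 3 x 3
#' lines, 45 volumes, compressed timing) used for determinism and interface
#' tests; too small for quantitative recovery.
#'
#' @param seed integer seed.
#' @export
tiny_config <- function(seed = 1L) {
  cfg <- default_config()
  cfg$seed <- as.integer(seed)
  cfg$acquisition$probe$n_x <- 4L
  cfg$acquisition$probe$n_y <- 4L
  cfg$acquisition$probe$pitch <- 1.2e-3
  cfg$acquisition$scheme$steer_deg <- 5
  fs <- cfg$acquisition$fs
  c0 <- cfg$acquisition$medium$speed_of_sound
  cfg$grid <- list(depth_min = 15e-3, depth_max = 35e-3,
                   axial_step = c0 / (2 * fs), sector_deg = 10,
                   lines_per_degree = 0.2)
  cfg$phantom$density <- 0.5
  cfg$phantom$shells <- list(
    list(label = 4L, center = c(0, 0, 25e-3),
         semi_axes = c(2.5e-3, 2.5e-3, 4e-3), wall = 2.5e-3),
    list(label = 1L, center = c(0, 0, 31.5e-3),
         semi_axes = c(2e-3, 2e-3, 1.5e-3), wall = 1.5e-3))
  cfg$activation_truth$p_onset <- 5e-3
  cfg$activation_truth$av_delay <- 20e-3
  cfg$activation_truth$v_vent <- 1.0
  cfg$activation_truth$tau <- 10e-3
  cfg$activation_truth$atrial_stretch_delay <- 5e-3
  cfg$activation_truth$atrial_tau <- 10e-3
  cfg$simulator$n_volumes <- 45L
  cfg$activation$n_sample_voxels <- 30L
  cfg$chamber$manual_systole <- c(21L, 38L)
  cfg
}

config_objects <- function(cfg) {
  pr <- cfg$acquisition$probe
  probe <- matrix_probe(pr$n_x, pr$n_y, pr$pitch, pr$center_frequency)
  medium <- do.call(medium_model, cfg$acquisition$medium)
  sc <- cfg$acquisition$scheme
  scheme <- if (identical(sc$config_name, "subaperture_unsteered"))
    make_subaperture_scheme(probe, sc$subaperture_source_depth, sc$prf)
  else
    make_steered_scheme(probe, sc$source_depth,
                        default_steer_angles() / 16 * sc$steer_deg, sc$prf)
  grid <- do.call(scan_grid, cfg$grid)
  pulse <- pulse_model(pr$center_frequency,
                       cfg$acquisition$pulse$fractional_bandwidth)
  list(probe = probe, medium = medium, scheme = scheme, grid = grid,
       pulse = pulse, fs = cfg$acquisition$fs)
}

config_phantom <- function(cfg, grid) {
  shells <- lapply(cfg$phantom$shells, function(s)
    chamber_shell(s$label, s$center, s$semi_axes, s$wall))
  spec <- phantom_spec(shells, cfg$phantom$density,
                       cfg$phantom$reflectivity_sd, cfg$seed)
  ph <- build_phantom(spec, grid)
  at <- cfg$activation_truth
  vent <- Filter(function(s) !is_atrial_label(s$label), shells)
  atr <- Filter(function(s) is_atrial_label(s$label), shells)
  vo <- at$vent_origin %||%
    c(vent[[1]]$center[1:2], vent[[1]]$center[3] - vent[[1]]$semi_axes[3])
  ao <- at$atrial_origin %||% if (length(atr))
    c(atr[[1]]$center[1:2], atr[[1]]$center[3] + atr[[1]]$semi_axes[3]) else NULL
  truth <- activation_model(vo, ao, at$v_vent, at$v_atrial, at$p_onset,
                            at$av_delay, at$tau, at$s_es_vent, at$s_es_atrial,
                            at$atrial_stretch_delay, at$atrial_tau)
  ph$cloud <- prepare_motion(ph$cloud, truth, spec)
  ph$truth <- truth
  ph
}

#' Run the full single-heartbeat pipeline on the synthetic phantom
#'
#' Simulates a diverging-wave acquisition of the contracting phantom
#' (streaming volume by volume), beamforms with coherent compounding, tracks
#' inter-volume axial displacement, estimates inter-volume and end-systolic
#' strain, selects the systolic interval, maps electromechanical activation
#' and computes chamber GLS.
#'
#' @param cfg a configuration list ([default_config()],
#'   [validation_config()], [tiny_config()] or [read_config()]).
#' @param verbose print progress.
#' @param keep_volumes keep the beamformed volumes in the result (memory!).
#' @return An `ewi_result` list: displacement/strain series, activation map
#'   and stats, GLS, systole interval, lattice mask and coordinates, phantom
#'   truth, markers, config, and a JSON-ready `results` summary.
#' @export
run_pipeline <- function(cfg = validation_config(), verbose = FALSE,
                         keep_volumes = FALSE) {
  set.seed(cfg$seed)
  obj <- config_objects(cfg)
  ph <- config_phantom(cfg, obj$grid)
  truth <- ph$truth
  rate <- effective_volume_rate(obj$scheme)
  n_vol <- cfg$simulator$n_volumes
  n_src <- length(obj$scheme$sources)
  prf <- obj$scheme$prf
  tcfg <- do.call(tracking_config, cfg$tracking)
  scfg <- strain_config(cfg$strain$sg_window)
  acfg <- activation_config(cfg$activation$n_sample_voxels, cfg$seed + 1L,
                            cfg$activation$ventricular_window,
                            cfg$activation$fallback_drop_factor,
                            cfg$activation$crossing_significance,
                            cfg$activation$confirm_samples)

  # ECG with an end-systole estimate from the prescribed law
  vent_sc <- ph$cloud$region == 2L
  t_plateau <- if (any(vent_sc))
    max(electrical_onset(ph$cloud$positions[vent_sc, , drop = FALSE],
                         rep(2L, sum(vent_sc)), truth)) + truth$tau
  else truth$q_onset + truth$tau
  # the ECG may outlast the imaging window (it normally does)
  duration <- max(n_vol * n_src / prf, t_plateau + 50e-3)
  ecg <- synthetic_ecg(truth$p_onset, truth$q_onset, t_plateau, duration)

  n_t <- required_samples(obj$grid, obj$probe, obj$scheme, obj$medium,
                          obj$fs, obj$pulse)
  s_mins <- vapply(obj$scheme$sources, source_min_distance, 0, probe = obj$probe)
  epos <- element_positions(obj$probe)
  co <- grid_coordinates(obj$grid)
  gdim <- grid_dims(obj$grid)
  ts <- tracking_samples(obj$grid, tcfg)
  n_w <- length(ts$starts)
  d4 <- array(NA_real_, c(n_w, gdim[2], gdim[3], n_vol - 1L))
  q4 <- array(NA_real_, dim(d4)); v4 <- array(FALSE, dim(d4))
  prev <- NULL
  vols <- if (keep_volumes) vector("list", n_vol) else NULL
  # before the earliest mechanical onset nothing moves: with noise-free
  # channels those volumes are bit-identical, so compute the first one only
  t_first_motion <- if (length(ph$cloud$motion$onset))
    min(ph$cloud$motion$onset) else Inf
  static_ok <- !is.finite(cfg$simulator$noise_snr_db)
  static_track <- NULL
  for (k in seq_len(n_vol)) {
    if (static_ok && k > 1L &&
        (k * n_src - 1) / prf < t_first_motion) {
      bf <- prev
      if (keep_volumes) vols[[k]] <- new_volume(bf, obj$grid, k, TRUE)
      if (is.null(static_track))
        static_track <- cpp_track(matrix(prev, gdim[1]), matrix(bf, gdim[1]),
                                  as.integer(ts$starts - 1L), ts$wlen,
                                  ts$max_lag, subsample_code(tcfg))
      res <- static_track
      p <- k - 1L
      dims3 <- c(n_w, gdim[2], gdim[3])
      d4[, , , p] <- array(-res$lag * obj$grid$axial_step, dims3)
      q4[, , , p] <- array(res$peak, dims3)
      v4[, , , p] <- array(res$flag == 0L & res$peak >= tcfg$min_correlation,
                           dims3)
      next
    }
    bf <- array(0, gdim)
    for (j in seq_len(n_src)) {
      t_tx <- if (cfg$simulator$frozen) (k - 1) * n_src / prf
              else ((k - 1) * n_src + (j - 1)) / prf
      cl <- displace(ph$cloud, t_tx)
      rf <- if (length(cl$reflectivity))
        cpp_simulate_rf(cl$positions, cl$reflectivity, epos,
                        obj$scheme$sources[[j]]$position, s_mins[j],
                        obj$medium$speed_of_sound, obj$fs, n_t,
                        obj$pulse$center_frequency, pulse_sigma_t(obj$pulse),
                        cfg$simulator$spreading)
      else matrix(0, n_t, nrow(epos))
      if (is.finite(cfg$simulator$noise_snr_db)) {
        sigma <- sqrt(mean(rf^2)) * 10^(-cfg$simulator$noise_snr_db / 20)
        rf <- rf + matrix(rnorm(length(rf), 0, sigma), nrow(rf))
      }
      bf <- bf + array(cpp_das(rf, epos, obj$scheme$sources[[j]]$position,
                               s_mins[j], obj$medium$speed_of_sound, obj$fs,
                               as.vector(co$x), as.vector(co$y),
                               as.vector(co$z)), gdim)
    }
    if (keep_volumes) vols[[k]] <- new_volume(bf, obj$grid, k, TRUE)
    if (!is.null(prev)) {
      res <- cpp_track(matrix(prev, gdim[1]), matrix(bf, gdim[1]),
                       as.integer(ts$starts - 1L), ts$wlen, ts$max_lag,
                       subsample_code(tcfg))
      p <- k - 1L
      dims3 <- c(n_w, gdim[2], gdim[3])
      d4[, , , p] <- array(-res$lag * obj$grid$axial_step, dims3)
      q4[, , , p] <- array(res$peak, dims3)
      v4[, , , p] <- array(res$flag == 0L & res$peak >= tcfg$min_correlation,
                           dims3)
    }
    prev <- bf
    if (verbose && k %% 20 == 0) message("volume ", k, "/", n_vol)
  }
  times <- ((seq_len(n_vol - 1L) - 1L) * n_src + n_src / 2 + 2) / prf
  dser <- new_displacement_series(d4, q4, v4, ts$centers, obj$grid, tcfg,
                                  times, rate)
  sser <- inter_volume_strain(dser, scfg)
  mask_w <- window_mask(ph$mask, obj$grid, ts$centers)
  coords_w <- grid_coordinates(obj$grid, ts$centers)
  junction_w <- if (!is.null(ph$junction))
    window_junction(ph$junction, obj$grid, ts$centers) else NULL

  systole <- select_systole(dser, mask_w, ecg$markers,
                            manual = cfg$chamber$manual_systole)
  cum <- accumulate_displacement(dser, systole$k_start, systole$k_end,
                                 lagrangian = isTRUE(cfg$strain$lagrangian))
  es <- end_systolic_strain(cum, scfg)
  gls <- chamber_gls(es, mask_w)
  map <- withCallingHandlers(
    map_activation(sser, mask_w, coords_w, ecg$markers, acfg),
    warning = function(w) invokeRestart("muffleWarning"))
  stats <- suppressWarnings(activation_stats(map, mask_w))

  results <- list(
    package_version = as.character(utils::packageVersion("ewi3d")),
    seed = cfg$seed,
    volume_rate_hz = rate,
    n_volumes = n_vol,
    systole = systole,
    agls_percent = gls$agls,
    vgls_percent = gls$vgls,
    chamber_gls = gls$chambers,
    activation_stats = stats,
    n_detections = nrow(map$detections),
    markers = ecg$markers
  )
  structure(list(dser = dser, sser = sser, cum = cum, es = es, gls = gls,
                 map = map, stats = stats, systole = systole,
                 mask_w = mask_w, coords_w = coords_w, junction_w = junction_w,
                 phantom = ph, truth = truth, ecg = ecg, grid = obj$grid,
                 volumes = vols, config = cfg, results = results),
            class = "ewi_result")
}

#' @export
print.ewi_result <- function(x, ...) {
  cat(sprintf("<ewi_result> %d volumes at %g volumes/s; VGLS %.1f%%, AGLS %.1f%%; %d onsets detected\n",
              x$results$n_volumes, x$results$volume_rate_hz,
              x$results$vgls_percent %||% NA, x$results$agls_percent %||% NA,
              x$results$n_detections))
  invisible(x)
}

#' Compare a pipeline result against the phantom ground truth
#'
#' Computes the recovery metrics of the validation study: ventricular
#' isochrone RMSE against the closed-form activation field, the regression
#' slope of detected onset time versus distance from the activation origin
#' (1/velocity for a constant-velocity wave), median onset per distance bin,
#' and the GLS recovery errors against the prescribed plateau strains.
#'
#' @param res an `ewi_result` from [run_pipeline()].
#' @param n_bins distance bins for the monotonicity profile.
#' @return List of metrics.
#' @export
evaluate_against_truth <- function(res, n_bins = 5L) {
  truth <- res$truth
  iso_true <- true_isochrones(truth, res$mask_w, res$grid, res$dser$depths)
  vent <- !is_atrial_label(res$mask_w) & res$mask_w != 0L
  sel <- vent & !is.na(res$map$t_ms)
  err_ms <- res$map$t_ms[sel] - (iso_true[sel] - truth$q_onset) * 1e3
  rmse_ms <- sqrt(mean(err_ms^2))

  det <- res$map$detections
  dv <- det[!det$atrial, , drop = FALSE]
  slope <- NA_real_; med_by_bin <- NULL
  if (nrow(dv) >= 3L) {
    dist <- sqrt((dv$x - truth$vent_origin[1])^2 +
                 (dv$y - truth$vent_origin[2])^2 +
                 (dv$z - truth$vent_origin[3])^2)
    t_rel <- dv$t_act - truth$q_onset
    slope <- unname(coef(lm(t_rel ~ dist))[2])
    bins <- cut(dist, breaks = quantile(dist, probs = seq(0, 1, length.out = n_bins + 1)),
                include.lowest = TRUE)
    med_by_bin <- tapply(t_rel, bins, median)
  }
  list(isochrone_rmse_ms = rmse_ms,
       n_compared = sum(sel),
       onset_distance_slope_s_per_m = slope,
       true_inverse_velocity_s_per_m = 1 / truth$v_vent,
       median_onset_by_distance_bin_s = med_by_bin,
       vgls_error_points = res$gls$vgls - 100 * truth$s_es_vent,
       agls_error_points = res$gls$agls - 100 * truth$s_es_atrial)
}
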