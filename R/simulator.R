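#' Transmit pulse model
#'
#' Gaussian-enveloped cosine pulse. The envelope standard deviation follows
#' from the -6 dB fractional bandwidth of the Gaussian spectrum:
#' sigma_t = sqrt(2 log 2) / (pi * bw * f0).
#'
#' @param center_frequency pulse center frequency (Hz).
#' @param fractional_bandwidth -6 dB fractional bandwidth (0 < bw < 2).
#' @export
pulse_model <- function(center_frequency = 3.6e6, fractional_bandwidth = 0.6) {
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("fractional bandwidth must be in (0, 2)")
  structure(list(center_frequency = center_frequency,
                 fractional_bandwidth = fractional_bandwidth),
            class = "ewi_pulse")
}

pulse_sigma_t <- function(pulse) {
  sqrt(2 * log(2)) / (pi * pulse$fractional_bandwidth * pulse$center_frequency)
}

#' Minimum sampling frequency for a pulse
#'
#' Twice the upper -6 dB band edge, f0 * (1 + bw / 2).
#' @param pulse a [pulse_model()].
#' @export
min_sampling_frequency <- function(pulse) {
  2 * pulse$center_frequency * (1 + pulse$fractional_bandwidth / 2)
}

check_fs <- function(fs, pulse) {
  fmin <- min_sampling_frequency(pulse)
  if (fs <= fmin)
    stop(sprintf("sampling frequency %.4g Hz too low; need > %.4g Hz", fs, fmin))
}

#' Fast-time samples needed to cover a scan grid
#'
#' @param grid an [scan_grid()].
#' @param probe,scheme,medium acquisition geometry.
#' @param fs sampling frequency (Hz).
#' @param pulse a [pulse_model()] (adds the pulse tail).
#' @export
required_samples <- function(grid, probe, scheme, medium, fs,
                             pulse = pulse_model(probe$center_frequency)) {
  pos <- element_positions(probe)
  co <- grid_coordinates(grid)
  n <- length(co$x)
  corners <- cbind(c(co$x[1], co$x[n]), c(co$y[1], co$y[n]), c(co$z[1], co$z[n]))
  far <- rbind(corners, c(0, 0, max(grid$depths)))
  worst <- 0
  for (src in scheme$sources) {
    s_min <- source_min_distance(src, probe)
    for (i in seq_len(nrow(far))) {
      d_tx <- sqrt(sum((far[i, ] - src$position)^2)) - s_min
      d_rx <- max(sqrt(rowSums(sweep(pos, 2, far[i, ])^2)))
      worst <- max(worst, (d_tx + d_rx) / medium$speed_of_sound)
    }
  }
  as.integer(ceiling((worst + 4 * pulse_sigma_t(pulse)) * fs) + 2L)
}

#' Simulate the per-channel RF of one diverging-wave transmit
#'
#' Single-scattering point-target model: each scatterer adds a pulse echo on
#' every receive element at the virtual-source forward delay plus the return
#' path, with amplitude reflectivity (optionally divided by the two-way
#' spreading 1/(r_tx r_rx)).
#'
#' @param cloud an `ewi_cloud` (possibly empty).
#' @param source an `ewi_source`.
#' @param probe,medium acquisition geometry.
#' @param pulse a [pulse_model()].
#' @param fs sampling frequency (Hz); must exceed
#'   [min_sampling_frequency()].
#' @param n_t number of fast-time samples.
#' @param spreading apply 1/(r_tx r_rx) two-way spreading (default FALSE).
#' @return n_t x n_elements RF matrix (receive on all elements).
#' @export
simulate_transmit <- function(cloud, source, probe, medium, pulse, fs, n_t,
                              spreading = FALSE) {
  check_fs(fs, pulse)
  pos <- element_positions(probe)
  if (length(cloud$reflectivity) == 0L)
    return(matrix(0, n_t, nrow(pos)))
  cpp_simulate_rf(cloud$positions, cloud$reflectivity, pos, source$position,
                  source_min_distance(source, probe), medium$speed_of_sound,
                  fs, as.integer(n_t), pulse$center_frequency,
                  pulse_sigma_t(pulse), spreading)
}

new_channel_data <- function(rf, meta) {
  structure(list(rf = rf, meta = meta), class = "ewi_channel_data")
}

#' @export
print.ewi_channel_data <- function(x, ...) {
  d <- dim(x$rf)
  cat(sprintf("<ewi_channel_data> %d samples x %d elements x %d transmits x %d volumes, fs %.3g MHz\n",
              d[1], d[2], d[3], d[4], x$meta$fs / 1e6))
  invisible(x)
}

#' Simulate a multi-volume diverging-wave acquisition
#'
#' Transmits fire at the pulse repetition interval 1/prf; transmit j of volume
#' k (both 1-based) sees the cloud displaced to time (k-1)*n_src/prf +
#' (j-1)/prf, or frozen at the volume start when `frozen = TRUE`.
#'
#' @param cloud an `ewi_cloud`; attach a motion law with [prepare_motion()]
#'   for a moving phantom.
#' @param scheme an `ewi_scheme`.
#' @param probe,medium,pulse acquisition models.
#' @param fs sampling frequency (Hz).
#' @param n_volumes number of compounded volumes (>= 1).
#' @param n_t fast-time samples; defaults to covering `grid` if given.
#' @param grid optional [scan_grid()] used to size `n_t`.
#' @param frozen hold the cloud fixed within each volume.
#' @param noise_snr_db additive white Gaussian channel noise level relative to
#'   the RMS of the noise-free data (Inf = none).
#' @param spreading two-way geometric spreading.
#' @param seed RNG seed for the noise.
#' @return An `ewi_channel_data` with rf dimension
#'   (fast time, element, transmit, volume) and acquisition metadata.
#' @export
simulate_sequence <- function(cloud, scheme, probe, medium, pulse, fs,
                              n_volumes, n_t = NULL, grid = NULL,
                              frozen = FALSE, noise_snr_db = Inf,
                              spreading = FALSE, seed = 1L) {
  if (n_volumes < 1L) stop("n_volumes must be >= 1")
  if (is.null(n_t)) {
    if (is.null(grid)) stop("give n_t or a grid to size the recording")
    n_t <- required_samples(grid, probe, scheme, medium, fs, pulse)
  }
  n_src <- length(scheme$sources)
  ne <- probe$n_x * probe$n_y
  rf <- array(0, c(n_t, ne, n_src, n_volumes))
  for (k in seq_len(n_volumes)) {
    for (j in seq_len(n_src)) {
      t_tx <- if (frozen) (k - 1) * n_src / scheme$prf
              else ((k - 1) * n_src + (j - 1)) / scheme$prf
      rf[, , j, k] <- simulate_transmit(displace(cloud, t_tx),
                                        scheme$sources[[j]], probe, medium,
                                        pulse, fs, n_t, spreading)
    }
  }
  if (is.finite(noise_snr_db)) {
    rms <- sqrt(mean(rf^2))
    sigma <- rms * 10^(-noise_snr_db / 20)
    rf <- rf + with_seed(seed, array(rnorm(length(rf), 0, sigma), dim(rf)))
  }
  meta <- list(probe = probe, scheme = scheme, medium = medium, pulse = pulse,
               fs = fs, n_volumes = n_volumes, frozen = frozen,
               noise_snr_db = noise_snr_db, spreading = spreading,
               t0 = "earliest active element firing")
  new_channel_data(rf, meta)
}
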