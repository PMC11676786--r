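# Shared fixtures: micro acquisition setups, band-limited RF generators and
# independent oracles used across the suite.

micro_probe <- function(n = 4L) matrix_probe(n, n, 1.2e-3)

micro_setup <- function(n_elem = 4L, sector = 20, step = 0.2e-3,
                        depth = c(20e-3, 34e-3), lines_per_degree = 0.25,
                        fs = 14.4e6) {
  probe <- micro_probe(n_elem)
  list(probe = probe,
       medium = medium_model(),
       pulse = pulse_model(),
       scheme = make_steered_scheme(probe, 8e-3, default_steer_angles() / 2),
       grid = scan_grid(depth[1], depth[2], step, sector_deg = sector,
                       lines_per_degree = lines_per_degree),
       fs = fs)
}

point_cloud <- function(positions, reflectivity = NULL) {
  positions <- rbind(positions)
  structure(list(positions = positions,
                 reflectivity = reflectivity %||% rep(1, nrow(positions)),
                 label = rep(4L, nrow(positions)),
                 region = rep(2L, nrow(positions))),
            class = "ewi_cloud")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Band-limited RF: white Gaussian noise shaped to the pulse spectrum, length n
# at sampling rate fs. Deterministic for a given seed.
bandlimited_rf <- function(n, fs = 14.4e6, pulse = pulse_model(), seed = 42) {
  set.seed(seed)
  x <- rnorm(n)
  f <- (seq_len(n) - 1) / n * fs
  f <- ifelse(f > fs / 2, f - fs, f)
  sf <- pulse$center_frequency * pulse$fractional_bandwidth / (2 * sqrt(2 * log(2)))
  H <- exp(-(abs(f) - pulse$center_frequency)^2 / (2 * sf^2))
  Re(fft(fft(x) * H, inverse = TRUE)) / n
}

# Circular subsample shift via a spectral phase ramp (exact for band-limited
# periodic signals).
subsample_shift <- function(x, shift) {
  n <- length(x)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n]
  Re(fft(fft(x) * exp(-2i * pi * k * shift / n), inverse = TRUE)) / n
}

# Independent NCC oracle: evaluates the zero-normalized correlation on a
# finely upsampled lag grid using sinc (spectral) interpolation of the search
# signal.
ncc_oracle_lag <- function(ref, search_full, start, L, max_lag, res = 0.01) {
  lags <- seq(-max_lag, max_lag, by = res)
  r <- ref - mean(ref)
  best <- c(-Inf, NA)
  for (g in lags) {
    s <- subsample_shift(search_full, -g)[start:(start + L - 1)]
    s <- s - mean(s)
    cc <- sum(r * s) / sqrt(sum(r^2) * sum(s^2))
    if (cc > best[1]) best <- c(cc, g)
  }
  best[2]
}

# Naive reference beamformer: a literal five-deep loop over transmits,
# elements and grid nodes with linear fast-time interpolation. Slow by
# design; the oracle for the optimized implementation.
naive_das <- function(chd, k, grid, medium = chd$meta$medium) {
  probe <- chd$meta$probe
  scheme <- chd$meta$scheme
  fs <- chd$meta$fs
  pos <- element_positions(probe)
  co <- grid_coordinates(grid)
  dims <- dim(co$x)
  bf <- array(0, dims)
  c0 <- medium$speed_of_sound
  for (j in seq_along(scheme$sources)) {
    src <- scheme$sources[[j]]
    act <- src$aperture
    s_min <- min(sqrt(rowSums(sweep(pos[act, , drop = FALSE], 2, src$position)^2)))
    rf <- chd$rf[, , j, k]
    n_t <- nrow(rf)
    for (di in seq_len(dims[1])) for (ai in seq_len(dims[2])) for (ei in seq_len(dims[3])) {
      p <- c(co$x[di, ai, ei], co$y[di, ai, ei], co$z[di, ai, ei])
      t_fwd <- (sqrt(sum((p - src$position)^2)) - s_min) / c0
      for (e in seq_len(nrow(pos))) {
        ts <- (t_fwd + sqrt(sum((p - pos[e, ])^2)) / c0) * fs
        i0 <- floor(ts)
        if (i0 >= 0 && i0 < n_t - 1) {
          w <- ts - i0
          bf[di, ai, ei] <- bf[di, ai, ei] +
            (1 - w) * rf[i0 + 1, e] + w * rf[i0 + 2, e]
        }
      }
    }
  }
  bf
}
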