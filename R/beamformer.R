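new_volume <- function(bf, grid, k, compounded, transmit = NA_integer_) {
  structure(list(bf = bf, grid = grid, volume = k, compounded = compounded,
                 transmit = transmit), class = "ewi_volume")
}

#' @export
print.ewi_volume <- function(x, ...) {
  d <- dim(x$bf)
  cat(sprintf("<ewi_volume> %d x %d x %d (%s, volume %s)\n", d[1], d[2], d[3],
              if (x$compounded) "compounded" else paste("transmit", x$transmit),
              x$volume))
  invisible(x)
}

check_grid_reach <- function(chd, grid, medium) {
  n_t <- dim(chd$rf)[1]
  need <- required_samples(grid, chd$meta$probe, chd$meta$scheme, medium,
                          chd$meta$fs, chd$meta$pulse)
  if (need > n_t) {
    reach <- (n_t / chd$meta$fs) * medium$speed_of_sound / 2
    stop(sprintf(
      "grid deeper than the recorded fast-time window (max reachable depth ~ %.1f mm)",
      reach * 1e3))
  }
}

beamform_rf <- function(rf, source, probe, medium, grid, fs) {
  co <- grid_coordinates(grid)
  bf <- cpp_das(rf, element_positions(probe), source$position,
                source_min_distance(source, probe), medium$speed_of_sound, fs,
                as.vector(co$x), as.vector(co$y), as.vector(co$z))
  array(bf, grid_dims(grid))
}

#' Delay-and-sum beamforming with coherent compounding
#'
#' Reconstructs volume `k` on the pyramidal grid: for every grid node the RF
#' trace of each element and each transmit is sampled (linear interpolation in
#' fast time) at the forward delay of the diverging wavefront plus the return
#' delay, and all contributions are summed uniformly (no apodization, no
#' normalization). Out-of-range delays contribute zero.
#'
#' @param chd an `ewi_channel_data`.
#' @param k volume index (1-based).
#' @param grid an [scan_grid()].
#' @param medium a [medium_model()].
#' @return An `ewi_volume` (RF-domain, compounded).
#' @export
das_beamform <- function(chd, k, grid, medium = chd$meta$medium) {
  check_grid_reach(chd, grid, medium)
  scheme <- chd$meta$scheme
  bf <- array(0, grid_dims(grid))
  for (j in seq_along(scheme$sources))
    bf <- bf + beamform_rf(chd$rf[, , j, k], scheme$sources[[j]],
                           chd$meta$probe, medium, grid, chd$meta$fs)
  new_volume(bf, grid, k, TRUE)
}

#' Single-transmit delay-and-sum reconstruction
#'
#' @inheritParams das_beamform
#' @param j transmit index (1-based).
#' @export
das_beamform_single <- function(chd, k, j, grid, medium = chd$meta$medium) {
  scheme <- chd$meta$scheme
  if (j < 1L || j > length(scheme$sources)) stop("transmit index out of range")
  check_grid_reach(chd, grid, medium)
  bf <- beamform_rf(chd$rf[, , j, k], scheme$sources[[j]], chd$meta$probe,
                    medium, grid, chd$meta$fs)
  new_volume(bf, grid, k, FALSE, as.integer(j))
}

# Analytic signal along columns of a matrix (FFT method).
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  mvfft(mvfft(x) * h, inverse = TRUE) / n
}

#' Envelope detection and B-mode rendering
#'
#' Magnitude of the analytic signal along depth, plus a log-compressed image
#' normalized to its maximum.
#'
#' @param volume an `ewi_volume` (RF-domain) or a bare array.
#' @param dynamic_range display dynamic range in dB (default 60).
#' @return List with `envelope` and `bmode_db` arrays.
#' @export
envelope_bmode <- function(volume, dynamic_range = 60) {
  bf <- if (inherits(volume, "ewi_volume")) volume$bf else volume
  d <- dim(bf)
  env <- array(Mod(analytic_signal(matrix(bf, d[1]))), d)
  peak <- max(env)
  db <- 20 * log10(pmax(env / max(peak, .Machine$double.xmin), 1e-30))
  list(envelope = env, bmode_db = pmax(db, -dynamic_range))
}

#' Scan conversion from the pyramidal grid to Cartesian voxels
#'
#' Trilinear interpolation in (depth, azimuth, elevation); voxels outside the
#' sector or depth range are marked invalid (NA).
#'
#' @param volume an `ewi_volume` or an array on `grid`.
#' @param grid the pyramidal [scan_grid()].
#' @param voxel Cartesian voxel size in meters (isotropic).
#' @return List with `volume` (NA outside the sector), axis vectors `x`,
#'   `y`, `z`, and a logical `valid` array.
#' @export
scan_convert <- function(volume, grid, voxel = 1e-3) {
  v <- if (inherits(volume, "ewi_volume")) volume$bf else volume
  rmax <- max(grid$depths); rmin <- min(grid$depths)
  amax <- deg2rad(max(abs(grid$az_deg))); emax <- deg2rad(max(abs(grid$el_deg)))
  xmax <- rmax * sin(amax); ymax <- rmax * sin(emax)
  xs <- seq(-xmax, xmax, by = voxel)
  ys <- seq(-ymax, ymax, by = voxel)
  zs <- seq(rmin * 0.9, rmax, by = voxel)
  gx <- rep(xs, times = length(ys) * length(zs))
  gy <- rep(rep(ys, each = length(xs)), times = length(zs))
  gz <- rep(zs, each = length(xs) * length(ys))
  r <- sqrt(gx^2 + gy^2 + gz^2)
  az <- rad2deg(atan2(gx, gz))
  el <- rad2deg(atan2(gy, gz))
  out <- rep(NA_real_, length(gx))
  ok <- gz > 0 & r >= rmin & r <= rmax &
    az >= min(grid$az_deg) & az <= max(grid$az_deg) &
    el >= min(grid$el_deg) & el <= max(grid$el_deg)
  if (any(ok))
    out[ok] <- trilinear_sample(v, grid, r[ok], az[ok], el[ok])
  dims <- c(length(xs), length(ys), length(zs))
  list(volume = array(out, dims), x = xs, y = ys, z = zs,
       valid = array(ok, dims))
}

# Sample an array on a pyramidal grid at (r, az, el), trilinear.
trilinear_sample <- function(v, grid, r, az, el) {
  fi <- (r - grid$depths[1]) / grid$axial_step + 1
  fa <- approx(grid$az_deg, seq_along(grid$az_deg), az, rule = 2)$y
  fe <- approx(grid$el_deg, seq_along(grid$el_deg), el, rule = 2)$y
  d <- dim(v)
  clamp <- function(i, n) pmin(pmax(i, 1), n)
  i0 <- clamp(floor(fi), d[1] - 1); a0 <- clamp(floor(fa), d[2] - 1)
  e0 <- clamp(floor(fe), d[3] - 1)
  wi <- pmin(pmax(fi - i0, 0), 1); wa <- pmin(pmax(fa - a0, 0), 1)
  we <- pmin(pmax(fe - e0, 0), 1)
  at <- function(i, a, e) v[cbind(i, a, e)]
  (1 - we) * ((1 - wa) * ((1 - wi) * at(i0, a0, e0) + wi * at(i0 + 1, a0, e0)) +
              wa * ((1 - wi) * at(i0, a0 + 1, e0) + wi * at(i0 + 1, a0 + 1, e0))) +
    we * ((1 - wa) * ((1 - wi) * at(i0, a0, e0 + 1) + wi * at(i0 + 1, a0, e0 + 1)) +
          wa * ((1 - wi) * at(i0, a0 + 1, e0 + 1) + wi * at(i0 + 1, a0 + 1, e0 + 1)))
}

#' Peak-to-sidelobe ratio of a point-target envelope
#'
#' Peak over the maximum envelope outside a guard box around the peak.
#'
#' @param env envelope array (depth x az x el).
#' @param guard guard half-widths in cells, `c(depth, az, el)`.
#' @return PSLR in dB.
#' @export
pslr_db <- function(env, guard = c(30L, 3L, 3L)) {
  pk <- which(env == max(env), arr.ind = TRUE)[1, ]
  d <- dim(env)
  side <- env
  side[max(1, pk[1] - guard[1]):min(d[1], pk[1] + guard[1]),
       max(1, pk[2] - guard[2]):min(d[2], pk[2] + guard[2]),
       max(1, pk[3] - guard[3]):min(d[3], pk[3] + guard[3])] <- 0
  20 * log10(max(env) / max(side))
}
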