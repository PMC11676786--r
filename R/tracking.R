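#' Speckle-tracking configuration
#'
#' @param window_length correlation window length in meters (default 4.9 mm).
#' @param overlap window overlap fraction in `[0, 1)` (default 0.90).
#' @param max_lag search range in meters (default 1 mm).
#' @param subsample subsample peak refinement: "cosine" (default; the
#'   standard fit for oscillatory RF correlation, bias < 0.02 samples at
#'   fs = 4 f0), "parabolic" or "none".
#' @param min_correlation quality floor; windows with a lower peak NCC are
#'   marked invalid (default 0.5). Note that the peak of an RF correlation
#'   sampled near 4 samples per carrier period legitimately dips to ~0.65 for
#'   true shifts halfway between samples.
#' @export
tracking_config <- function(window_length = 4.9e-3, overlap = 0.90,
                            max_lag = 1.0e-3,
                            subsample = c("cosine", "parabolic", "none"),
                            min_correlation = 0.5) {
  subsample <- match.arg(subsample)
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  if (max_lag >= window_length) stop("max_lag must be smaller than the window")
  structure(list(window_length = window_length, overlap = overlap,
                 max_lag = max_lag, subsample = subsample,
                 min_correlation = min_correlation),
            class = "ewi_tracking_config")
}

subsample_code <- function(cfg) {
  match(cfg$subsample, c("none", "parabolic", "cosine")) - 1L
}

#' 1-D zero-normalized cross-correlation with subsample refinement
#'
#' Correlates a reference segment against a search segment that is longer by
#' twice the admissible lag; the integer-lag peak is refined by a parabolic
#' (or cosine) fit through the peak and its two neighbours. A peak on the
#' search boundary is not refined and is flagged (flag 2); a zero-variance
#' segment returns quality 0, lag 0, flag 1.
#'
#' @param ref reference segment (length L).
#' @param search search segment (length L + 2 * max_lag samples).
#' @param subsample "cosine" (default), "parabolic" or "none".
#' @return List with `lag` (samples, positive = pattern found deeper in
#'   `search`), `peak` (correlation) and `flag`.
#' @export
ncc_1d <- function(ref, search, subsample = "cosine") {
  L <- length(ref)
  m <- (length(search) - L) / 2
  if (m < 0 || m != floor(m)) stop("search must be longer than ref by an even number of samples")
  m <- as.integer(m)
  r <- ref - mean(ref)
  vr <- sum(r^2)
  if (vr <= 0) return(list(lag = 0, peak = 0, flag = 1L))
  lags <- -m:m
  cc <- vapply(lags, function(g) {
    s <- search[(m + g + 1):(m + g + L)]
    s <- s - mean(s)
    vs <- sum(s^2)
    if (vs <= 0) 0 else sum(r * s) / sqrt(vr * vs)
  }, 0)
  b <- which.max(cc)
  flag <- 0L; sub <- 0
  if (m > 0 && (b == 1L || b == length(lags))) {
    flag <- 2L
  } else if (cc[b] >= 1 - 1e-12) {
    # exact match: subsample refinement would only amplify round-off
  } else if (m > 0 && subsample != "none") {
    cm <- cc[b - 1]; c0 <- cc[b]; cp <- cc[b + 1]
    if (subsample == "parabolic") {
      den <- cm - 2 * c0 + cp
      if (den < 0) sub <- 0.5 * (cm - cp) / den
    } else {
      arg <- (cm + cp) / (2 * c0)
      if (c0 != 0 && abs(arg) < 1) {
        om <- acos(arg)
        if (om > 1e-12) sub <- -atan((cm - cp) / (2 * c0 * sin(om))) / om
      }
    }
  }
  list(lag = lags[b] + sub, peak = cc[b], flag = flag)
}

window_starts <- function(n_d, wlen, hop) {
  seq(1L, n_d - wlen + 1L, by = hop)
}

tracking_samples <- function(grid, cfg) {
  step <- grid$axial_step
  wlen <- max(3L, as.integer(round(cfg$window_length / step)))
  hop <- max(1L, as.integer(round(wlen * (1 - cfg$overlap))))
  mlag <- max(1L, as.integer(round(cfg$max_lag / step)))
  starts <- window_starts(length(grid$depths), wlen, hop)
  list(wlen = wlen, hop = hop, max_lag = mlag, starts = starts,
       centers = grid$depths[1] + (starts - 1 + (wlen - 1) / 2) * step)
}

#' Track inter-volume axial displacement between two beamformed volumes
#'
#' Windows of `window_length` are laid along each (azimuth, elevation) line
#' with hop `window_length * (1 - overlap)`; the zero-normalized NCC lag,
#' refined to subsample precision, is mapped to displacement with the apical
#' sign convention: echoes of tissue moving toward the transducer appear at
#' shallower depth, so displacement = -lag * axial_step (positive = toward
#' the transducer).
#'
#' @param vol0,vol1 `ewi_volume` objects on the same grid (volumes k, k+1).
#' @param cfg a [tracking_config()].
#' @return An `ewi_displacement`: `d` (m), `quality` (peak NCC), `flag`,
#'   `valid`, window-center `depths`, `grid`, `cfg`.
#' @export
track_pair <- function(vol0, vol1, cfg = tracking_config()) {
  g0 <- vol0$grid; g1 <- vol1$grid
  if (!isTRUE(all.equal(g0$depths, g1$depths)) ||
      !isTRUE(all.equal(g0$az_deg, g1$az_deg)) ||
      !isTRUE(all.equal(g0$el_deg, g1$el_deg)))
    stop("volumes do not share a grid")
  ts <- tracking_samples(g0, cfg)
  d <- dim(vol0$bf)
  res <- cpp_track(matrix(vol0$bf, d[1]), matrix(vol1$bf, d[1]),
                   as.integer(ts$starts - 1L), ts$wlen, ts$max_lag,
                   subsample_code(cfg))
  dims <- c(length(ts$starts), d[2], d[3])
  disp <- array(-res$lag * g0$axial_step, dims)
  quality <- array(res$peak, dims)
  flag <- array(res$flag, dims)
  structure(list(d = disp, quality = quality, flag = flag,
                 valid = flag == 0L & quality >= cfg$min_correlation,
                 depths = ts$centers, grid = g0, cfg = cfg),
            class = "ewi_displacement")
}

new_displacement_series <- function(d, quality, valid, depths, grid, cfg,
                                    times, rate) {
  structure(list(d = d, quality = quality, valid = valid, depths = depths,
                 grid = grid, cfg = cfg, times = times, rate = rate),
            class = "ewi_displacement_series")
}

#' Track a whole sequence of beamformed volumes
#'
#' @param volumes list of `ewi_volume` (consecutive).
#' @param cfg a [tracking_config()].
#' @param rate compounded volume rate (Hz), used to time-stamp each
#'   inter-volume field at the midpoint of its volume pair.
#' @return An `ewi_displacement_series` with `d[w, az, el, pair]`.
#' @export
track_sequence <- function(volumes, cfg = tracking_config(), rate = NA_real_) {
  n <- length(volumes)
  if (n < 2L) stop("need at least two volumes")
  first <- track_pair(volumes[[1]], volumes[[2]], cfg)
  dims <- c(dim(first$d), n - 1L)
  d <- array(NA_real_, dims); q <- array(NA_real_, dims)
  v <- array(FALSE, dims)
  d[, , , 1] <- first$d; q[, , , 1] <- first$quality; v[, , , 1] <- first$valid
  if (n > 2L) for (k in 2:(n - 1L)) {
    p <- track_pair(volumes[[k]], volumes[[k + 1L]], cfg)
    d[, , , k] <- p$d; q[, , , k] <- p$quality; v[, , , k] <- p$valid
  }
  times <- if (is.na(rate)) rep(NA_real_, n - 1L) else (seq_len(n - 1L) - 0.5) / rate
  new_displacement_series(d, q, v, first$depths, first$grid, cfg, times, rate)
}

#' Axial displacement M-mode of one scan line
#'
#' @param dser an `ewi_displacement_series`.
#' @param line (azimuth index, elevation index); defaults to the center line.
#' @return Matrix (window depth x volume pair) of displacements (m).
#' @export
displacement_mmode <- function(dser, line = NULL) {
  dims <- dim(dser$d)
  if (is.null(line)) line <- c(ceiling(dims[2] / 2), ceiling(dims[3] / 2))
  matrix(dser$d[, line[1], line[2], ], dims[1], dims[4])
}
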