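#' Matrix-array probe geometry
#'
#' Describes a fully-sampled 2D matrix transducer centered on the origin in the
#' z = 0 plane, z pointing into the body (axial direction). Defaults match a
#' 32x32-element, 0.3 mm pitch, 3.6 MHz cardiac matrix array (1,024 channels).
#'
#' @param n_x,n_y element counts along x and y.
#' @param pitch inter-element spacing in meters.
#' @param center_frequency probe center frequency in Hz.
#' @return An object of class `ewi_probe`.
#' @export
matrix_probe <- function(n_x = 32L, n_y = 32L, pitch = 0.3e-3,
                         center_frequency = 3.6e6) {
  n_x <- as.integer(n_x); n_y <- as.integer(n_y)
  if (n_x < 1L || n_y < 1L) stop("element counts must be positive")
  if (pitch <= 0) stop("pitch must be positive")
  structure(list(n_x = n_x, n_y = n_y, pitch = pitch,
                 center_frequency = center_frequency),
            class = "ewi_probe")
}

#' Element positions of a matrix probe
#'
#' Elements are ordered x-fastest (element index e = ix + n_x * (iy - 1)),
#' positions symmetric about the origin, all at z = 0.
#'
#' @param probe an [matrix_probe()] object.
#' @return A (n_x * n_y) x 3 matrix of positions in meters.
#' @export
element_positions <- function(probe) {
  x <- (seq_len(probe$n_x) - (probe$n_x + 1) / 2) * probe$pitch
  y <- (seq_len(probe$n_y) - (probe$n_y + 1) / 2) * probe$pitch
  cbind(rep(x, times = probe$n_y), rep(y, each = probe$n_x), 0)
}

#' @export
print.ewi_probe <- function(x, ...) {
  cat(sprintf("<ewi_probe> %dx%d elements, pitch %.3g mm, f0 %.3g MHz\n",
              x$n_x, x$n_y, x$pitch * 1e3, x$center_frequency / 1e6))
  invisible(x)
}

#' Propagation medium
#'
#' @param speed_of_sound speed of sound in m/s (default 1540, soft tissue).
#' @param attenuation attenuation in dB/cm/MHz (simulation only; default 0).
#' @export
medium_model <- function(speed_of_sound = 1540, attenuation = 0) {
  if (speed_of_sound <= 0) stop("speed_of_sound must be positive")
  structure(list(speed_of_sound = speed_of_sound, attenuation = attenuation),
            class = "ewi_medium")
}

virtual_source <- function(position, aperture, steer = c(0, 0), label = 1L) {
  position <- as.numeric(position)
  if (length(position) != 3L) stop("source position must be (x, y, z)")
  if (position[3] >= 0) stop("virtual source must lie behind the aperture (z < 0)")
  if (length(aperture) == 0L) stop("active aperture must be non-empty")
  structure(list(position = position, aperture = as.integer(aperture),
                 steer = as.numeric(steer), label = as.integer(label)),
            class = "ewi_source")
}

new_scheme <- function(sources, prf, config_name) {
  structure(list(sources = sources, prf = prf, config_name = config_name),
            class = "ewi_scheme")
}

#' Unsteered sub-aperture diverging-wave transmit scheme
#'
#' Five unsteered virtual sources, one centered behind each quadrant
#' (n_x/2 x n_y/2) sub-aperture of the array and one behind a central
#' sub-aperture, each at depth `source_depth` behind the array plane so the
#' transmitted wavefront diverges.
#'
#' @param probe an [matrix_probe()]; element counts must be even.
#' @param source_depth virtual-source distance behind the array, meters (> 0).
#' @param prf pulse repetition frequency in Hz (default 4200).
#' @return An `ewi_scheme` with 5 sources (quadrants, then center).
#' @export
make_subaperture_scheme <- function(probe, source_depth = 4.8e-3, prf = 4200) {
  if (probe$n_x %% 2L != 0L || probe$n_y %% 2L != 0L)
    stop("quadrant sub-apertures require even element counts")
  if (source_depth <= 0) stop("source_depth must be positive")
  hx <- probe$n_x %/% 2L; hy <- probe$n_y %/% 2L
  pos <- element_positions(probe)
  ix <- rep(seq_len(probe$n_x), times = probe$n_y)
  iy <- rep(seq_len(probe$n_y), each = probe$n_x)
  blocks <- list(
    which(ix <= hx & iy <= hy),
    which(ix > hx & iy <= hy),
    which(ix <= hx & iy > hy),
    which(ix > hx & iy > hy)
  )
  ox <- probe$n_x %/% 4L; oy <- probe$n_y %/% 4L
  blocks[[5]] <- which(ix > ox & ix <= ox + hx & iy > oy & iy <= oy + hy)
  sources <- lapply(seq_along(blocks), function(b) {
    idx <- blocks[[b]]
    ctr <- colMeans(pos[idx, , drop = FALSE])
    virtual_source(c(ctr[1], ctr[2], -source_depth), idx, c(0, 0), b)
  })
  new_scheme(sources, prf, "subaperture_unsteered")
}

#' Default steering angle pairs for the full-aperture scheme
#'
#' The four diagonal pairs at +/-16 degrees in azimuth and elevation plus the
#' unsteered (0, 0) transmit.
#' @return A 5 x 2 matrix of (azimuth, elevation) in degrees.
#' @export
default_steer_angles <- function() {
  rbind(c(16, 16), c(16, -16), c(-16, 16), c(-16, -16), c(0, 0))
}

#' Steered full-aperture diverging-wave transmit scheme
#'
#' Each transmit uses the whole array; the virtual source is placed at
#' (-d tan(az), -d tan(el), -d) so the ray from the source through the array
#' center leaves at the requested steering angle.
#'
#' @param probe an [matrix_probe()].
#' @param source_depth virtual-source depth behind the array, meters.
#' @param angles matrix of (azimuth, elevation) pairs in degrees; defaults to
#'   [default_steer_angles()].
#' @param prf pulse repetition frequency in Hz.
#' @export
make_steered_scheme <- function(probe, source_depth = 10e-3,
                                angles = default_steer_angles(), prf = 4200) {
  if (source_depth <= 0) stop("source_depth must be positive")
  angles <- rbind(angles)
  if (nrow(angles) == 0L) stop("at least one steering angle pair is required")
  if (any(abs(angles) >= 90)) stop("steering angles must satisfy |angle| < 90 degrees")
  all_el <- seq_len(probe$n_x * probe$n_y)
  sources <- lapply(seq_len(nrow(angles)), function(j) {
    az <- angles[j, 1]; el <- angles[j, 2]
    p <- c(-source_depth * tan(deg2rad(az)),
           -source_depth * tan(deg2rad(el)), -source_depth)
    virtual_source(p, all_el, c(az, el), j)
  })
  new_scheme(sources, prf, "fullaperture_steered")
}

#' @export
print.ewi_scheme <- function(x, ...) {
  cat(sprintf("<ewi_scheme> %s: %d sources, PRF %g Hz (%g volumes/s)\n",
              x$config_name, length(x$sources), x$prf, effective_volume_rate(x)))
  invisible(x)
}

#' Per-element transmit firing delays realizing a diverging wavefront
#'
#' Element e of the active aperture fires at
#' (|p_e - p_source| - min_active |p - p_source|) / c, so the emitted wavefront
#' is the spherical wave of the virtual source and the earliest element fires
#' at t = 0 (the shared t = 0 convention of simulator and beamformer).
#' Inactive elements get NA.
#'
#' @param source an `ewi_source`.
#' @param probe an [matrix_probe()].
#' @param medium a [medium_model()].
#' @return Numeric vector of firing delays (s) per element, NA where inactive.
#' @export
transmit_delay_law <- function(source, probe, medium = medium_model()) {
  pos <- element_positions(probe)
  d <- sqrt(rowSums(sweep(pos, 2, source$position)^2))
  delay <- rep(NA_real_, nrow(pos))
  act <- source$aperture
  delay[act] <- (d[act] - min(d[act])) / medium$speed_of_sound
  delay
}

source_min_distance <- function(source, probe) {
  pos <- element_positions(probe)
  act <- source$aperture
  min(sqrt(rowSums(sweep(pos[act, , drop = FALSE], 2, source$position)^2)))
}

#' Compounded volume rate of a transmit scheme
#'
#' @param scheme an `ewi_scheme`.
#' @return PRF divided by the number of transmits per compounded volume (Hz).
#' @export
effective_volume_rate <- function(scheme) {
  if (length(scheme$sources) == 0L) stop("scheme has no sources")
  scheme$prf / length(scheme$sources)
}

#' Pyramidal scan grid
#'
#' Depth samples along rays fanned over a sector in azimuth (x-z plane) and
#' elevation (y-z plane); ordering is depth fastest, then azimuth, then
#' elevation. The ray of line (az, el) has direction proportional to
#' (tan az, tan el, 1), matching the steering convention of
#' [make_steered_scheme()].
#'
#' @param depth_min,depth_max depth range in meters (both positive).
#' @param axial_step axial sampling in meters (default 32.1e-6).
#' @param sector_deg full sector angle in degrees (default 90).
#' @param lines_per_degree line density (default 1).
#' @param az_deg,el_deg optional explicit line angle vectors (degrees,
#'   strictly increasing), overriding the sector parameters.
#' @return An object of class `ewi_grid`.
#' @export
scan_grid <- function(depth_min, depth_max, axial_step = 32.1e-6,
                      sector_deg = 90, lines_per_degree = 1,
                      az_deg = NULL, el_deg = NULL) {
  if (depth_min <= 0 || depth_max <= depth_min) stop("need 0 < depth_min < depth_max")
  if (axial_step <= 0) stop("axial_step must be positive")
  if (is.null(az_deg)) {
    half <- sector_deg / 2
    az_deg <- seq(-half, half, by = 1 / lines_per_degree)
  }
  if (is.null(el_deg)) el_deg <- az_deg
  if (any(diff(az_deg) <= 0) || any(diff(el_deg) <= 0))
    stop("line angles must be strictly increasing")
  depths <- seq(depth_min, depth_max, by = axial_step)
  structure(list(depths = depths, az_deg = az_deg, el_deg = el_deg,
                 axial_step = axial_step),
            class = "ewi_grid")
}

#' @export
print.ewi_grid <- function(x, ...) {
  cat(sprintf("<ewi_grid> %d x %d x %d (depth x az x el), %.3g-%.3g mm, step %.3g um\n",
              length(x$depths), length(x$az_deg), length(x$el_deg),
              min(x$depths) * 1e3, max(x$depths) * 1e3, x$axial_step * 1e6))
  invisible(x)
}

grid_dims <- function(grid) {
  c(length(grid$depths), length(grid$az_deg), length(grid$el_deg))
}

#' Unit ray directions of the scan lines
#'
#' @param grid an [scan_grid()].
#' @return List with matrices `ux`, `uy`, `uz` of dimension n_az x n_el.
#' @export
line_directions <- function(grid) {
  ta <- tan(deg2rad(grid$az_deg))
  te <- tan(deg2rad(grid$el_deg))
  tx <- outer(ta, rep(1, length(te)))
  ty <- outer(rep(1, length(ta)), te)
  nrm <- sqrt(tx^2 + ty^2 + 1)
  list(ux = tx / nrm, uy = ty / nrm, uz = 1 / nrm)
}

#' Cartesian coordinates of all grid nodes
#'
#' @param grid an [scan_grid()].
#' @param depths optional depth vector replacing `grid$depths` (used for
#'   window-center lattices).
#' @return List of arrays `x`, `y`, `z` with dimension (n_depth, n_az, n_el).
#' @export
grid_coordinates <- function(grid, depths = NULL) {
  depths <- depths %||% grid$depths
  u <- line_directions(grid)
  nd <- length(depths)
  dims <- c(nd, length(grid$az_deg), length(grid$el_deg))
  x <- outer(depths, as.vector(u$ux))
  y <- outer(depths, as.vector(u$uy))
  z <- outer(depths, as.vector(u$uz))
  list(x = array(x, dims), y = array(y, dims), z = array(z, dims))
}
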