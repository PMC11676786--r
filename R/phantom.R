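#' Ellipsoidal chamber shell
#'
#' A myocardial wall modelled as the region between two concentric ellipsoids:
#' the outer ellipsoid with the given semi-axes and an inner one with semi-axes
#' reduced by `wall` (clamped at zero, so `wall >= min(semi_axes)` gives a
#' solid chamber).
#'
#' @param label chamber label: 1 RA, 2 LA, 3 RV, 4 LV.
#' @param center ellipsoid center (x, y, z) in meters.
#' @param semi_axes outer semi-axes (a, b, c) in meters.
#' @param wall wall thickness in meters (0 < wall <= min(semi_axes)).
#' @export
chamber_shell <- function(label, center, semi_axes, wall) {
  label <- as.integer(label)
  if (!label %in% 1:4) stop("label must be in 1 (RA), 2 (LA), 3 (RV), 4 (LV)")
  semi_axes <- as.numeric(semi_axes)
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (wall <= 0 || wall > min(semi_axes)) stop("need 0 < wall <= min(semi_axes)")
  structure(list(label = label, center = as.numeric(center),
                 semi_axes = semi_axes, wall = wall,
                 inner = pmax(semi_axes - wall, 0)),
            class = "ewi_shell")
}

shell_volume_mm3 <- function(shell) {
  4 / 3 * pi * (prod(shell$semi_axes) - prod(shell$inner)) * 1e9
}

is_atrial_label <- function(label) label %in% c(1L, 2L)

#' Test points against a chamber shell
#'
#' @param points n x 3 matrix of positions (m).
#' @param shell a [chamber_shell()].
#' @return Logical vector: inside the wall (outer ellipsoid minus cavity).
#' @export
in_shell <- function(points, shell) {
  q_out <- sweep(sweep(points, 2, shell$center), 2, shell$semi_axes, "/")
  inside_outer <- rowSums(q_out^2) <= 1
  if (all(shell$inner > 0)) {
    q_in <- sweep(sweep(points, 2, shell$center), 2, shell$inner, "/")
    inside_outer & rowSums(q_in^2) > 1
  } else inside_outer
}

#' Phantom specification
#'
#' @param shells list of [chamber_shell()] objects.
#' @param density scatterer density in count per mm^3.
#' @param reflectivity_sd standard deviation of the zero-mean Gaussian
#'   scattering amplitudes.
#' @param seed integer seed; the phantom is bit-reproducible given the seed.
#' @export
phantom_spec <- function(shells, density = 1, reflectivity_sd = 1, seed = 1L) {
  if (density < 0) stop("density must be non-negative")
  for (s in shells) stopifnot(inherits(s, "ewi_shell"))
  structure(list(shells = shells, density = density,
                 reflectivity_sd = reflectivity_sd, seed = as.integer(seed)),
            class = "ewi_phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_shell <- function(shell, n) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    m <- max(64L, 2L * (n - nrow(out)))
    cand <- cbind(runif(m, -1, 1) * shell$semi_axes[1],
                  runif(m, -1, 1) * shell$semi_axes[2],
                  runif(m, -1, 1) * shell$semi_axes[3])
    cand <- sweep(cand, 2, shell$center, "+")
    out <- rbind(out, cand[in_shell(cand, shell), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Build a scatterer phantom with ground-truth masks
#'
#' Draws a Poisson number of uniformly-placed scatterers in each chamber wall,
#' labels the scan-grid voxels whose centers fall inside a wall, and locates
#' the atrio-ventricular junction surface as the per-line axial index of the
#' plane separating ventricular from atrial walls.
#'
#' @param spec an [phantom_spec()].
#' @param grid an [scan_grid()] on which the label mask is rasterized.
#' @return A list with `cloud` (positions, reflectivity, label, region),
#'   `mask` (integer array, 0 background and chamber labels 1-4),
#'   `junction` (n_az x n_el matrix of axial indices, or NULL),
#'   `junction_z` (meters, or NULL) and the `spec`.
#' @export
build_phantom <- function(spec, grid) {
  res <- with_seed(spec$seed, {
    pos <- matrix(numeric(0), 0, 3); lab <- integer(0)
    for (s in spec$shells) {
      n <- rpois(1, spec$density * shell_volume_mm3(s))
      p <- sample_shell(s, n)
      pos <- rbind(pos, p); lab <- c(lab, rep(s$label, n))
    }
    refl <- rnorm(nrow(pos), 0, spec$reflectivity_sd)
    list(pos = pos, lab = lab, refl = refl)
  })
  cloud <- structure(list(positions = res$pos, reflectivity = res$refl,
                          label = res$lab,
                          region = ifelse(is_atrial_label(res$lab), 1L, 2L)),
                     class = "ewi_cloud")

  co <- grid_coordinates(grid)
  pts <- cbind(as.vector(co$x), as.vector(co$y), as.vector(co$z))
  mask <- integer(nrow(pts))
  for (s in spec$shells) {
    hit <- in_shell(pts, s)
    clash <- hit & mask != 0L & mask != s$label
    if (any(clash)) stop("overlapping shells with conflicting labels")
    mask[hit] <- s$label
  }
  mask <- array(mask, grid_dims(grid))

  junction <- NULL; junction_z <- NULL
  vent <- Filter(function(s) !is_atrial_label(s$label), spec$shells)
  atr <- Filter(function(s) is_atrial_label(s$label), spec$shells)
  if (length(vent) && length(atr)) {
    z_vent_max <- max(vapply(vent, function(s) s$center[3] + s$semi_axes[3], 0))
    z_atr_min <- min(vapply(atr, function(s) s$center[3] - s$semi_axes[3], 0))
    junction_z <- (z_vent_max + z_atr_min) / 2
    u <- line_directions(grid)
    r_j <- junction_z / u$uz
    junction <- matrix(vapply(as.vector(r_j), function(r)
      which.min(abs(grid$depths - r)), 0L),
      length(grid$az_deg), length(grid$el_deg))
  }
  list(cloud = cloud, mask = mask, junction = junction,
       junction_z = junction_z, spec = spec)
}

#' Prescribed electromechanical activation and shortening law
#'
#' The electrical activation wave spreads at constant conduction velocity from
#' a regional origin: atrial voxels activate at
#' `p_onset + |p - atrial_origin| / v_atrial`, ventricular voxels at
#' `q_onset + |p - vent_origin| / v_vent` with `q_onset = p_onset + av_delay`.
#' Mechanically, a ventricular point ramps its local axial strain linearly
#' from 0 to `s_es_vent` (negative, shortening) over `tau` after its
#' activation, then holds; atrial tissue instead lengthens to `s_es_atrial`
#' (positive, reservoir stretch) during ventricular systole, starting
#' `atrial_stretch_delay` after QRS onset and ramping over `atrial_tau`.
#'
#' @param vent_origin,atrial_origin activation origins (x, y, z) in meters.
#' @param v_vent,v_atrial conduction velocities in m/s.
#' @param p_onset P-wave onset (s); the atrial electrical reference.
#' @param av_delay atrio-ventricular delay (s); QRS onset is
#'   `p_onset + av_delay`.
#' @param tau ventricular shortening ramp duration (s).
#' @param s_es_vent,s_es_atrial plateau (end-systolic) strains.
#' @param atrial_stretch_delay,atrial_tau onset delay after QRS and ramp
#'   duration of the atrial reservoir stretch (s).
#' @return An object of class `ewi_activation_truth`.
#' @export
activation_model <- function(vent_origin, atrial_origin = NULL,
                             v_vent = 1.5, v_atrial = 1.0,
                             p_onset = 8e-3, av_delay = 80e-3,
                             tau = 60e-3, s_es_vent = -0.15,
                             s_es_atrial = 0.25,
                             atrial_stretch_delay = 10e-3, atrial_tau = 60e-3) {
  if (v_vent <= 0 || v_atrial <= 0) stop("conduction velocities must be positive")
  structure(list(vent_origin = as.numeric(vent_origin),
                 atrial_origin = if (is.null(atrial_origin)) NULL else as.numeric(atrial_origin),
                 v_vent = v_vent, v_atrial = v_atrial,
                 p_onset = p_onset, av_delay = av_delay,
                 q_onset = p_onset + av_delay,
                 tau = tau, s_es_vent = s_es_vent, s_es_atrial = s_es_atrial,
                 atrial_stretch_delay = atrial_stretch_delay,
                 atrial_tau = atrial_tau),
            class = "ewi_activation_truth")
}

#' Electrical activation onset of arbitrary points
#'
#' @param points n x 3 matrix of positions (m).
#' @param region integer vector, 1 atrial / 2 ventricular.
#' @param truth an [activation_model()].
#' @return Activation times in seconds.
#' @export
electrical_onset <- function(points, region, truth) {
  points <- rbind(points)
  t_act <- numeric(nrow(points))
  v <- region == 2L
  if (any(v)) {
    d <- sqrt(rowSums(sweep(points[v, , drop = FALSE], 2, truth$vent_origin)^2))
    t_act[v] <- truth$q_onset + d / truth$v_vent
  }
  if (any(!v)) {
    if (is.null(truth$atrial_origin)) stop("truth has no atrial origin")
    d <- sqrt(rowSums(sweep(points[!v, , drop = FALSE], 2, truth$atrial_origin)^2))
    t_act[!v] <- truth$p_onset + d / truth$v_atrial
  }
  t_act
}

# Mechanical response onset / ramp parameters for points of a given region.
response_law <- function(points, region, truth) {
  onset <- numeric(length(region)); tau <- numeric(length(region))
  s_es <- numeric(length(region))
  v <- region == 2L
  onset[v] <- electrical_onset(points[v, , drop = FALSE], rep(2L, sum(v)), truth)
  tau[v] <- truth$tau; s_es[v] <- truth$s_es_vent
  onset[!v] <- truth$q_onset + truth$atrial_stretch_delay
  tau[!v] <- truth$atrial_tau; s_es[!v] <- truth$s_es_atrial
  list(onset = onset, tau = tau, s_es = s_es)
}

# Shallowest myocardial z reached by the vertical column through (x, y); Inf
# when the column misses every shell.
column_entry_z <- function(x, y, shells) {
  z <- Inf
  for (s in shells) {
    q <- ((x - s$center[1]) / s$semi_axes[1])^2 + ((y - s$center[2]) / s$semi_axes[2])^2
    if (q < 1) z <- min(z, s$center[3] - s$semi_axes[3] * sqrt(1 - q))
  }
  z
}

#' Precompute the axial motion integral of a set of points
#'
#' The prescribed displacement is purely axial: u(p, t) is the integral of the
#' local strain law along z from the apical anchor (the shallowest myocardial
#' depth of the point's (x, y) column; apical-view convention where the apex is
#' nearly stationary with respect to the probe) up to the point. The integral
#' is discretized at step `dz` and stored as a flat table so displacement at
#' any time is a clamped-ramp sum.
#'
#' @param points n x 3 positions (m).
#' @param truth an [activation_model()].
#' @param spec the [phantom_spec()] providing the shell geometry.
#' @param dz integration step (m).
#' @return A motion table (list of flat vectors) consumed by
#'   [displace_points()].
#' @export
motion_table <- function(points, truth, spec, dz = 0.25e-3) {
  points <- rbind(points)
  n <- nrow(points)
  idx_l <- vector("list", n); on_l <- vector("list", n)
  tau_l <- vector("list", n); ss_l <- vector("list", n)
  for (i in seq_len(n)) {
    x <- points[i, 1]; y <- points[i, 2]; zp <- points[i, 3]
    za <- column_entry_z(x, y, spec$shells)
    if (!is.finite(za) || zp <= za + dz / 2) next
    zq <- seq(za + dz / 2, zp, by = dz)
    if (!length(zq)) next
    samp <- cbind(x, y, zq)
    lab <- integer(length(zq))
    for (s in spec$shells) lab[in_shell(samp, s)] <- s$label
    inside <- lab != 0L
    if (!any(inside)) next
    reg <- ifelse(is_atrial_label(lab[inside]), 1L, 2L)
    law <- response_law(samp[inside, , drop = FALSE], reg, truth)
    idx_l[[i]] <- rep(i, sum(inside))
    on_l[[i]] <- law$onset; tau_l[[i]] <- law$tau; ss_l[[i]] <- law$s_es
  }
  list(idx = unlist(idx_l), onset = unlist(on_l), tau = unlist(tau_l),
       step_strain = unlist(ss_l) * dz, n = n, dz = dz)
}

#' Evaluate the prescribed axial displacement at time t
#'
#' @param tab a [motion_table()].
#' @param t time in seconds.
#' @return Numeric vector of z-displacements (m; positive = deeper, i.e. away
#'   from the transducer).
#' @export
displace_points <- function(tab, t) {
  u <- numeric(tab$n)
  if (!length(tab$idx)) return(u)
  f <- pmin(pmax((t - tab$onset) / tab$tau, 0), 1)
  s <- rowsum(tab$step_strain * f, tab$idx, reorder = FALSE)
  u[as.integer(rownames(s))] <- s[, 1]
  u
}

#' Attach the motion law to a scatterer cloud
#'
#' @param cloud an `ewi_cloud` from [build_phantom()].
#' @param truth an [activation_model()].
#' @param spec the [phantom_spec()].
#' @param dz integration step for the strain integral (m).
#' @return The cloud with a precomputed motion table.
#' @export
prepare_motion <- function(cloud, truth, spec, dz = 0.25e-3) {
  cloud$motion <- motion_table(cloud$positions, truth, spec, dz)
  cloud$truth <- truth
  cloud
}

#' Displace a scatterer cloud to time t
#'
#' Identity for clouds without a motion law and for t before the earliest
#' mechanical onset.
#'
#' @param cloud an `ewi_cloud`.
#' @param t time in seconds (>= 0).
#' @export
displace <- function(cloud, t) {
  if (t < 0) stop("t must be non-negative")
  if (is.null(cloud$motion)) return(cloud)
  u <- displace_points(cloud$motion, t)
  cloud$positions[, 3] <- cloud$positions[, 3] + u
  cloud
}

#' Ground-truth isochrones on the mask
#'
#' Evaluates the closed-form electrical activation time at every masked voxel.
#'
#' @param truth an [activation_model()].
#' @param mask integer label array from [build_phantom()].
#' @param grid the [scan_grid()] of the mask (or a window-center lattice via
#'   `depths`).
#' @param depths optional depth vector for a window-center lattice.
#' @return Array of activation times (s), NA outside the myocardium.
#' @export
true_isochrones <- function(truth, mask, grid, depths = NULL) {
  co <- grid_coordinates(grid, depths)
  out <- array(NA_real_, dim(mask))
  idx <- which(mask != 0L)
  if (!length(idx)) return(out)
  pts <- cbind(co$x[idx], co$y[idx], co$z[idx])
  reg <- ifelse(is_atrial_label(mask[idx]), 1L, 2L)
  out[idx] <- electrical_onset(pts, reg, truth)
  out
}

#' Synthetic ECG trace with activation markers
#'
#' A cosmetic waveform (Gaussian P and T waves, narrow QRS complex) carrying
#' the markers the pipeline actually consumes.
#'
#' @param p_onset,q_onset,end_systole marker times in seconds.
#' @param duration recording length (s).
#' @param fs sampling rate (Hz).
#' @return An `ewi_ecg` list: `time`, `mv`, `markers`.
#' @export
synthetic_ecg <- function(p_onset, q_onset, end_systole, duration, fs = 1000) {
  if (!(p_onset < q_onset && q_onset < end_systole))
    stop("markers must satisfy p_onset < q_onset < end_systole")
  if (end_systole > duration) stop("markers must lie within the recording")
  t <- seq(0, duration, by = 1 / fs)
  bump <- function(mu, sd, a) a * exp(-(t - mu)^2 / (2 * sd^2))
  mv <- bump(p_onset + 0.04, 0.02, 0.15) +
    bump(q_onset + 0.02, 0.008, 1.0) - bump(q_onset + 0.035, 0.01, 0.25) +
    bump(end_systole + 0.05, 0.035, 0.3)
  structure(list(time = t, mv = mv,
                 markers = list(p_onset = p_onset, q_onset = q_onset,
                                end_systole = end_systole)),
            class = "ewi_ecg")
}
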