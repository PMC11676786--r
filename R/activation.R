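#' Activation-mapping configuration
#'
#' @param n_sample_voxels number of myocardial voxels randomly sampled for
#'   onset detection (default 200).
#' @param seed seed of the voxel sampling.
#' @param ventricular_window search window after QRS onset, seconds
#'   (default 0.250, meaningful range 0.200-0.300).
#' @param fallback_drop_factor a curve with no zero crossing that stays
#'   non-positive and whose steepest one-step decrement exceeds this factor
#'   times the median absolute one-step change dates the activation at the
#'   sample before the steepest decrement.
#' @param crossing_significance scale-free gate: a positive-to-negative
#'   crossing is accepted only if the curve then falls below
#'   -crossing_significance * median(|one-step change|); 0 disables the gate
#'   (literal first-crossing rule). Invariant under positive rescaling of the
#'   curve.
#' @param confirm_samples how many samples after a candidate crossing are
#'   inspected by the significance gate.
#' @export
activation_config <- function(n_sample_voxels = 200L, seed = 1L,
                              ventricular_window = 0.250,
                              fallback_drop_factor = 4.0,
                              crossing_significance = 4.0,
                              confirm_samples = 8L) {
  structure(list(n_sample_voxels = as.integer(n_sample_voxels),
                 seed = as.integer(seed),
                 ventricular_window = ventricular_window,
                 fallback_drop_factor = fallback_drop_factor,
                 crossing_significance = crossing_significance,
                 confirm_samples = as.integer(confirm_samples)),
            class = "ewi_activation_config")
}

#' Detect the local onset of shortening in a strain curve
#'
#' Scans the inter-volume axial strain samples inside
#' `[ref_time, ref_time + window]` for the first positive-to-negative zero
#' crossing (strain > 0 followed by strain <= 0), dating the onset by linear
#' interpolation to the zero. If no (significant) crossing exists but the
#' curve stays non-positive and then drops rapidly and strongly — a one-step
#' decrement exceeding `fallback_drop_factor` times the median absolute
#' one-step change — the sample before the first such decrement is used
#' (method `"rapid_decrease"`). Otherwise no onset is returned.
#'
#' @param strain strain time series at one voxel.
#' @param times sample times (s), same length.
#' @param ref_time reference time (P onset for atria, QRS onset for
#'   ventricles).
#' @param window search window length after `ref_time` (s).
#' @param cfg an [activation_config()].
#' @return List `t_act` (s, absolute) and `method`, or NULL when no onset is
#'   detected.
#' @export
detect_onset <- function(strain, times, ref_time, window,
                         cfg = activation_config()) {
  sel <- which(times >= ref_time & times <= ref_time + window)
  if (!length(sel)) stop("empty search window")
  e <- strain[sel]; t <- times[sel]
  ok <- is.finite(e)
  e <- e[ok]; t <- t[ok]
  n <- length(e)
  if (n < 2L) return(NULL)
  de <- diff(e)
  scale <- median(abs(de))
  thr <- cfg$crossing_significance * scale
  cand <- which(e[-n] > 0 & e[-1] <= 0)
  # the descent the crossing must belong to: the first sample significantly
  # below zero on the curve's own fluctuation scale
  neg <- which(e < -thr)
  if (length(neg) && length(cand)) {
    m <- if (thr == 0) cand[1] else {
      before <- cand[cand < neg[1]]
      if (length(before)) before[length(before)] else integer(0)
    }
    if (length(m)) {
      t0 <- t[m] + (t[m + 1L] - t[m]) * e[m] / (e[m] - e[m + 1L])
      return(list(t_act = t0, method = "zero_crossing"))
    }
  }
  if (all(e <= thr)) {
    big <- which(-de > cfg$fallback_drop_factor * scale & de < 0)
    if (length(big))   # date the sample before the decrease starts
      return(list(t_act = t[big[1]], method = "rapid_decrease"))
  }
  NULL
}

# Exact scattered interpolation with a linear radial basis (phi(r) = r) plus
# an affine polynomial term; well-posed for distinct sites, exact at sites.
rbf_interp3 <- function(xyz, y, xyz_eval) {
  n <- nrow(xyz)
  dmat <- function(a, b) {
    sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
         outer(a[, 3], b[, 3], "-")^2)
  }
  P <- cbind(1, xyz)
  A <- rbind(cbind(dmat(xyz, xyz), P), cbind(t(P), matrix(0, 4, 4)))
  coefs <- solve(A, c(y, numeric(4)))
  w <- coefs[seq_len(n)]; beta <- coefs[n + 1:4]
  as.vector(dmat(xyz_eval, xyz) %*% w + cbind(1, xyz_eval) %*% beta)
}

#' Map electromechanical activation over the myocardium
#'
#' Randomly samples myocardial lattice sites (seeded, without replacement),
#' detects the onset of shortening at each — atrial sites are searched from P
#' onset to QRS onset, ventricular sites over `ventricular_window` after QRS
#' onset — and interpolates the detections to every myocardial voxel of the
#' same region by exact scattered (linear radial-basis) interpolation in
#' Cartesian coordinates. Regions with fewer than 4 detections are left unset
#' with a warning (detections are still reported).
#'
#' @param sser an `ewi_strain_series` (inter-volume strain with `times`).
#' @param mask integer chamber-label array on the strain lattice.
#' @param coords Cartesian lattice coordinates, as from [grid_coordinates()]
#'   evaluated at the window-center depths.
#' @param markers list with `p_onset` and `q_onset` (s).
#' @param cfg an [activation_config()].
#' @return An `ewi_activation_map`: `t_ms` (activation time in ms relative to
#'   the per-region reference), `t_abs_ms` (relative to P onset), `method`
#'   (1 zero-crossing, 2 rapid decrease, 3 interpolated), `detections`
#'   data.frame, and the references used.
#' @export
map_activation <- function(sser, mask, coords, markers,
                           cfg = activation_config()) {
  dims <- dim(sser$eps)[1:3]
  stopifnot(all(dim(mask) == dims))
  myo <- which(mask != 0L)
  if (!length(myo)) stop("mask selects no myocardial voxels")
  n_take <- min(cfg$n_sample_voxels, length(myo))
  sites <- with_seed(cfg$seed, sort(sample(myo, n_take)))
  epsm <- matrix(sser$eps, prod(dims))

  atrial <- is_atrial_label(mask[sites])
  refs <- ifelse(atrial, markers$p_onset, markers$q_onset)
  wins <- ifelse(atrial, markers$q_onset - markers$p_onset,
                 cfg$ventricular_window)
  det <- data.frame(site = sites, atrial = atrial, t_act = NA_real_,
                    method = NA_character_,
                    x = coords$x[sites], y = coords$y[sites],
                    z = coords$z[sites])
  for (i in seq_len(nrow(det))) {
    if (!any(sser$times >= refs[i] & sser$times <= refs[i] + wins[i]))
      next  # search window outside the recording: no detection possible
    r <- detect_onset(epsm[sites[i], ], sser$times, refs[i], wins[i], cfg)
    if (!is.null(r)) {
      det$t_act[i] <- r$t_act
      det$method[i] <- r$method
    }
  }
  hit <- !is.na(det$t_act)

  t_ms <- array(NA_real_, dims)
  method <- array(NA_integer_, dims)
  for (reg_atrial in c(TRUE, FALSE)) {
    in_reg <- det$atrial == reg_atrial & hit
    reg_sites <- det$site[in_reg]
    reg_ref <- if (reg_atrial) markers$p_onset else markers$q_onset
    reg_all <- myo[is_atrial_label(mask[myo]) == reg_atrial]
    if (!length(reg_all)) next
    if (sum(in_reg) == 0L) {
      warning(sprintf("no activation detected in the %s; region left unset",
                      if (reg_atrial) "atria" else "ventricles"))
      next
    }
    t_ms[reg_sites] <- (det$t_act[in_reg] - reg_ref) * 1e3
    method[reg_sites] <- ifelse(det$method[in_reg] == "zero_crossing", 1L, 2L)
    if (sum(in_reg) >= 4L) {
      rest <- setdiff(reg_all, reg_sites)
      if (length(rest)) {
        xyz <- cbind(det$x[in_reg], det$y[in_reg], det$z[in_reg])
        xyz_e <- cbind(coords$x[rest], coords$y[rest], coords$z[rest])
        t_ms[rest] <- rbf_interp3(xyz, (det$t_act[in_reg] - reg_ref) * 1e3, xyz_e)
        method[rest] <- 3L
      }
    } else {
      warning("fewer than 4 detections; interpolation skipped for one region")
    }
  }
  t_abs_ms <- t_ms
  vent_set <- which(!is.na(t_ms) & !is_atrial_label(mask) & mask != 0L)
  t_abs_ms[vent_set] <- t_ms[vent_set] +
    (markers$q_onset - markers$p_onset) * 1e3
  structure(list(t_ms = t_ms, t_abs_ms = t_abs_ms, method = method,
                 detections = det[hit, , drop = FALSE],
                 markers = markers, cfg = cfg),
            class = "ewi_activation_map")
}

#' Regional activation statistics
#'
#' Mean, span (max - min) and extreme activation times over the set voxels of
#' the atria, the ventricles and the whole heart. Per-region rows use the
#' region's own ECG reference; the whole-heart row uses times relative to P
#' onset.
#'
#' @param map an `ewi_activation_map`.
#' @param mask chamber-label array on the same lattice.
#' @return data.frame with one row per non-empty region.
#' @export
activation_stats <- function(map, mask) {
  regions <- list(
    atria = list(sel = is_atrial_label(mask) & !is.na(map$t_ms),
                 val = map$t_ms, ref = "p_onset"),
    ventricles = list(sel = !is_atrial_label(mask) & mask != 0L & !is.na(map$t_ms),
                      val = map$t_ms, ref = "q_onset"),
    whole_heart = list(sel = mask != 0L & !is.na(map$t_abs_ms),
                       val = map$t_abs_ms, ref = "p_onset")
  )
  rows <- lapply(names(regions), function(nm) {
    r <- regions[[nm]]
    v <- r$val[r$sel]
    if (!length(v)) {
      warning(sprintf("region %s empty; omitted", nm))
      return(NULL)
    }
    data.frame(region = nm, n = length(v), mean_ms = mean(v),
               span_ms = max(v) - min(v), earliest_ms = min(v),
               latest_ms = max(v), reference = r$ref)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
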