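#' Resample a scan-grid label mask onto the tracking lattice
#'
#' Nearest-depth-sample label lookup: the tracking lattice shares the scan
#' lines and replaces the depth axis by the window centers.
#'
#' @param mask integer label array on the full scan grid.
#' @param grid the [scan_grid()] of the mask.
#' @param depths window-center depths (m) of the tracking lattice.
#' @return Integer label array (n_window x n_az x n_el).
#' @export
window_mask <- function(mask, grid, depths) {
  idx <- vapply(depths, function(r) which.min(abs(grid$depths - r)), 0L)
  mask[idx, , , drop = FALSE]
}

#' Atrio-ventricular junction on the tracking lattice
#'
#' @param junction per-line axial index matrix on the full grid.
#' @param grid the [scan_grid()].
#' @param depths window-center depths (m).
#' @return Matrix of window indices.
#' @export
window_junction <- function(junction, grid, depths) {
  jz <- matrix(grid$depths[junction], nrow(junction), ncol(junction))
  matrix(vapply(as.vector(jz), function(r) which.min(abs(depths - r)), 0L),
         nrow(junction), ncol(junction))
}

#' Select the systolic interval from ventricular inward motion
#'
#' The systole starts at the first volume at/after QRS onset and extends over
#' the longest contiguous run of volume pairs (searched from that volume) in
#' which the median valid ventricular inter-volume displacement is positive,
#' i.e. directed toward the transducer — the inward motion of an apical view.
#' A manual interval, when provided, is passed through unchanged.
#'
#' @param dser an `ewi_displacement_series` (with `times` and `rate`).
#' @param mask chamber-label array on the tracking lattice.
#' @param markers list with `q_onset` (s).
#' @param manual optional `c(k_start, k_end)` volume indices.
#' @return List `k_start`, `k_end` (volume indices, 1-based) and
#'   `provenance`.
#' @export
select_systole <- function(dser, mask, markers, manual = NULL) {
  if (!is.null(manual)) {
    if (!(manual[1] < manual[2])) stop("manual interval must satisfy k_start < k_end")
    return(list(k_start = as.integer(manual[1]), k_end = as.integer(manual[2]),
                provenance = "manual"))
  }
  n_pairs <- dim(dser$d)[4]
  vent <- !is_atrial_label(mask) & mask != 0L
  med <- vapply(seq_len(n_pairs), function(p) {
    d <- dser$d[, , , p][vent & dser$valid[, , , p]]
    if (!length(d)) return(NA_real_)
    median(d)
  }, 0)
  p_start <- which(dser$times >= markers$q_onset)[1]
  if (is.na(p_start)) stop("QRS onset is after the recording")
  pos <- !is.na(med) & med > 0
  pos[seq_len(p_start - 1)] <- FALSE
  if (!any(pos))
    stop("no positive ventricular displacement run after QRS onset; supply a manual interval")
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  ri <- which(runs$values)[which.max(runs$lengths[runs$values])]
  list(k_start = as.integer(p_start), k_end = as.integer(ends[ri] + 1L),
       provenance = "mmode_auto")
}

#' Chamber-resolved global longitudinal strain
#'
#' Unweighted means of the end-systolic axial strain over the labeled voxel
#' sets, in percent: VGLS over the ventricles (RV + LV), AGLS over the atria
#' (RA + LA), plus per-chamber means. Invalid (quality-masked) voxels are
#' excluded; an empty chamber is omitted with a warning.
#'
#' @param es end-systolic strain, as from [end_systolic_strain()].
#' @param mask chamber-label array on the same lattice.
#' @return List with `agls`, `vgls` (percent, NA when empty) and a
#'   data.frame `chambers`.
#' @export
chamber_gls <- function(es, mask) {
  stopifnot(all(dim(mask) == dim(es$eps)))
  ok <- es$valid
  pick <- function(sel) {
    v <- es$eps[sel & ok]
    if (!length(v)) NA_real_ else 100 * mean(v)
  }
  agls <- pick(is_atrial_label(mask))
  vgls <- pick(!is_atrial_label(mask) & mask != 0L)
  if (is.na(agls)) warning("no valid atrial voxels; AGLS omitted")
  if (is.na(vgls)) warning("no valid ventricular voxels; VGLS omitted")
  labels <- c(RA = 1L, LA = 2L, RV = 3L, LV = 4L)
  chambers <- do.call(rbind, lapply(names(labels), function(nm) {
    sel <- mask == labels[[nm]]
    if (!any(sel)) return(NULL)
    data.frame(chamber = nm, n = sum(sel & ok), gls_percent = pick(sel))
  }))
  list(agls = agls, vgls = vgls, chambers = chambers)
}
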