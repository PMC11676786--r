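#' Strain-estimator configuration
#'
#' @param sg_window Savitzky-Golay window length in meters (default 3.2 mm);
#'   converted to an odd number of displacement-lattice samples (>= 3).
#' @param sg_polyorder polynomial order of the local least-squares fit; fixed
#'   to 1 (the estimator is a local slope).
#' @export
strain_config <- function(sg_window = 3.2e-3, sg_polyorder = 1L) {
  if (sg_polyorder != 1L)
    stop("only order-1 (local slope) least-squares gradients are supported")
  structure(list(sg_window = sg_window, sg_polyorder = 1L),
            class = "ewi_strain_config")
}

sg_half_width <- function(cfg, spacing) {
  max(1L, as.integer(floor(cfg$sg_window / (2 * spacing))))
}

#' Savitzky-Golay least-squares gradient along depth
#'
#' The strain at each sample is the slope of the degree-1 least-squares line
#' fitted over a centered window of the displacement profile; at the
#' boundaries the window is truncated to the available one-sided samples.
#' With the abscissa in meters the slope is directly the axial strain
#' du/dz (dimensionless).
#'
#' @param u displacement profile: a vector, or an array whose first dimension
#'   is depth (each remaining column is filtered independently).
#' @param spacing sample spacing of the profile in meters.
#' @param cfg a [strain_config()].
#' @return Strain with the same shape as `u`.
#' @export
sg_gradient <- function(u, spacing, cfg = strain_config()) {
  vec <- is.null(dim(u))
  dims <- if (vec) c(length(u), 1L) else dim(u)
  n <- dims[1]
  if (n < 3L) stop("need at least 3 depth samples")
  um <- matrix(u, n)
  h <- min(sg_half_width(cfg, spacing), n - 1L)
  out <- matrix(0, n, ncol(um))
  if (n >= 2L * h + 1L) {
    k <- -h:h
    w <- k / (sum(k^2) * spacing)
    core <- (h + 1):(n - h)
    for (i in seq_along(k))
      out[core, ] <- out[core, ] + w[i] * um[core + k[i], , drop = FALSE]
    for (i in seq_len(h)) {
      out[i, ] <- ls_slope(um[1:(i + h), , drop = FALSE], spacing)
      out[n - i + 1, ] <- ls_slope(um[(n - i + 1 - h):n, , drop = FALSE], spacing)
    }
  } else {
    for (i in seq_len(n))
      out[i, ] <- ls_slope(um[max(1, i - h):min(n, i + h), , drop = FALSE], spacing)
  }
  if (vec) out[, 1] else array(out, dims)
}

# Least-squares slope of each column against an evenly spaced abscissa.
ls_slope <- function(um, spacing) {
  m <- nrow(um)
  x <- (seq_len(m) - (m + 1) / 2) * spacing
  colSums(x * sweep(um, 2, colMeans(um))) / sum(x^2)
}

#' Inter-volume axial strain of a displacement series
#'
#' Applies the Savitzky-Golay gradient along depth on the displacement
#' lattice (window centers). A strain sample is valid only where every
#' displacement sample in its stencil is valid.
#'
#' @param dser an `ewi_displacement_series`.
#' @param cfg a [strain_config()].
#' @return An `ewi_strain_series` with `eps[w, az, el, pair]` and `valid`.
#' @export
inter_volume_strain <- function(dser, cfg = strain_config()) {
  spacing <- dser$depths[2] - dser$depths[1]
  # the stored displacement is positive toward the transducer, i.e. along -z;
  # the axial strain is the z-gradient of the z-signed displacement
  eps <- sg_gradient(-dser$d, spacing, cfg)
  valid <- stencil_valid(dser$valid, sg_half_width(cfg, spacing))
  structure(list(eps = eps, valid = valid, depths = dser$depths,
                 grid = dser$grid, cfg = cfg, times = dser$times,
                 rate = dser$rate),
            class = "ewi_strain_series")
}

stencil_valid <- function(valid, h) {
  dims <- dim(valid)
  n <- dims[1]
  vm <- matrix(valid, n)
  out <- vm
  for (k in seq_len(h)) {
    out[(1 + k):n, ] <- out[(1 + k):n, ] & vm[1:(n - k), ]
    out[1:(n - k), ] <- out[1:(n - k), ] & vm[(1 + k):n, ]
  }
  array(out, dims)
}

#' Accumulate inter-volume displacements over an interval
#'
#' Eulerian (fixed-lattice) sum of the inter-volume fields between volumes
#' `k0` and `k1` (1-based, pairs k0..k1-1). A site is valid only if every
#' summed step is valid there. With `lagrangian = TRUE` the sampling site
#' follows the material: at every step the field is read at the lattice
#' sample nearest to the site's accumulated displacement (motion toward the
#' transducer shifts the material to shallower depth). The Lagrangian mode
#' matters only when the cumulative motion approaches the lattice spacing.
#'
#' @param dser an `ewi_displacement_series`.
#' @param k0,k1 volume indices, `k0 < k1 <= n_volumes`.
#' @param lagrangian follow material points instead of fixed lattice sites.
#' @return An `ewi_cumulative`: `u` (m), `valid`, interval, lattice info.
#' @export
accumulate_displacement <- function(dser, k0, k1, lagrangian = FALSE) {
  n_pairs <- dim(dser$d)[4]
  if (!(k0 >= 1 && k0 < k1 && k1 <= n_pairs + 1))
    stop("need 1 <= k0 < k1 <= n_volumes")
  pairs <- k0:(k1 - 1)
  dims <- dim(dser$d)[1:3]
  u <- array(0, dims); valid <- array(TRUE, dims)
  if (!lagrangian) {
    for (p in pairs) {
      u <- u + dser$d[, , , p]
      valid <- valid & dser$valid[, , , p]
    }
  } else {
    spacing <- dser$depths[2] - dser$depths[1]
    n_w <- dims[1]
    idx0 <- slice.index(u, 1)
    for (p in pairs) {
      # displacement toward the transducer moves material shallower
      at <- idx0 - as.integer(round(u / spacing))
      oob <- at < 1L | at > n_w
      at[oob] <- 1L
      dp <- matrix(dser$d[, , , p], n_w); vp <- matrix(dser$valid[, , , p], n_w)
      lin <- cbind(as.vector(at),
                   rep(seq_len(prod(dims[2:3])), each = n_w))
      u <- u + array(dp[lin], dims)
      valid <- valid & array(vp[lin], dims) & !oob
    }
  }
  structure(list(u = u, valid = valid, k0 = k0, k1 = k1,
                 lagrangian = lagrangian,
                 depths = dser$depths, grid = dser$grid),
            class = "ewi_cumulative")
}

#' End-systolic strain from accumulated displacement
#'
#' Savitzky-Golay gradient of the cumulative displacement field; negative
#' strain is longitudinal shortening, positive is lengthening.
#'
#' @param cum an `ewi_cumulative` (accumulated to systole end).
#' @param cfg a [strain_config()].
#' @return List with `eps` (dimensionless), `valid` and lattice info.
#' @export
end_systolic_strain <- function(cum, cfg = strain_config()) {
  spacing <- cum$depths[2] - cum$depths[1]
  eps <- sg_gradient(-cum$u, spacing, cfg)  # toward-transducer -> z-signed
  h <- sg_half_width(cfg, spacing)
  valid <- stencil_valid(array(cum$valid, c(dim(cum$valid), 1L)), h)[, , , 1]
  list(eps = eps, valid = valid, depths = cum$depths, grid = cum$grid,
       k0 = cum$k0, k1 = cum$k1)
}
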