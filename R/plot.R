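#' Quick-look image of a displacement M-mode
#'
#' Depth-by-time image of the center-line axial displacement; red/positive is
#' motion toward the transducer.
#'
#' @param dser an `ewi_displacement_series`.
#' @param line optional (azimuth, elevation) line indices.
#' @export
plot_mmode <- function(dser, line = NULL) {
  mm <- displacement_mmode(dser, line)
  graphics::image(x = dser$times, y = dser$depths * 1e3, z = t(mm) * 1e6,
                  xlab = "time (s)", ylab = "depth (mm)",
                  main = "axial displacement M-mode (um)",
                  col = grDevices::hcl.colors(64, "Blue-Red 3"))
  invisible(mm)
}

#' Quick-look image of one isochrone slice
#'
#' @param map an `ewi_activation_map`.
#' @param el elevation index of the slice (default: center).
#' @export
plot_isochrones <- function(map, el = NULL) {
  t_ms <- map$t_abs_ms
  if (is.null(el)) el <- ceiling(dim(t_ms)[3] / 2)
  graphics::image(z = t(t_ms[, , el]), xlab = "azimuth", ylab = "depth window",
                  main = sprintf("activation time (ms after P onset), slice %d", el),
                  col = grDevices::hcl.colors(64, "Spectral"))
  invisible(t_ms[, , el])
}
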