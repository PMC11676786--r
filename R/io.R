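SCHEMA_VERSION <- 1L

write_store <- function(x, path, schema) {
  saveRDS(c(list(schema = schema, version = SCHEMA_VERSION), x), path)
}

read_store <- function(path, schema, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readRDS(path)
  if (!identical(x$schema, schema))
    stop(sprintf("not a %s file: %s", schema, path))
  if (!identical(x$version, SCHEMA_VERSION))
    stop(sprintf("schema version mismatch in %s: file %s, package %s",
                 path, x$version, SCHEMA_VERSION))
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("missing required groups: ", paste(missing, collapse = ", "))
  x
}

#' Persist / load channel data
#'
#' A versioned single-file store holding the RF array (fast time x element x
#' transmit x volume) and the full acquisition metadata; write -> read is
#' bit-identical.
#'
#' @param chd an `ewi_channel_data`.
#' @param path file path.
#' @export
write_channel <- function(chd, path) {
  write_store(list(rf = chd$rf, acquisition = chd$meta), path, "ewi3d/channel")
  invisible(path)
}

#' @rdname write_channel
#' @export
read_channel <- function(path) {
  x <- read_store(path, "ewi3d/channel", c("rf", "acquisition"))
  new_channel_data(x$rf, x$acquisition)
}

#' Persist / load derived pipeline products
#'
#' @param products named list of groups (beamformed series, displacement,
#'   strain, activation, results, ...).
#' @param path file path.
#' @param required group names that [read_products()] must find.
#' @export
write_products <- function(products, path) {
  write_store(list(products = products), path, "ewi3d/products")
  invisible(path)
}

#' @rdname write_products
#' @export
read_products <- function(path, required = character()) {
  x <- read_store(path, "ewi3d/products", "products")
  missing <- setdiff(required, names(x$products))
  if (length(missing))
    stop("missing required groups: ", paste(missing, collapse = ", "))
  x$products
}

#' Write a segmentation mask as NIfTI
#'
#' Stores the label volume on the pyramidal grid axes (depth, azimuth,
#' elevation) with pixdim (axial step in mm, degrees, degrees); the pyramidal
#' axes convention is documented rather than encoded in the affine.
#'
#' @param mask integer label array {0 bg, 1 RA, 2 LA, 3 RV, 4 LV}.
#' @param grid the [scan_grid()].
#' @param path output path (.nii or .nii.gz).
#' @export
write_mask_nifti <- function(mask, grid, path) {
  img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
  img <- RNifti::`pixdim<-`(img, c(grid$axial_step * 1e3,
                                   mean(diff(grid$az_deg)),
                                   mean(diff(grid$el_deg))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a segmentation mask
#'
#' Accepts the 4-chamber labeling {0, 1 RA, 2 LA, 3 RV, 4 LV} or a 2-label
#' {0, 1 atria, 2 ventricles} variant (mapped to RA / RV). The junction
#' surface is read from `junction` or derived per line as the boundary
#' between the deepest ventricular and the shallowest atrial label; atrial
#' labels must lie basal (deeper) of the junction on every line.
#'
#' @param path a NIfTI file (labels) or an RDS products file with groups
#'   `mask` and optional `junction`.
#' @param grid the [scan_grid()] the mask lives on.
#' @param junction optional per-line axial index matrix.
#' @return List with `mask` (canonical labels), `junction` and `labels`
#'   ("four_chamber" or "two_label").
#' @export
read_mask <- function(path, grid, junction = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    mask <- array(as.integer(round(as.array(RNifti::readNifti(path)))),
                  dim = dim(RNifti::readNifti(path)))
  } else {
    p <- read_products(path, "mask")
    mask <- p$mask
    junction <- junction %||% p$junction
  }
  vals <- sort(unique(as.vector(mask)))
  if (any(!vals %in% 0:4)) stop("labels outside {0..4}: ",
                                paste(setdiff(vals, 0:4), collapse = ", "))
  labels <- "four_chamber"
  if (all(vals %in% 0:2) && !any(vals %in% 3:4) && any(vals == 2L)) {
    # two-label variant: 1 = atria, 2 = ventricles
    m2 <- mask
    mask[m2 == 1L] <- 1L   # atria -> RA slot
    mask[m2 == 2L] <- 3L   # ventricles -> RV slot
    labels <- "two_label"
  }
  if (is.null(junction)) junction <- derive_junction(mask)
  validate_junction(mask, junction)
  list(mask = mask, junction = junction, labels = labels)
}

derive_junction <- function(mask) {
  d <- dim(mask)
  jn <- matrix(NA_integer_, d[2], d[3])
  for (a in seq_len(d[2])) for (e in seq_len(d[3])) {
    line <- mask[, a, e]
    vent <- which(line %in% c(3L, 4L)); atr <- which(line %in% c(1L, 2L))
    if (length(vent) && length(atr))
      jn[a, e] <- as.integer(floor((max(vent) + min(atr)) / 2))
  }
  jn
}

validate_junction <- function(mask, junction) {
  d <- dim(mask)
  for (a in seq_len(d[2])) for (e in seq_len(d[3])) {
    j <- junction[a, e]
    if (is.na(j)) next
    line <- mask[, a, e]
    atr <- which(line %in% c(1L, 2L)); vent <- which(line %in% c(3L, 4L))
    if (length(atr) && any(atr <= j))
      stop("atrial voxel apical of the AV junction (line ", a, ",", e, ")")
    if (length(vent) && any(vent > j))
      stop("ventricular voxel basal of the AV junction (line ", a, ",", e, ")")
  }
  invisible(TRUE)
}

#' Write / read an ECG trace as CSV plus a YAML marker sidecar
#'
#' Two-column CSV (time in seconds, amplitude in millivolts); markers
#' (p_onset, q_onset, end_systole) in a YAML sidecar.
#'
#' @param ecg an `ewi_ecg`.
#' @param csv_path CSV output path.
#' @param markers_path YAML sidecar path (default: csv path with
#'   `.markers.yaml`).
#' @export
write_ecg <- function(ecg, csv_path,
                      markers_path = sub("\\.csv$", ".markers.yaml", csv_path)) {
  write.csv(data.frame(t = ecg$time, mv = ecg$mv), csv_path, row.names = FALSE)
  yaml::write_yaml(ecg$markers, markers_path)
  invisible(csv_path)
}

#' @rdname write_ecg
#' @export
read_ecg <- function(csv_path,
                     markers_path = sub("\\.csv$", ".markers.yaml", csv_path)) {
  df <- read.csv(csv_path)
  markers <- yaml::read_yaml(markers_path)
  if (!all(c("p_onset", "q_onset") %in% names(markers)))
    stop("markers sidecar must define p_onset and q_onset")
  structure(list(time = df[[1]], mv = df[[2]], markers = markers),
            class = "ewi_ecg")
}

#' Read and validate a run configuration
#'
#' YAML configuration mirroring [default_config()]; unknown keys are
#' rejected, known keys override the defaults.
#'
#' @param path YAML file.
#' @param defaults the configuration the file overrides.
#' @export
read_config <- function(path, defaults = default_config()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(defaults, user, character())
}

merge_config <- function(base, user, trail) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste(paste(c(trail, ""), collapse = "/"), unknown, sep = "", collapse = ", "))
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]], c(trail, nm))
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Write pipeline results as JSON
#'
#' @param results named list (scalars unboxed, full precision).
#' @param path output path.
#' @export
write_results_json <- function(results, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
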