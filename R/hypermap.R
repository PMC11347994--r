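#' Hyperspectral SERS cube
#'
#' One time-stamped depth-resolved image: an `n_depth x n_lateral` spatial
#' grid of spectra on a shared wavenumber axis. Depth row 1 is the pericarp
#' surface (0 um), increasing inward; spectra are stored row-major by
#' (depth, lateral).
#'
#' @param spectra numeric matrix, `n_depth * n_lateral` rows (row-major by
#'   depth, then lateral) by `n_channels` columns; all finite.
#' @param axis a [wn_axis] with `n_channels` points.
#' @param n_depth,n_lateral grid dimensions.
#' @param depth_step_um,lateral_step_um pixel spacing in micrometres.
#' @param time_h acquisition time in hours (>= 0).
#' @param metadata free-form named list (sample, treatment, ...).
#' @return a `hypermap` object.
#' @export
hypermap <- function(spectra, axis, n_depth, n_lateral,
                     depth_step_um, lateral_step_um, time_h,
                     metadata = list()) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  n_depth <- as.integer(n_depth); n_lateral <- as.integer(n_lateral)
  if (n_depth < 1L || n_lateral < 1L) stop_domain("grid dimensions must be >= 1")
  if (nrow(spectra) != n_depth * n_lateral)
    stop_domain("spectra has ", nrow(spectra), " rows but the grid declares ",
                n_depth * n_lateral, " pixels")
  if (ncol(spectra) != length(axis))
    stop_domain("spectra column count must equal axis length")
  check_finite(spectra, "cube intensities")
  check_scalar_num(depth_step_um, "depth_step_um", lower = .Machine$double.eps)
  check_scalar_num(lateral_step_um, "lateral_step_um", lower = .Machine$double.eps)
  check_scalar_num(time_h, "time_h", lower = 0)
  structure(list(spectra = spectra, axis = axis,
                 n_depth = n_depth, n_lateral = n_lateral,
                 depth_step_um = depth_step_um, lateral_step_um = lateral_step_um,
                 time_h = time_h, metadata = metadata),
            class = "hypermap")
}

#' @export
print.hypermap <- function(x, ...) {
  cat(sprintf(paste0("<hypermap> %d x %d pixels (%.4g x %.4g um steps), ",
                     "%d channels, t = %g h, depth extent %.4g um\n"),
              x$n_depth, x$n_lateral, x$depth_step_um, x$lateral_step_um,
              ncol(x$spectra), x$time_h, depth_extent(x)))
  invisible(x)
}

#' @export
dim.hypermap <- function(x) c(x$n_depth, x$n_lateral, ncol(x$spectra))

#' Depth extent of a cube in micrometres
#' @param cube a [hypermap].
#' @return `(n_depth - 1) * depth_step_um`.
#' @export
depth_extent <- function(cube) (cube$n_depth - 1L) * cube$depth_step_um

#' Depth coordinate (um) of every pixel row of the spectra matrix
#' @param cube a [hypermap].
#' @return numeric vector of length `n_depth * n_lateral`.
#' @export
pixel_depths <- function(cube) {
  rep((seq_len(cube$n_depth) - 1L) * cube$depth_step_um,
      each = cube$n_lateral)
}

#' Extract one pixel spectrum
#' @param cube a [hypermap].
#' @param depth_idx,lateral_idx 1-based grid indices.
#' @return a [new_spectrum].
#' @export
pixel_spectrum <- function(cube, depth_idx, lateral_idx) {
  row <- (depth_idx - 1L) * cube$n_lateral + lateral_idx
  new_spectrum(cube$axis, cube$spectra[row, ])
}

#' Write / read a hyperspectral cube
#'
#' Two containers are supported. `format = "text"`: a tab-delimited matrix
#' (one pixel spectrum per row) plus a JSON sidecar `<path>.json` carrying
#' `n_depth, n_lateral, depth_step_um, lateral_step_um, time_h, axis_cm1,
#' metadata`; round trip preserves intensities to <= 1e-9 relative.
#' `format = "rds"`: R serialization, bit-exact round trip.
#'
#' @param map a [hypermap].
#' @param path file path. For text, the sidecar is written at `<path>.json`.
#' @param format `"text"` or `"rds"`.
#' @return `write_hypermap` returns `path` invisibly; `read_hypermap` returns
#'   the [hypermap].
#' @export
write_hypermap <- function(map, path, format = c("text", "rds")) {
  stopifnot(inherits(map, "hypermap"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(map, path)
    return(invisible(path))
  }
  meta <- list(n_depth = map$n_depth, n_lateral = map$n_lateral,
               depth_step_um = map$depth_step_um,
               lateral_step_um = map$lateral_step_um,
               time_h = map$time_h,
               axis_cm1 = as.numeric(map$axis),
               metadata = map$metadata)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(format(map$spectra, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_hypermap
#' @export
read_hypermap <- function(path, format = c("text", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    map <- readRDS(path)
    if (!inherits(map, "hypermap")) stop_domain("RDS file does not contain a hypermap")
    return(map)
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_domain("format error: missing JSON sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("n_depth", "n_lateral", "depth_step_um", "lateral_step_um",
                "time_h", "axis_cm1")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop_domain("format error: sidecar missing field(s): ",
                paste(missing, collapse = ", "))
  X <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(X) <- NULL
  if (nrow(X) != meta$n_depth * meta$n_lateral)
    stop_domain("format error: file has ", nrow(X),
                " spectra but sidecar declares ", meta$n_depth * meta$n_lateral)
  md <- meta$metadata
  if (is.null(md)) md <- list()
  hypermap(X, wn_axis(meta$axis_cm1), meta$n_depth, meta$n_lateral,
           meta$depth_step_um, meta$lateral_step_um, meta$time_h,
           metadata = as.list(md))
}

#' Read a two-column reference spectrum with a JSON peak list
#'
#' File format: whitespace/tab-delimited `cm^-1  intensity` pairs; peak list
#' sidecar `<path>.json` = `{name, peaks: [{center, half_window}, ...]}`.
#'
#' @param path path to the two-column spectrum file.
#' @return a [reference_spectrum].
#' @export
read_reference_spectrum <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "numeric")
  if (ncol(tab) < 2L) stop_domain("format error: expected two columns (cm^-1, intensity)")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop_domain("format error: missing JSON peak-list sidecar ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$name) || is.null(meta$peaks))
    stop_domain("format error: sidecar needs fields `name` and `peaks`")
  reference_spectrum(meta$name,
                     new_spectrum(wn_axis(tab[[1L]]), tab[[2L]]),
                     as.data.frame(meta$peaks))
}

#' @rdname read_reference_spectrum
#' @param ref a [reference_spectrum] to write.
#' @export
write_reference_spectrum <- function(ref, path) {
  stopifnot(inherits(ref, "reference_spectrum"))
  utils::write.table(
    data.frame(cm1 = as.numeric(ref$spectrum$axis),
               intensity = ref$spectrum$intensities),
    path, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(name = ref$name, peaks = ref$peaks),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
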