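#' Wavenumber axis
#'
#' A strictly increasing grid of Raman shifts in cm^-1, the common abscissa of
#' all spectra in a cube. The constructor validates monotonicity; an axis is a
#' plain numeric vector with class `"wn_axis"`.
#'
#' @param values numeric vector of wavenumbers (cm^-1), strictly increasing,
#'   length >= 2.
#' @return a `wn_axis` object.
#' @export
wn_axis <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop_domain("axis needs at least 2 wavenumbers")
  check_finite(values, "axis values")
  d <- diff(values)
  if (any(d <= 0)) stop_domain("axis must be strictly increasing")
  structure(values, class = "wn_axis")
}

#' Build a uniformly spaced wavenumber axis
#'
#' @param start_cm1,stop_cm1 axis endpoints in cm^-1; `stop_cm1 > start_cm1`.
#' @param n_channels number of channels (>= 2); endpoints are included.
#' @return a [wn_axis] with exactly `n_channels` points.
#' @examples
#' ax <- build_axis(400, 1800, 701)   # 2 cm^-1 spacing
#' @export
build_axis <- function(start_cm1, stop_cm1, n_channels) {
  check_scalar_num(start_cm1, "start_cm1")
  check_scalar_num(stop_cm1, "stop_cm1")
  if (stop_cm1 <= start_cm1) stop_domain("stop_cm1 must exceed start_cm1")
  if (!is.numeric(n_channels) || n_channels < 2 || n_channels != round(n_channels))
    stop_domain("n_channels must be an integer >= 2")
  wn_axis(seq(start_cm1, stop_cm1, length.out = n_channels))
}

#' Is the axis uniformly spaced?
#' @param axis a [wn_axis].
#' @return logical; TRUE when max/min spacing ratio < 1 + 1e-9.
#' @export
axis_is_uniform <- function(axis) {
  d <- diff(unclass(axis))
  max(d) / min(d) < 1 + 1e-9
}

#' @export
print.wn_axis <- function(x, ...) {
  v <- unclass(x)
  cat(sprintf("<wn_axis> %d channels, %.6g-%.6g cm^-1%s\n",
              length(v), v[1L], v[length(v)],
              if (axis_is_uniform(x)) sprintf(", spacing %.6g", v[2L] - v[1L]) else ""))
  invisible(x)
}
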