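#' Single spectrum on a wavenumber axis
#'
#' @param axis a [wn_axis].
#' @param intensities numeric vector of intensities (a.u.), same length as the
#'   axis; all finite. Negative values are allowed (baseline-corrected data).
#' @return a `spectrum` object: list with elements `axis` and `intensities`.
#' @export
new_spectrum <- function(axis, intensities) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(axis))
    stop_domain("intensities length (", length(intensities),
                ") must equal axis length (", length(axis), ")")
  check_finite(intensities, "intensities")
  structure(list(axis = axis, intensities = intensities), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d channels, intensity range [%.4g, %.4g]\n",
              length(x$intensities), min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...,
                          xlab = expression(paste("Raman shift (", cm^-1, ")")),
                          ylab = "Intensity (a.u.)", type = "l") {
  graphics::plot(unclass(x$axis), x$intensities, type = type,
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Reference spectrum of a pesticide
#'
#' A library spectrum together with its characteristic band list, used for
#' endmember matching, similarity maps and peak-intensity profiling.
#'
#' @param name pesticide identifier (e.g. "chlorpyrifos", "thiabendazole",
#'   "thiram", "acetamiprid", or any user-defined name).
#' @param spectrum a [new_spectrum] object.
#' @param peaks data.frame with columns `center` (cm^-1) and `half_window`
#'   (cm^-1); non-empty, every center inside the axis range.
#' @return a `reference_spectrum` object.
#' @export
reference_spectrum <- function(name, spectrum, peaks) {
  stopifnot(inherits(spectrum, "spectrum"))
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0L) stop_domain("peak list must be non-empty")
  if (!all(c("center", "half_window") %in% names(peaks)))
    stop_domain("peaks needs columns `center` and `half_window`")
  rng <- range(unclass(spectrum$axis))
  if (any(peaks$center < rng[1L] | peaks$center > rng[2L]))
    stop_domain("every peak center must lie within the axis range")
  structure(list(name = as.character(name), spectrum = spectrum, peaks = peaks),
            class = "reference_spectrum")
}

#' @export
print.reference_spectrum <- function(x, ...) {
  cat(sprintf("<reference_spectrum> %s: %d channels, %d characteristic band(s) at %s cm^-1\n",
              x$name, length(x$spectrum$intensities), nrow(x$peaks),
              paste(signif(x$peaks$center, 5), collapse = ", ")))
  invisible(x)
}

#' Normalize a spectrum
#'
#' @param spec a [new_spectrum].
#' @param mode `"max"` (peak value 1), `"l2"` (unit Euclidean norm) or
#'   `"area"` (unit trapezoidal integral over the axis).
#' @return the normalized `spectrum`. Idempotent per mode.
#' @export
normalize_spectrum <- function(spec, mode = c("l2", "max", "area")) {
  mode <- match.arg(mode)
  y <- spec$intensities
  nrm <- switch(mode,
    max  = max(y),
    l2   = sqrt(sum(y^2)),
    area = trapz_axis(unclass(spec$axis), y))
  if (!is.finite(nrm) || nrm <= 0)
    stop_domain("cannot normalize: ", mode, "-norm is not positive")
  new_spectrum(spec$axis, y / nrm)
}

## trapezoidal integral on a (possibly non-uniform) axis
trapz_axis <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)

#' Resample a spectrum onto a target axis by linear interpolation
#'
#' @param spec a [new_spectrum].
#' @param target a [wn_axis] whose range lies inside the source axis range
#'   (no extrapolation).
#' @return the resampled `spectrum` on `target`.
#' @export
resample_spectrum <- function(spec, target) {
  if (!inherits(target, "wn_axis")) target <- wn_axis(target)
  src <- unclass(spec$axis); tgt <- unclass(target)
  if (min(tgt) < min(src) || max(tgt) > max(src))
    stop_domain("target axis extends beyond the source range; extrapolation is not supported")
  y <- stats::approx(src, spec$intensities, xout = tgt, method = "linear")$y
  new_spectrum(target, y)
}

#' Characteristic peak intensity in a wavenumber window
#'
#' Maximum intensity within `center +/- half_window`; the standard univariate
#' "content" read-out when unmixing is skipped (e.g. the 1380 cm^-1 band of
#' thiram).
#'
#' @param spec a [new_spectrum] (assumed baseline-corrected).
#' @param center_cm1 band center in cm^-1.
#' @param half_window_cm1 half-window in cm^-1 (default 10).
#' @return maximum intensity in the window.
#' @export
peak_intensity <- function(spec, center_cm1, half_window_cm1 = 10) {
  ax <- unclass(spec$axis)
  sel <- ax >= center_cm1 - half_window_cm1 & ax <= center_cm1 + half_window_cm1
  if (!any(sel))
    stop_domain("window [", center_cm1 - half_window_cm1, ", ",
                center_cm1 + half_window_cm1, "] does not intersect the axis")
  max(spec$intensities[sel])
}
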