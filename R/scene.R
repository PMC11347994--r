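#' Synthetic scene configuration
#'
#' Describes a synthetic depth-resolved SERS imaging experiment: the
#' wavenumber axis, the spatial grid, the pesticide components (band lists and
#' surface doses), the penetration model, the fluorescence baseline, the
#' multiplicative substrate-heterogeneity gain field, the noise level, and
#' the acquisition time points. The generator is the stand-in for raw imaging
#' data: cubes assembled from a scene follow the linear mixing model the
#' unmixing stages assume, with known ground truth.
#'
#' @param axis a [wn_axis]; default 400-1800 cm^-1 at 5 cm^-1 spacing.
#' @param n_depth,n_lateral grid size; defaults 41 x 20.
#' @param depth_step_um,lateral_step_um pixel spacing (um); defaults 5.
#' @param components list of components, each a list with `name`,
#'   `peaks` (data.frame `center`, `fwhm`, `amplitude`), `shape`
#'   ("lorentzian"/"gaussian") and `dose` (surface boundary concentration,
#'   a.u.). Default: chlorpyrifos + acetamiprid, the mixed-application pair.
#' @param penetration list of penetration-model parameters: `D` (diffusivity,
#'   um^2 h^-1), `k0` (max degradation rate, h^-1), `E0` (initial enzyme
#'   level), `gamma` (enzyme consumption rate), `s` (enzyme resupply rate),
#'   `surface_decay` (exponential decay rate of the surface dose, h^-1,
#'   drying/washoff of a residue that mainly stays at the surface).
#' @param baseline list `amplitude`, `center`, `width` (broad Gaussian
#'   fluorescence hump) and `slope` (linear tilt per cm^-1).
#' @param gain list `log_sd` (standard deviation of log gain) and
#'   `corr_length_um` (spatial correlation length).
#' @param target_snr_db additive-noise level expressed as the cube
#'   signal-to-noise ratio in dB (noise sd derived from the clean signal
#'   power); default 25.
#' @param times_h acquisition times (hours), strictly increasing; default the
#'   standard 10-point course 2, 4, 6, 8, 10, 12, 24, 48, 72, 96 h.
#' @param seed integer; all scene randomness derives from it.
#' @return a `scene_config` object.
#' @export
scene_config <- function(axis = build_axis(400, 1800, 281),
                         n_depth = 41L, n_lateral = 20L,
                         depth_step_um = 5, lateral_step_um = 5,
                         components = default_scene_components(),
                         penetration = list(D = 50, k0 = 2, E0 = 1,
                                            gamma = 5, s = 0.05,
                                            surface_decay = 0.05),
                         baseline = list(amplitude = 150, center = 1300,
                                         width = 500, slope = 0.02),
                         gain = list(log_sd = 0.2, corr_length_um = 10),
                         target_snr_db = 25,
                         times_h = c(2, 4, 6, 8, 10, 12, 24, 48, 72, 96),
                         seed = 1L) {
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  if (length(times_h) < 1L || any(diff(times_h) <= 0) || any(times_h < 0))
    stop_domain("times_h must be non-negative and strictly increasing")
  pen <- penetration
  for (nm in c("D", "k0", "E0", "gamma", "s", "surface_decay"))
    if (is.null(pen[[nm]]) || pen[[nm]] < 0)
      stop_domain("penetration parameter `", nm, "` must be present and >= 0")
  for (comp in components) {
    if (is.null(comp$name) || is.null(comp$peaks) || is.null(comp$dose))
      stop_domain("each component needs `name`, `peaks` and `dose`")
    if (comp$dose < 0) stop_domain("doses must be >= 0")
  }
  if (pen$D <= 0 && any(vapply(components, function(x) x$dose, 0) > 0))
    stop_domain("diffusivity D must be > 0 when any component penetrates")
  if (gain$log_sd < 0 || gain$corr_length_um < 0)
    stop_domain("gain parameters must be >= 0")
  structure(list(axis = axis, n_depth = as.integer(n_depth),
                 n_lateral = as.integer(n_lateral),
                 depth_step_um = depth_step_um, lateral_step_um = lateral_step_um,
                 components = components, penetration = pen,
                 baseline = baseline, gain = gain,
                 target_snr_db = target_snr_db,
                 times_h = times_h, seed = as.integer(seed)),
            class = "scene_config")
}

#' Default two-pesticide component set
#'
#' Chlorpyrifos and acetamiprid band lists (Lorentzian centers/FWHMs/
#' amplitudes chosen as plausible SERS fingerprints with distinct
#' characteristic bands) and unit-order surface doses. Each component may
#' carry a `penetration` list overriding scene-level penetration parameters
#' — the defaults make chlorpyrifos behave as the contact (non-systemic)
#' pesticide (shallower diffusion, faster surface washoff) and acetamiprid
#' as the systemic one (deeper, persistent), so their depth-time
#' concentration fields differ in shape and the factorization is
#' well-posed.
#' @return list of component descriptions for [scene_config].
#' @export
default_scene_components <- function() {
  list(
    list(name = "chlorpyrifos",
         peaks = data.frame(center    = c(630, 975, 1240, 1450),
                            fwhm      = c(14, 12, 16, 18),
                            amplitude = c(600, 400, 500, 300)),
         shape = "lorentzian", dose = 1.0,
         penetration = list(D = 30, surface_decay = 0.08)),
    list(name = "acetamiprid",
         peaks = data.frame(center    = c(770, 1109, 1366, 1580),
                            fwhm      = c(12, 14, 14, 16),
                            amplitude = c(300, 500, 450, 700)),
         shape = "lorentzian", dose = 0.8,
         penetration = list(D = 50, surface_decay = 0.02)))
}

#' Built-in pesticide reference library
#'
#' Reference spectra for the four pesticides of the study (chlorpyrifos,
#' thiabendazole, thiram, acetamiprid) synthesized from their band lists on a
#' given axis. Thiram carries its characteristic 1380 cm^-1 band.
#'
#' @param axis a [wn_axis].
#' @param names subset of pesticide names to return.
#' @return named list of [reference_spectrum] objects.
#' @export
pesticide_library <- function(axis = build_axis(400, 1800, 281),
                              names = c("chlorpyrifos", "thiabendazole",
                                        "thiram", "acetamiprid")) {
  bands <- list(
    chlorpyrifos  = data.frame(center = c(630, 975, 1240, 1450),
                               fwhm = c(14, 12, 16, 18),
                               amplitude = c(600, 400, 500, 300)),
    thiabendazole = data.frame(center = c(782, 1010, 1276, 1592),
                               fwhm = c(12, 12, 14, 16),
                               amplitude = c(700, 450, 500, 400)),
    thiram        = data.frame(center = c(560, 1145, 1380, 1510),
                               fwhm = c(14, 12, 14, 16),
                               amplitude = c(600, 400, 1000, 300)),
    acetamiprid   = data.frame(center = c(770, 1109, 1366, 1580),
                               fwhm = c(12, 14, 14, 16),
                               amplitude = c(300, 500, 450, 700)))
  out <- lapply(names, function(nm) {
    b <- bands[[nm]]
    if (is.null(b)) stop_domain("unknown pesticide: ", nm)
    make_reference_spectrum(b, axis, shape = "lorentzian", name = nm)
  })
  stats::setNames(out, names)
}

#' Synthesize a reference spectrum from a band list
#'
#' Intensity is the superposition of Lorentzian (default, the Raman
#' convention) or Gaussian bands; the recorded peak list uses
#' half-window = FWHM.
#'
#' @param peaks data.frame with columns `center` (cm^-1), `fwhm` (cm^-1, > 0)
#'   and `amplitude` (peak height, a.u.); non-empty, centers inside the axis.
#' @param axis a [wn_axis].
#' @param shape `"lorentzian"` or `"gaussian"`.
#' @param name identifier for the resulting [reference_spectrum].
#' @return a [reference_spectrum].
#' @export
make_reference_spectrum <- function(peaks, axis, shape = c("lorentzian", "gaussian"),
                                    name = "reference") {
  shape <- match.arg(shape)
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0L) stop_domain("band list must be non-empty")
  if (any(peaks$fwhm <= 0)) stop_domain("FWHM must be > 0")
  if (!inherits(axis, "wn_axis")) axis <- wn_axis(axis)
  rng <- range(unclass(axis))
  if (any(peaks$center < rng[1L] | peaks$center > rng[2L]))
    stop_domain("band center outside the axis range")
  y <- band_superposition(unclass(axis), peaks, shape)
  reference_spectrum(name, new_spectrum(axis, y),
                     data.frame(center = peaks$center, half_window = peaks$fwhm))
}

## unit-peak-height band profiles
band_superposition <- function(nu, peaks, shape) {
  y <- numeric(length(nu))
  for (i in seq_len(nrow(peaks))) {
    c0 <- peaks$center[i]; w <- peaks$fwhm[i]; a <- peaks$amplitude[i]
    y <- y + if (shape == "lorentzian") {
      hw <- w / 2
      a * hw^2 / ((nu - c0)^2 + hw^2)
    } else {
      s <- w / (2 * sqrt(2 * log(2)))
      a * exp(-(nu - c0)^2 / (2 * s^2))
    }
  }
  y
}

## fluorescence baseline profile of a scene on its axis
scene_baseline <- function(scene) {
  nu <- unclass(scene$axis)
  b <- scene$baseline
  b$amplitude * exp(-(nu - b$center)^2 / (2 * b$width^2)) +
    b$slope * (nu - nu[1L])
}

#' Multiplicative substrate-heterogeneity gain field
#'
#' Emulates the image bias induced by an uneven enhancing substrate: a
#' positive multiplicative field with lognormal marginals (log sd
#' `gain$log_sd`), spatially correlated at `gain$corr_length_um`, and unit
#' mean in expectation. `log_sd = 0` gives an all-ones field.
#'
#' @param scene a [scene_config].
#' @param seed integer seed (default: derived from the scene seed).
#' @return `n_depth x n_lateral` matrix of positive gains.
#' @export
make_gain_field <- function(scene, seed = sub_seed(scene$seed, 77L)) {
  nd <- scene$n_depth; nl <- scene$n_lateral
  sd_log <- scene$gain$log_sd
  if (sd_log == 0) return(matrix(1, nd, nl))
  z <- with_seed(seed, matrix(stats::rnorm(nd * nl), nd, nl))
  sig_d <- scene$gain$corr_length_um / scene$depth_step_um
  sig_l <- scene$gain$corr_length_um / scene$lateral_step_um
  z <- gauss_smooth_mat(z, sig_d, sig_l)
  ## standardize the log-field so the sample log-sd equals the target and the
  ## lognormal mean is 1
  z <- (z - mean(z)) / stats::sd(z)
  exp(z * sd_log - sd_log^2 / 2)
}

## separable Gaussian smoothing with reflecting boundaries
gauss_smooth_mat <- function(z, sigma_row, sigma_col) {
  smooth1 <- function(m, sigma) {
    if (sigma <= 0 || nrow(m) == 1L) return(m)
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
    n <- nrow(m)
    idx <- outer(seq_len(n), -r:r, "+")
    idx <- abs(idx - 1L) %% (2L * n - 2L) + 1L          # reflect
    idx[idx > n] <- 2L * n - idx[idx > n]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(smooth1(t(smooth1(z, sigma_row)), sigma_col))
}
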