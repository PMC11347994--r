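#' Assemble a synthetic hyperspectral cube at one time point
#'
#' Pixel spectra follow the linear mixing model the unmixing stages assume:
#' `gain(z, x) * (sum_comp c_comp(z, t) * S_comp(nu) + baseline(nu)) + eps`,
#' with `eps ~ N(0, noise_sd^2)` and `noise_sd` derived from the scene's
#' target SNR. The concentration of each component comes from
#' [simulate_penetration_field]; ground truth (per-pixel mixing coefficients
#' including the gain, the gain field, the noise sd and the clean signal) is
#' returned alongside. Fully determined by the scene seed and the time index.
#'
#' @param scene a [scene_config].
#' @param time_h one of the scene's time points.
#' @param fields optional precomputed list of `concentration_field`s (one per
#'   component) to avoid re-solving the PDE per time point.
#' @return list with elements `map` (a [hypermap]), `truth` (list `C`
#'   (n_pixels x n_components mixing coefficients, gain included), `S`
#'   (component spectra matrix), `concentration` (n_depth x n_components),
#'   `gain`, `baseline`, `noise_sd`).
#' @export
assemble_hypermap <- function(scene, time_h, fields = NULL) {
  ti <- match(TRUE, abs(scene$times_h - time_h) < 1e-9)
  if (is.na(ti)) stop_domain("time_h must be one of the scene time points")
  ncomp <- length(scene$components)
  if (is.null(fields))
    fields <- lapply(seq_len(ncomp), function(j)
      simulate_penetration_field(scene, j))
  conc <- vapply(fields, function(f) f$values[ti, ], numeric(scene$n_depth))
  conc <- matrix(conc, ncol = ncomp)
  S <- t(vapply(scene$components, function(comp)
    band_superposition(unclass(scene$axis), comp$peaks,
                       match.arg(comp$shape, c("lorentzian", "gaussian"))),
    numeric(length(scene$axis))))
  bl <- scene_baseline(scene)
  gain <- make_gain_field(scene, seed = sub_seed(scene$seed, 100L + ti))
  nd <- scene$n_depth; nl <- scene$n_lateral
  npx <- nd * nl
  ## per-pixel mixing coefficients: row-major (depth, lateral)
  conc_px <- conc[rep(seq_len(nd), each = nl), , drop = FALSE]
  gain_px <- as.numeric(t(gain))   # row-major by (depth, lateral)
  C_true <- conc_px * gain_px
  clean <- C_true %*% S + gain_px %*% t(bl)
  noise_sd <- if (is.null(scene$target_snr_db) || !is.finite(scene$target_snr_db)) 0
  else sqrt(mean(clean^2) / 10^(scene$target_snr_db / 10))
  eps <- with_seed(sub_seed(scene$seed, 500L + ti),
                   matrix(stats::rnorm(npx * ncol(clean), sd = noise_sd),
                          npx, ncol(clean)))
  X <- clean + if (noise_sd > 0) eps else 0
  map <- hypermap(X, scene$axis, nd, nl, scene$depth_step_um,
                  scene$lateral_step_um, time_h,
                  metadata = list(synthetic = TRUE, seed = scene$seed))
  list(map = map,
       truth = list(C = C_true, S = S, concentration = conc, gain = gain,
                    baseline = bl, noise_sd = noise_sd, clean = clean))
}

#' Labeled spectral dataset
#'
#' Container for the classification stage: spectra matrix, class labels,
#' optional per-spectrum group (sample/crop identifier) and provenance.
#'
#' @param X numeric matrix, spectra in rows.
#' @param labels character vector of class names, length `nrow(X)`.
#' @param group optional per-spectrum group identifier.
#' @param axis optional [wn_axis].
#' @param provenance `"synthetic"` or `"curated"`.
#' @return a `spectra_dataset` object.
#' @export
spectra_dataset <- function(X, labels, group = NULL, axis = NULL,
                            provenance = c("synthetic", "curated")) {
  provenance <- match.arg(provenance)
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop_domain("labels length must equal the number of spectra")
  if (!is.null(group) && length(group) != nrow(X))
    stop_domain("group length must equal the number of spectra")
  structure(list(X = X, labels = labels, group = group, axis = axis,
                 provenance = provenance),
            class = "spectra_dataset")
}

#' @export
print.spectra_dataset <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<spectra_dataset> %d spectra x %d channels (%s): %s\n",
              nrow(x$X), ncol(x$X), x$provenance,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Generate labeled spectra for classifier training
#'
#' For each pesticide class, spectra are `dose * reference + baseline +
#' noise` with the dose drawn log-uniformly from `dose_range`; the
#' `"background"` class is baseline + noise only. The noise sd derives from
#' the scene target SNR applied to the mean clean signal power. Rows are
#' shuffled deterministically by `seed`.
#'
#' @param scene a [scene_config].
#' @param n_per_class spectra per class (>= 1).
#' @param classes class names: component names of the scene plus
#'   `"background"`.
#' @param seed integer seed; default the scene seed.
#' @param dose_range log-uniform dose range (default 0.3 to 3, spanning an
#'   order of magnitude around the unit surface dose).
#' @param n_groups optional number of synthetic sample groups to attach
#'   (cyclically) for proportional-score evaluation.
#' @return a [spectra_dataset] with provenance `"synthetic"`.
#' @export
make_labeled_spectra <- function(scene, n_per_class, classes = NULL,
                                 seed = scene$seed,
                                 dose_range = c(0.3, 3), n_groups = NULL) {
  if (n_per_class < 1) stop_domain("n_per_class must be >= 1")
  comp_names <- vapply(scene$components, function(x) x$name, "")
  if (is.null(classes)) classes <- c(comp_names, "background")
  unknown <- setdiff(classes, c(comp_names, "background"))
  if (length(unknown))
    stop_domain("unknown class name(s): ", paste(unknown, collapse = ", "))
  nu <- unclass(scene$axis)
  bl <- scene_baseline(scene)
  Sl <- lapply(scene$components, function(comp)
    band_superposition(nu, comp$peaks,
                       match.arg(comp$shape, c("lorentzian", "gaussian"))))
  names(Sl) <- comp_names
  n_total <- n_per_class * length(classes)
  clean <- matrix(0, n_total, length(nu))
  labels <- character(n_total)
  with_seed(sub_seed(seed, 900L), {
    row <- 0L
    for (cl in classes) {
      doses <- exp(stats::runif(n_per_class, log(dose_range[1L]), log(dose_range[2L])))
      for (i in seq_len(n_per_class)) {
        row <- row + 1L
        labels[row] <- cl
        clean[row, ] <- bl + if (cl == "background") 0 else doses[i] * Sl[[cl]]
      }
    }
    noise_sd <- if (is.null(scene$target_snr_db) || !is.finite(scene$target_snr_db)) 0
    else sqrt(mean(clean^2) / 10^(scene$target_snr_db / 10))
    X <- clean + if (noise_sd > 0)
      matrix(stats::rnorm(length(clean), sd = noise_sd), nrow(clean)) else 0
    ord <- sample.int(n_total)
    group <- if (is.null(n_groups)) NULL
    else paste0("sample", (seq_len(n_total) - 1L) %% n_groups + 1L)[ord]
    spectra_dataset(X[ord, , drop = FALSE], labels[ord], group = group,
                    axis = scene$axis, provenance = "synthetic")
  })
}
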