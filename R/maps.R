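#' Pearson similarity of two spectra
#'
#' Pearson correlation of the intensity vectors; bounded in `[-1, 1]` and
#' scale/offset free, the default similarity behind the 0.8 / 0.5 labeling
#' thresholds.
#'
#' @param a,b [new_spectrum] objects or numeric vectors of equal length;
#'   both with nonzero variance.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_similarity <- function(a, b) {
  va <- if (inherits(a, "spectrum")) a$intensities else as.numeric(a)
  vb <- if (inherits(b, "spectrum")) b$intensities else as.numeric(b)
  if (length(va) != length(vb)) stop_domain("spectra must have equal length")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop_domain("Pearson similarity undefined for a zero-variance spectrum")
  as.numeric(stats::cor(va, vb))
}

#' Euclidean distance between spectra and its similarity transform
#'
#' `euclidean_distance` is the plain L2 distance, optionally after l2
#' normalization of both spectra (the default in mapping, so the similarity
#' has a fixed usable range). `ed_to_similarity` maps a distance to
#' `1 / (1 + d)`, strictly decreasing, equal to 1 iff `d = 0`.
#'
#' @param a,b [new_spectrum] objects or numeric vectors of equal length.
#' @param normalize l2-normalize both spectra first (both must be non-zero).
#' @return non-negative distance.
#' @export
euclidean_distance <- function(a, b, normalize = TRUE) {
  va <- if (inherits(a, "spectrum")) a$intensities else as.numeric(a)
  vb <- if (inherits(b, "spectrum")) b$intensities else as.numeric(b)
  if (length(va) != length(vb)) stop_domain("spectra must have equal length")
  if (normalize) {
    na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
    if (na == 0 || nb == 0) stop_domain("cannot l2-normalize a zero spectrum")
    va <- va / na; vb <- vb / nb
  }
  sqrt(sum((va - vb)^2))
}

#' @rdname euclidean_distance
#' @param d non-negative distance.
#' @export
ed_to_similarity <- function(d) {
  if (any(d < 0)) stop_domain("distance must be >= 0")
  1 / (1 + d)
}

#' Per-pixel similarity map of a cube against a reference
#'
#' Each pixel spectrum is compared to the reference with the chosen metric
#' (Pearson correlation, or Euclidean-distance similarity `1/(1+d)` on
#' l2-normalized spectra). Spectra are expected baseline-corrected; set
#' `baseline = TRUE` to correct on the fly.
#'
#' @param cube a [hypermap]; its axis must equal the reference axis
#'   (resample first otherwise).
#' @param ref a [reference_spectrum], or an [endmember_set] row passed as a
#'   [new_spectrum] — matching against the VCA-extracted endmember is the
#'   default pipeline route.
#' @param metric `"pearson"` or `"ed"`.
#' @param baseline correct each pixel with [baseline_correct] first
#'   (default FALSE).
#' @param cfg a [pipeline_config] supplying baseline parameters.
#' @return a `similarity_map`: list with `values` (`n_depth x n_lateral`
#'   matrix), `metric`, `reference` name.
#' @export
similarity_map <- function(cube, ref, metric = c("pearson", "ed"),
                           baseline = FALSE, cfg = pipeline_config()) {
  metric <- match.arg(metric)
  stopifnot(inherits(cube, "hypermap"))
  ref_spec <- if (inherits(ref, "reference_spectrum")) ref$spectrum
  else if (inherits(ref, "spectrum")) ref
  else stop_domain("ref must be a reference_spectrum or spectrum")
  ref_name <- if (inherits(ref, "reference_spectrum")) ref$name else "reference"
  if (length(cube$axis) != length(ref_spec$axis) ||
      max(abs(unclass(cube$axis) - unclass(ref_spec$axis))) > 1e-9)
    stop_domain("cube and reference axes differ: resample the reference ",
                "onto the cube axis with resample_spectrum() first")
  X <- cube$spectra
  if (baseline)
    X <- baseline_correct_cube(cube, cfg$baseline_smoothness,
                               cfg$baseline_asymmetry, cfg$baseline_iter)$spectra
  r <- ref_spec$intensities
  vals <- if (metric == "pearson") {
    rs <- stats::sd(r)
    if (rs == 0) stop_domain("reference has zero variance")
    as.numeric(stats::cor(t(X), r))
  } else {
    rn <- r / sqrt(sum(r^2))
    Xn <- X / sqrt(rowSums(X^2))
    d <- sqrt(pmax(rowSums(sweep(Xn, 2L, rn)^2), 0))
    d[!is.finite(d)] <- Inf            # zero-norm pixels: maximally distant
    ed_to_similarity(d)
  }
  vals[!is.finite(vals)] <- 0     # zero-variance or zero-norm pixels
  structure(list(values = matrix(vals, cube$n_depth, cube$n_lateral, byrow = TRUE),
                 metric = metric, reference = ref_name,
                 depth_step_um = cube$depth_step_um,
                 lateral_step_um = cube$lateral_step_um,
                 time_h = cube$time_h),
            class = "similarity_map")
}

#' @export
print.similarity_map <- function(x, ...) {
  cat(sprintf("<similarity_map> %s vs %s: %d x %d pixels, range [%.3f, %.3f]\n",
              x$metric, x$reference, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.similarity_map <- function(x, ...) {
  ## red = similar to the pesticide, blue = dissimilar
  graphics::image(seq_len(ncol(x$values)) * x$lateral_step_um,
                  seq_len(nrow(x$values)) * x$depth_step_um,
                  t(x$values)[, rev(seq_len(nrow(x$values))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "Lateral (um)", ylab = "Depth (um)",
                  main = sprintf("Similarity to %s (%s)", x$reference, x$metric), ...)
  invisible(x)
}

#' Threshold a similarity map into pesticide / suspected / background
#'
#' A pixel is `"pesticide"` when its similarity is strictly greater than
#' `pesticide_threshold` (default 0.8); `"suspected"` (interpreted as
#' partially metabolized pesticide) when it lies in
#' `[suspected_threshold, pesticide_threshold]` (boundaries inclusive, so
#' exactly 0.8 is suspected); otherwise `"background"`.
#'
#' @param sim a `similarity_map` (or plain numeric matrix/vector).
#' @param cfg a [pipeline_config].
#' @return a `label_map`: list with `labels` (character matrix), `categories`,
#'   `color_values` (integer matrix: background 0, suspected 1, pesticide 2).
#' @export
classify_similarity <- function(sim, cfg = pipeline_config()) {
  v <- if (inherits(sim, "similarity_map")) sim$values else sim
  lab <- ifelse(v > cfg$pesticide_threshold, "pesticide",
                ifelse(v >= cfg$suspected_threshold, "suspected", "background"))
  codes <- matrix(match(lab, c("background", "suspected", "pesticide")) - 1L,
                  nrow(as.matrix(v)), ncol(as.matrix(v)))
  structure(list(labels = lab,
                 categories = c("background", "suspected", "pesticide"),
                 color_values = codes,
                 reference = if (inherits(sim, "similarity_map")) sim$reference else NULL),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$categories))
  cat(sprintf("<label_map>%s %s\n",
              if (!is.null(x$reference)) paste0(" [", x$reference, "]") else "",
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Mixed-pesticide overlap map
#'
#' Classifies every pixel independently against two references with the
#' Euclidean-distance similarity at `pesticide_threshold`, then encodes the
#' outcome additively with the configured color codes: none -> 0, A only ->
#' `codeA` (default 10), B only -> `codeB` (default 20), both ->
#' `codeA + codeB` (default 30).
#'
#' @param cube a [hypermap].
#' @param refA,refB distinct [reference_spectrum] objects (or spectra, e.g.
#'   matched VCA endmembers).
#' @param cfg a [pipeline_config] (thresholds and color codes).
#' @return a `label_map` whose `color_values` matrix takes values in
#'   `{0, codeA, codeB, codeA + codeB}`; `labels` in
#'   `{"none", "A", "B", "A+B"}`.
#' @export
mixed_overlap_map <- function(cube, refA, refB, cfg = pipeline_config()) {
  sA <- if (inherits(refA, "reference_spectrum")) refA$spectrum$intensities
  else refA$intensities
  sB <- if (inherits(refB, "reference_spectrum")) refB$spectrum$intensities
  else refB$intensities
  if (length(sA) == length(sB) && max(abs(sA - sB)) < 1e-12)
    stop_domain("the two references are identical")
  simA <- similarity_map(cube, refA, metric = "ed")$values
  simB <- similarity_map(cube, refB, metric = "ed")$values
  presA <- simA > cfg$pesticide_threshold
  presB <- simB > cfg$pesticide_threshold
  codeA <- unname(cfg$color_codes["pesticide_a"])
  codeB <- unname(cfg$color_codes["pesticide_b"])
  code0 <- unname(cfg$color_codes["none"])
  vals <- code0 + codeA * presA + codeB * presB
  lab <- matrix("none", nrow(vals), ncol(vals))
  lab[presA & !presB] <- "A"
  lab[!presA & presB] <- "B"
  lab[presA & presB] <- "A+B"
  nmA <- if (inherits(refA, "reference_spectrum")) refA$name else "A"
  nmB <- if (inherits(refB, "reference_spectrum")) refB$name else "B"
  structure(list(labels = lab, categories = c("none", "A", "B", "A+B"),
                 color_values = vals,
                 reference = paste(nmA, nmB, sep = " + "),
                 code_set = c(code0, codeA, codeB, codeA + codeB)),
            class = "label_map")
}
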