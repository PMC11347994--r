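#' Pipeline configuration
#'
#' Central knobs shared by the mapping and classification stages: the
#' similarity thresholds (a pixel is called a pesticide when its similarity
#' exceeds `pesticide_threshold`; between `suspected_threshold` and
#' `pesticide_threshold` it is "suspected", interpreted as partially
#' metabolized pesticide), the overlap-map color codes, the training fraction
#' of the classifier stage, and baseline-correction parameters.
#'
#' @param pesticide_threshold similarity cutoff above which a pixel is called
#'   pesticide (default 0.8; the call is strict: exactly 0.8 is "suspected").
#' @param suspected_threshold lower cutoff of the suspected band (default 0.5);
#'   must satisfy `0 <= suspected_threshold < pesticide_threshold <= 1`.
#' @param color_codes named numeric vector of overlap-map codes,
#'   `c(none = 0, pesticide_a = 10, pesticide_b = 20)`; codes must be distinct
#'   and non-negative. Overlapping pixels get the sum of the two codes.
#' @param train_fraction fraction of spectra used for training (default 0.7).
#' @param n_endmembers number of VCA endmembers; default = expected pesticides
#'   + 1 for the fluorescence background.
#' @param baseline_smoothness,baseline_asymmetry,baseline_iter AsLS baseline
#'   parameters (see [baseline_correct]).
#' @param seed integer seed from which all stage randomness derives.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(pesticide_threshold = 0.8,
                            suspected_threshold = 0.5,
                            color_codes = c(none = 0, pesticide_a = 10, pesticide_b = 20),
                            train_fraction = 0.7,
                            n_endmembers = 3L,
                            baseline_smoothness = 1e5,
                            baseline_asymmetry = 0.01,
                            baseline_iter = 10L,
                            seed = 1L) {
  check_scalar_num(pesticide_threshold, "pesticide_threshold", 0, 1)
  check_scalar_num(suspected_threshold, "suspected_threshold", 0, 1)
  if (!(suspected_threshold < pesticide_threshold))
    stop_domain("config error: need 0 <= suspected_threshold < pesticide_threshold <= 1")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop_domain("config error: train_fraction must lie in (0, 1)")
  if (any(color_codes < 0) || anyDuplicated(color_codes))
    stop_domain("config error: color codes must be distinct and non-negative")
  if (n_endmembers < 1) stop_domain("config error: n_endmembers must be >= 1")
  structure(list(pesticide_threshold = pesticide_threshold,
                 suspected_threshold = suspected_threshold,
                 color_codes = color_codes,
                 train_fraction = train_fraction,
                 n_endmembers = as.integer(n_endmembers),
                 baseline_smoothness = baseline_smoothness,
                 baseline_asymmetry = baseline_asymmetry,
                 baseline_iter = as.integer(baseline_iter),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  cat(sprintf("  similarity thresholds: pesticide > %.3g, suspected [%.3g, %.3g]\n",
              x$pesticide_threshold, x$suspected_threshold, x$pesticide_threshold))
  cat(sprintf("  overlap codes: %s\n",
              paste(names(x$color_codes), x$color_codes, sep = "=", collapse = ", ")))
  cat(sprintf("  train fraction %.2f, %d endmembers, seed %d\n",
              x$train_fraction, x$n_endmembers, x$seed))
  invisible(x)
}
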