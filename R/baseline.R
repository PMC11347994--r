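#' Asymmetric-least-squares baseline correction
#'
#' Estimates a smooth fluorescence background with a Whittaker smoother under
#' asymmetric weights (AsLS): points above the running baseline get weight
#' `asymmetry`, points below get `1 - asymmetry`, and the baseline minimizes
#' the weighted residual plus a second-difference roughness penalty of
#' strength `smoothness`. The standard choice for broad Raman/SERS
#' fluorescence backgrounds.
#'
#' @param spec a [new_spectrum] (or numeric vector when `axis` is given).
#' @param smoothness penalty weight lambda (> 0); default 1e5.
#' @param asymmetry weight p in (0, 1) for points above the baseline;
#'   default 0.01.
#' @param n_iter number of reweighting iterations (>= 1); default 10.
#' @param return_baseline if TRUE, return a list with the corrected spectrum
#'   and the estimated baseline.
#' @return the baseline-corrected `spectrum` (input minus estimated baseline),
#'   or a list `(corrected, baseline)` when `return_baseline = TRUE`.
#' @details Correction is translation-equivariant: adding a constant to the
#'   input moves the baseline by the same constant, leaving the corrected
#'   spectrum unchanged. Negative residuals are retained, not clipped.
#' @export
baseline_correct <- function(spec, smoothness = 1e5, asymmetry = 0.01,
                             n_iter = 10, return_baseline = FALSE) {
  stopifnot(inherits(spec, "spectrum"))
  check_scalar_num(smoothness, "smoothness", lower = .Machine$double.eps)
  if (!is.numeric(asymmetry) || asymmetry <= 0 || asymmetry >= 1)
    stop_domain("asymmetry must lie strictly in (0, 1)")
  if (n_iter < 1) stop_domain("n_iter must be >= 1")
  y <- spec$intensities
  check_finite(y, "spectrum intensities")
  z <- whittaker_asls(y, lambda = smoothness, p = asymmetry, n_iter = n_iter)
  corrected <- new_spectrum(spec$axis, y - z)
  if (return_baseline) list(corrected = corrected, baseline = new_spectrum(spec$axis, z))
  else corrected
}

## Whittaker smoother with asymmetric reweighting. Sparse banded system
## (W + lambda D'D) z = W y solved per iteration.
whittaker_asls <- function(y, lambda, p, n_iter) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2L, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2L), rep(-2, m - 2L), rep(1, m - 2L)))
  DtD <- Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (i in seq_len(n_iter)) {
    W <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(W + lambda * DtD, w * y))
    w_new <- ifelse(y > z, p, 1 - p)
    if (identical(w_new, w) && i > 1L) break
    w <- w_new
  }
  z
}

#' Baseline-correct every pixel spectrum of a cube
#'
#' @param cube a [hypermap].
#' @inheritParams baseline_correct
#' @return a new `hypermap` with corrected spectra.
#' @export
baseline_correct_cube <- function(cube, smoothness = 1e5, asymmetry = 0.01,
                                  n_iter = 10) {
  stopifnot(inherits(cube, "hypermap"))
  X <- cube$spectra
  for (i in seq_len(nrow(X))) {
    X[i, ] <- X[i, ] - whittaker_asls(X[i, ], lambda = smoothness,
                                      p = asymmetry, n_iter = n_iter)
  }
  cube$spectra <- X
  cube
}
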