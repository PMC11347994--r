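#' MCR-ALS non-negative bilinear factorization
#'
#' Refines an initial endmember matrix by multivariate curve resolution with
#' alternating least squares: exact non-negative least-squares solves of
#' `C` given `S` (per pixel) and `S` given `C` (per channel), with each `S`
#' row rescaled to unit maximum after every S-step (the scale is absorbed
#' into `C`, leaving the reconstruction `C S` unchanged). Iteration stops
#' when the relative change of the lack of fit (LOF) drops below `tol` or
#' after `max_iter` iterations. Both sub-solves are exact minimizers, so the
#' LOF trace is non-increasing.
#'
#' This is the quantification stage of the imaging pipeline: initialized
#' from VCA endmembers, the refined per-pixel coefficients of the matched
#' pesticide component are its relative local content.
#'
#' @param X spectral matrix (pixels x channels) or a [hypermap]; must not be
#'   all zero. Negative intensities (from baseline correction) are clipped
#'   to zero, honoring the non-negativity model.
#' @param S_init initial endmembers: an [endmember_set] or a matrix with
#'   endmembers in rows; no zero rows.
#' @param tol relative LOF-change stopping threshold (default 1e-6).
#' @param max_iter maximum iterations (default 200).
#' @return an object of class `mcr_fit`: list with `C` (abundance matrix,
#'   pixels x p), `S` (endmember matrix, p x channels, rows scaled to max 1),
#'   `lof_trace` (LOF percent per iteration, position 1 = after the first
#'   C-step), `n_iter`, `converged`, `names` (endmember labels, if any),
#'   `grid` (cube geometry when `X` was a [hypermap]), `axis`.
#' @seealso [lack_of_fit], [run_vca]; methods: [print.mcr_fit],
#'   [summary.mcr_fit], [coef.mcr_fit], [fitted.mcr_fit],
#'   [residuals.mcr_fit], [predict.mcr_fit], [plot.mcr_fit].
#' @export
run_mcr_als <- function(X, S_init, tol = 1e-6, max_iter = 200L) {
  grid <- NULL; axis <- NULL
  if (inherits(X, "hypermap")) {
    grid <- list(n_depth = X$n_depth, n_lateral = X$n_lateral,
                 depth_step_um = X$depth_step_um,
                 lateral_step_um = X$lateral_step_um, time_h = X$time_h)
    axis <- X$axis
    X <- X$spectra
  }
  X <- as.matrix(X)
  X[X < 0] <- 0
  if (sum(X^2) == 0) stop_domain("degenerate input: all-zero spectral matrix")
  nms <- NULL
  S <- if (inherits(S_init, "endmember_set")) { nms <- S_init$names; S_init$S }
  else as.matrix(S_init)
  if (any(rowSums(abs(S)) == 0)) stop_domain("S_init must have no zero rows")
  S[S < 0] <- 0
  if (tol <= 0) stop_domain("tol must be > 0")
  if (max_iter < 1) stop_domain("max_iter must be >= 1")

  sumX2 <- sum(X^2)
  lof_trace <- numeric(0)
  converged <- FALSE
  C <- NULL
  for (it in seq_len(max_iter)) {
    C <- nnls_multi(X, S)                         # C-step, exact per pixel
    S <- t(nnls_multi(t(X), t(C)))                # S-step, exact per channel
    ## scale ambiguity: S rows to unit max, scale absorbed into C
    sc <- apply(S, 1L, max)
    sc[sc <= 0] <- 1
    S <- S / sc
    C <- sweep(C, 2L, sc, "*")
    lof <- 100 * sqrt(sum((X - C %*% S)^2) / sumX2)
    lof_trace <- c(lof_trace, lof)
    if (it > 1L) {
      prev <- lof_trace[it - 1L]
      if (prev == 0 || abs(prev - lof) / max(prev, .Machine$double.eps) < tol) {
        converged <- TRUE
        break
      }
    } else if (lof < 1e-9) { converged <- TRUE; break }
  }
  colnames(C) <- nms
  structure(list(C = C, S = S, lof_trace = lof_trace,
                 n_iter = length(lof_trace), converged = converged,
                 names = nms, grid = grid, axis = axis, sumX2 = sumX2),
            class = "mcr_fit")
}

#' Lack of fit of a bilinear factorization
#'
#' The standard MCR diagnostic `100 * sqrt(sum((X - C S)^2) / sum(X^2))`, in
#' percent; 0 iff the factorization is exact.
#'
#' @param X data matrix (pixels x channels); must not be all zero.
#' @param C abundance matrix (pixels x p).
#' @param S endmember matrix (p x channels).
#' @return LOF percentage in `[0, Inf)`.
#' @export
lack_of_fit <- function(X, C, S) {
  X <- as.matrix(X); C <- as.matrix(C); S <- as.matrix(S)
  if (ncol(C) != nrow(S) || nrow(C) != nrow(X) || ncol(S) != ncol(X))
    stop_domain("nonconformable shapes for lack_of_fit")
  sumX2 <- sum(X^2)
  if (sumX2 == 0) stop_domain("lack of fit undefined for an all-zero matrix")
  100 * sqrt(sum((X - C %*% S)^2) / sumX2)
}

#' @export
print.mcr_fit <- function(x, ...) {
  cat(sprintf("MCR-ALS fit: %d pixels x %d channels, %d components\n",
              nrow(x$C), ncol(x$S), nrow(x$S)))
  cat(sprintf("  %d iteration(s), %s, final LOF %.4g%%\n", x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$lof_trace, 1L)))
  if (!is.null(x$names))
    cat("  components:", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mcr_fit <- function(object, ...) {
  tot <- colSums(object$C)
  out <- list(n_components = nrow(object$S),
              n_pixels = nrow(object$C),
              n_iter = object$n_iter,
              converged = object$converged,
              lof_final = utils::tail(object$lof_trace, 1L),
              lof_initial = object$lof_trace[1L],
              component_totals = stats::setNames(
                tot, object$names %||% paste0("em", seq_along(tot))))
  class(out) <- "summary.mcr_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.summary.mcr_fit <- function(x, ...) {
  cat(sprintf("MCR-ALS: %d components over %d pixels\n", x$n_components, x$n_pixels))
  cat(sprintf("  LOF %.4g%% -> %.4g%% in %d iteration(s) (%s)\n",
              x$lof_initial, x$lof_final, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  total abundance per component:\n")
  print(signif(x$component_totals, 4))
  invisible(x)
}

#' Extract MCR-ALS coefficients
#' @param object an `mcr_fit`.
#' @param which `"C"` (per-pixel abundances, default) or `"S"` (endmember
#'   spectra).
#' @param ... unused.
#' @export
coef.mcr_fit <- function(object, which = c("C", "S"), ...) {
  which <- match.arg(which)
  if (which == "C") object$C else object$S
}

#' Reconstructed data matrix `C S`
#' @param object an `mcr_fit`.
#' @param ... unused.
#' @export
fitted.mcr_fit <- function(object, ...) object$C %*% object$S

#' Residuals of the factorization
#'
#' Requires the original data: residuals are computed against `newdata` (the
#' matrix or cube the model was fitted to).
#' @param object an `mcr_fit`.
#' @param newdata the fitted data matrix or [hypermap].
#' @param ... unused.
#' @export
residuals.mcr_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "hypermap")) newdata$spectra else as.matrix(newdata)
  X[X < 0] <- 0
  X - fitted(object)
}

#' Project new spectra onto the fitted endmembers
#'
#' Per-row exact NNLS of new pixel spectra against the fitted `S`, the MCR
#' analogue of predicting scores for new observations.
#' @param object an `mcr_fit`.
#' @param newdata matrix of spectra (rows) or a [hypermap].
#' @param ... unused.
#' @return abundance matrix for the new spectra.
#' @export
predict.mcr_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "hypermap")) newdata$spectra else as.matrix(newdata)
  X[X < 0] <- 0
  C <- nnls_multi(X, object$S)
  colnames(C) <- object$names
  C
}

#' Plot an MCR-ALS fit
#'
#' Left panel: LOF convergence trace; right panel: resolved endmember
#' spectra (and, when cube geometry is known, the abundance image of
#' `component` below, high content drawn in blue).
#' @param x an `mcr_fit`.
#' @param component component index for the abundance image.
#' @param ... passed to [graphics::matplot].
#' @export
plot.mcr_fit <- function(x, component = 1L, ...) {
  has_grid <- !is.null(x$grid)
  op <- graphics::par(mfrow = c(1L, if (has_grid) 3L else 2L))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$lof_trace), x$lof_trace, type = "b", log = "y",
                 xlab = "Iteration", ylab = "Lack of fit (%)", main = "ALS convergence")
  xs <- if (!is.null(x$axis)) as.numeric(x$axis) else seq_len(ncol(x$S))
  graphics::matplot(xs, t(x$S), type = "l", lty = 1,
                    xlab = expression(paste("Raman shift (", cm^-1, ")")),
                    ylab = "Normalized intensity", main = "Endmembers", ...)
  if (has_grid) {
    img <- matrix(x$C[, component], x$grid$n_depth, x$grid$n_lateral, byrow = TRUE)
    graphics::image(seq_len(x$grid$n_lateral) * x$grid$lateral_step_um,
                    seq_len(x$grid$n_depth) * x$grid$depth_step_um,
                    t(img)[, rev(seq_len(x$grid$n_depth)), drop = FALSE],
                    col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                    xlab = "Lateral (um)", ylab = "Depth (um)",
                    main = paste("Abundance:", x$names[component] %||% component))
  }
  invisible(x)
}
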