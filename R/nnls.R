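## Exact non-negative least squares for many right-hand sides sharing one
## small design: enumerate candidate active supports (all subsets of the p
## components), solve the unconstrained restricted problem for every row at
## once, and keep the feasible candidate with the smallest residual. The
## optimum's support is one of the subsets and its restricted solution is
## feasible, so the feasible minimum is the global optimum. Vectorized across
## rows; intended for the small p (a few endmembers) this domain uses.

## B: n x m rows to fit; A: p x m design. Returns n x p coefficients >= 0.
nnls_multi <- function(B, A) {
  B <- as.matrix(B); A <- as.matrix(A)
  p <- nrow(A)
  if (ncol(B) != ncol(A)) stop_domain("nonconformable NNLS shapes")
  if (p > 12L)
    stop_domain("support-enumeration NNLS is limited to p <= 12 components")
  n <- nrow(B)
  best_obj <- rowSums(B^2)          # empty support: all coefficients zero
  best_C <- matrix(0, n, p)
  for (mask in seq_len(2^p - 1L)) {
    J <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1L))) != 0L)
    AJ <- A[J, , drop = FALSE]
    G <- tcrossprod(AJ)             # |J| x |J|
    ok <- TRUE
    coef <- tryCatch(t(solve(G, AJ %*% t(B))),
                     error = function(e) { ok <<- FALSE; NULL })
    if (!ok) next                   # singular restricted design: skip subset
    feas <- rowSums(coef < -1e-10) == 0L
    if (!any(feas)) next
    coef[coef < 0] <- 0
    R <- B[feas, , drop = FALSE] - coef[feas, , drop = FALSE] %*% AJ
    obj <- rowSums(R^2)
    idx <- which(feas)
    better <- obj < best_obj[idx] - 1e-12 * (1 + best_obj[idx])
    upd <- idx[better]
    if (length(upd)) {
      best_obj[upd] <- obj[better]
      best_C[upd, ] <- 0
      best_C[upd, J] <- coef[feas, , drop = FALSE][better, , drop = FALSE]
    }
  }
  best_C
}

#' Per-pixel non-negative least-squares abundances
#'
#' Solves, for every pixel spectrum x, `min || x - c' S ||` subject to
#' `c >= 0`, exactly (active-support enumeration), against a fixed endmember
#' matrix. The abundances feed the content heat maps.
#'
#' @param X spectral matrix (n_pixels x n_channels) or a [hypermap].
#' @param E an [endmember_set] (or a plain endmember matrix, rows =
#'   endmembers).
#' @return an `abundance_map`: matrix (n_pixels x p) of non-negative
#'   coefficients with attribute `grid` when `X` is a [hypermap]; column
#'   names follow endmember names.
#' @export
abundance_nnls <- function(X, E) {
  grid <- NULL
  if (inherits(X, "hypermap")) {
    grid <- list(n_depth = X$n_depth, n_lateral = X$n_lateral,
                 depth_step_um = X$depth_step_um,
                 lateral_step_um = X$lateral_step_um, time_h = X$time_h)
    X <- X$spectra
  }
  S <- if (inherits(E, "endmember_set")) E$S else as.matrix(E)
  if (any(rowSums(abs(S)) == 0)) stop_domain("degenerate endmember matrix (zero row)")
  C <- nnls_multi(as.matrix(X), S)
  colnames(C) <- if (inherits(E, "endmember_set") && !is.null(E$names)) E$names
  else paste0("em", seq_len(nrow(S)))
  structure(C, class = c("abundance_map", class(C)), grid = grid)
}

#' Reshape one abundance column onto the spatial grid
#' @param C an `abundance_map` with a `grid` attribute.
#' @param j column (component) index.
#' @return `n_depth x n_lateral` matrix.
#' @export
abundance_image <- function(C, j = 1L) {
  grid <- attr(C, "grid")
  if (is.null(grid)) stop_domain("abundance map carries no grid geometry")
  matrix(C[, j], grid$n_depth, grid$n_lateral, byrow = TRUE)
}
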