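#' Endmember set
#'
#' The spectral signatures extracted by VCA (or refined by MCR-ALS): a
#' `p x n_channels` matrix, the source pixel indices when extracted from a
#' cube, and optional per-endmember labels after matching.
#'
#' @param S numeric matrix, endmembers in rows; finite, `p >= 1`.
#' @param source_pixel_indices optional integer vector of length p, no
#'   duplicates.
#' @param names optional character labels.
#' @param axis optional [wn_axis].
#' @return an `endmember_set` object.
#' @export
endmember_set <- function(S, source_pixel_indices = NULL, names = NULL,
                          axis = NULL) {
  S <- as.matrix(S)
  if (nrow(S) < 1L) stop_domain("need at least one endmember")
  check_finite(S, "endmember spectra")
  if (!is.null(source_pixel_indices)) {
    if (length(source_pixel_indices) != nrow(S))
      stop_domain("one source pixel index per endmember required")
    if (anyDuplicated(source_pixel_indices))
      stop_domain("duplicate source pixel indices")
  }
  structure(list(S = S, source_pixel_indices = source_pixel_indices,
                 names = names, axis = axis),
            class = "endmember_set")
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf("<endmember_set> %d endmembers x %d channels%s\n",
              nrow(x$S), ncol(x$S),
              if (!is.null(x$names)) paste0(": ", paste(x$names, collapse = ", "))
              else ""))
  invisible(x)
}

#' Estimate the signal-to-noise ratio of a spectral matrix
#'
#' SNR in dB from the energy captured by the rank-`p` principal subspace of
#' the mean-removed data versus the residual — the canonical switch deciding
#' the VCA projection mode. Exactly rank-`p` data returns `Inf`.
#'
#' @param X spectral matrix, pixels in rows.
#' @param p assumed number of endmembers, `p < min(n_pixels, n_channels)`.
#' @return SNR estimate in dB.
#' @export
estimate_snr <- function(X, p) {
  X <- as.matrix(X)
  N <- nrow(X); L <- ncol(X)
  if (p < 1 || p >= min(N, L)) stop_domain("p must satisfy 1 <= p < min(n_pixels, n_channels)")
  r_m <- colMeans(X)
  X0 <- sweep(X, 2L, r_m)
  sv <- svd(X0, nu = 0, nv = p)
  P_y <- sum(X^2) / N
  P_x <- sum(sv$d[seq_len(p)]^2) / N + sum(r_m^2)
  denom <- P_y - P_x
  if (denom <= 1e-12 * P_y) return(Inf)
  10 * log10(max((P_x - p / L * P_y) / denom, .Machine$double.xmin))
}

#' Vertex component analysis (VCA)
#'
#' Geometric endmember extraction: assuming every component has at least one
#' (nearly) pure pixel, the extreme points of the data simplex are found by
#' `p` iterations of projection onto directions orthogonal to the span of the
#' endmembers found so far, each time selecting the pixel with the largest
#' absolute projection. The subspace step follows the canonical rule: above
#' an SNR threshold of `15 + 10 log10(p)` dB the data are projectively
#' projected onto the rank-`p` principal subspace; below it, mean-removed
#' rank-`p-1` projection with a constant extra coordinate.
#'
#' Returned endmembers are actual pixel spectra of `X` (pure-pixel
#' property); selection ties break to the lowest pixel index and already
#' chosen pixels are excluded, so the source indices are distinct. The run is
#' deterministic given `seed` (used for the random orthogonal directions).
#'
#' @param X spectral matrix (pixels x channels) or a [hypermap].
#' @param p number of endmembers, `p <= min(n_pixels, n_channels)`.
#' @param seed integer seed.
#' @param snr_db optional externally supplied SNR (dB); default estimated by
#'   [estimate_snr].
#' @return an [endmember_set] with `source_pixel_indices`.
#' @export
run_vca <- function(X, p, seed = 1L, snr_db = NULL) {
  axis <- NULL
  if (inherits(X, "hypermap")) { axis <- X$axis; X <- X$spectra }
  X <- as.matrix(X)
  N <- nrow(X); L <- ncol(X)
  if (p < 1 || p > min(N, L)) stop_domain("p must satisfy 1 <= p <= min(n_pixels, n_channels)")
  if (all(abs(sweep(X, 2L, colMeans(X))) < 1e-12))
    stop_domain("degenerate input: all pixel spectra identical")
  Y <- t(X)                                   # L x N, canonical orientation

  if (p == 1L) {
    ## single endmember: pixel with maximal projection on the first
    ## principal direction of the data
    u1 <- svd(Y, nu = 1, nv = 0)$u[, 1L]
    k <- which.max(abs(as.numeric(crossprod(u1, Y))))
    S <- X[k, , drop = FALSE]
    return(endmember_set(flip_endmember_sign(S), source_pixel_indices = k,
                         axis = axis))
  }

  if (is.null(snr_db)) snr_db <- estimate_snr(X, min(p, min(N, L) - 1L))
  snr_th <- 15 + 10 * log10(p)

  if (snr_db > snr_th) {
    ## projective projection onto the rank-p principal subspace
    Ud <- svd(Y %*% t(Y) / N, nu = p, nv = 0)$u
    x_p <- crossprod(Ud, Y)                   # p x N
    u <- rowMeans(x_p)
    denom <- as.numeric(crossprod(u, x_p))
    denom[abs(denom) < 1e-12] <- 1e-12
    y <- sweep(x_p, 2L, denom, "/")
  } else {
    ## mean-removed rank-(p-1) projection plus a constant coordinate
    d <- p - 1L
    r_m <- rowMeans(Y)
    Y0 <- Y - r_m
    Ud <- svd(Y0 %*% t(Y0) / N, nu = d, nv = 0)$u
    x_p <- crossprod(Ud, Y0)                  # d x N
    cconst <- max(sqrt(colSums(x_p^2)))
    y <- rbind(x_p, cconst)
  }

  indice <- integer(p)
  A <- matrix(0, p, p); A[p, 1L] <- 1
  with_seed(seed, {
    for (i in seq_len(p)) {
      w <- stats::runif(p)
      f <- (diag(p) - A %*% pracma::pinv(A)) %*% w
      nf <- sqrt(sum(f^2))
      if (nf < 1e-12) f <- w else f <- f / nf
      v <- abs(as.numeric(crossprod(f, y)))
      v[indice[seq_len(i - 1L)]] <- -Inf      # distinct source pixels
      k <- which.max(v)                       # ties -> lowest index
      indice[i] <- k
      A[, i] <- y[, k]
    }
  })
  S <- X[indice, , drop = FALSE]
  endmember_set(flip_endmember_sign(S), source_pixel_indices = indice,
                axis = axis)
}

## sign convention: the channel of maximal |value| is positive
flip_endmember_sign <- function(S) {
  for (i in seq_len(nrow(S))) {
    j <- which.max(abs(S[i, ]))
    if (S[i, j] < 0) S[i, ] <- -S[i, ]
  }
  S
}

#' Spectral angle between two spectra
#'
#' `arccos` of the normalized inner product; scale-invariant dissimilarity in
#' `[0, pi]` radians.
#'
#' @param a,b [new_spectrum] objects or numeric vectors of equal length;
#'   both non-zero.
#' @return angle in radians.
#' @export
spectral_angle <- function(a, b) {
  va <- if (inherits(a, "spectrum")) a$intensities else as.numeric(a)
  vb <- if (inherits(b, "spectrum")) b$intensities else as.numeric(b)
  if (length(va) != length(vb)) stop_domain("spectra must have equal length")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop_domain("spectral angle undefined for a zero vector")
  acos(min(1, max(-1, sum(va * vb) / (na * nb))))
}

## exact minimum-cost one-to-one assignment by bitmask dynamic programming;
## cost: n1 x n2. Returns integer vector a with a[i] = assigned column of row
## i (NA if unassigned); all min(n1, n2) pairs assigned.
assignment_min <- function(cost) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  transposed <- FALSE
  if (n1 > n2) { cost <- t(cost); tmp <- n1; n1 <- n2; n2 <- tmp; transposed <- TRUE }
  if (n2 > 16L) stop_domain("assignment limited to 16 references")
  nmask <- bitwShiftL(1L, n2)
  dp <- matrix(Inf, n1 + 1L, nmask); dp[1L, 1L] <- 0
  choice <- matrix(NA_integer_, n1 + 1L, nmask)
  prev <- matrix(NA_integer_, n1 + 1L, nmask)
  for (i in seq_len(n1)) {
    for (m in 0:(nmask - 1L)) {
      if (!is.finite(dp[i, m + 1L])) next
      for (j in seq_len(n2)) {
        bit <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(m, bit) != 0L) next
        nm <- bitwOr(m, bit)
        val <- dp[i, m + 1L] + cost[i, j]
        if (val < dp[i + 1L, nm + 1L]) {
          dp[i + 1L, nm + 1L] <- val
          choice[i + 1L, nm + 1L] <- j
          prev[i + 1L, nm + 1L] <- m
        }
      }
    }
  }
  best <- which.min(dp[n1 + 1L, ])
  assign1 <- integer(n1)
  m <- best - 1L
  for (i in n1:1) {
    assign1[i] <- choice[i + 1L, m + 1L]
    m <- prev[i + 1L, m + 1L]
  }
  if (!transposed) assign1
  else { out <- rep(NA_integer_, n2); out[assign1] <- seq_len(n1); out }
}

#' Match endmembers to pesticide reference spectra
#'
#' Optimal one-to-one assignment (minimum total spectral angle, exact) of
#' endmembers to references; each reference is used at most once. An
#' endmember whose assigned angle exceeds `max_angle` — or left without a
#' reference — is labeled `"background"`.
#'
#' @param E an [endmember_set].
#' @param refs list of [reference_spectrum] objects (non-empty).
#' @param max_angle acceptance threshold in radians (default 0.5).
#' @return the [endmember_set] with `names` filled in and attributes
#'   `match_angle` (per-endmember assigned angle, NA when unassigned).
#' @export
match_endmembers <- function(E, refs, max_angle = 0.5) {
  stopifnot(inherits(E, "endmember_set"))
  if (length(refs) == 0L) stop_domain("reference list must be non-empty")
  p <- nrow(E$S); r <- length(refs)
  cost <- matrix(0, p, r)
  for (i in seq_len(p)) for (j in seq_len(r))
    cost[i, j] <- spectral_angle(E$S[i, ], refs[[j]]$spectrum$intensities)
  a <- assignment_min(cost)
  nm <- rep("background", p)
  ang <- rep(NA_real_, p)
  for (i in seq_len(p)) {
    if (is.na(a[i])) next
    ang[i] <- cost[i, a[i]]
    if (ang[i] <= max_angle) nm[i] <- refs[[a[i]]]$name
  }
  E$names <- nm
  attr(E, "match_angle") <- ang
  E
}
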