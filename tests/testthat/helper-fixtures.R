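## shared fixtures, all generated in code

tiny_axis <- function(n = 161L) build_axis(400, 1800, n)

## three distinct reference spectra on a common axis
three_refs <- function(axis = tiny_axis()) {
  pesticide_library(axis, c("chlorpyrifos", "thiabendazole", "thiram"))
}

## noiseless pure-pixel cube: random non-negative mixtures of `refs` with one
## guaranteed pure pixel per component (rows 1..p), optional noise at a
## target SNR (dB)
## `mix_total_range = NULL` gives constant-sum abundances (the data lie in a
## 2-D affine plane, so the convex-hull simplex oracle is exact); a range
## like c(0.1, 0.5) dims the mixed pixels relative to the pure ones, the
## depth-attenuated structure of real cubes.
pure_pixel_cube <- function(refs, n_pixels = 1024L, seed = 1L,
                            snr_db = Inf, scale = 2, mix_total_range = NULL) {
  S <- do.call(rbind, lapply(refs, function(r) r$spectrum$intensities))
  p <- nrow(S)
  set.seed(seed)
  C <- matrix(stats::runif(n_pixels * p), n_pixels, p)
  tot <- if (is.null(mix_total_range)) rep(1, n_pixels)
  else stats::runif(n_pixels, mix_total_range[1], mix_total_range[2])
  C <- scale * tot * C / rowSums(C)
  C[seq_len(p), ] <- diag(p) * scale
  X <- C %*% S
  if (is.finite(snr_db)) {
    noise_sd <- sqrt(mean(X^2) / 10^(snr_db / 10))
    X <- X + matrix(stats::rnorm(length(X), sd = noise_sd), nrow(X))
  }
  list(X = X, C = C, S = S)
}

## single-pesticide synthetic scene (the depth-imaging layout of one treated
## fruit) at reduced size for fast tests
one_pesticide_scene <- function(seed = 3L, n_channels = 161L) {
  scene_config(axis = build_axis(400, 1800, n_channels),
               components = default_scene_components()[1],
               seed = seed)
}

## best per-row spectral angle of an endmember set against true signatures
min_angles <- function(E, S_true) {
  vapply(seq_len(nrow(E$S)), function(i)
    min(vapply(seq_len(nrow(S_true)), function(j)
      spectral_angle(E$S[i, ], S_true[j, ]), 0)), 0)
}

## area of the triangle spanned by three rows of a 2-column matrix
tri_area <- function(P) {
  abs((P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
        (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])) / 2
}

## brute-force maximum-area pixel triple in the rank-2 projection of a
## noiseless 3-component cube; the max-area triple's vertices must be convex
## hull vertices, so the search over hull points is exact
max_simplex_area <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  Y <- Xc %*% svd(Xc, nu = 0, nv = 2)$v            # n x 2 projection
  hull <- chull(Y)
  best <- 0
  nh <- length(hull)
  for (a in 1:(nh - 2)) for (b in (a + 1):(nh - 1)) for (cc in (b + 1):nh) {
    ar <- tri_area(Y[hull[c(a, b, cc)], , drop = FALSE])
    if (ar > best) best <- ar
  }
  list(area = best, project = function(idx) tri_area(Y[idx, , drop = FALSE]))
}

## all permutations of 1..n (tiny n), for brute-force assignment oracles
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (q in all_perms(n - 1L))
      out[[length(out) + 1L]] <- c(i, rest[q])
  }
  out
}
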