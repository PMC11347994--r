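test_that("estimate_snr behaves at its limits and at a constructed SNR", {
  refs <- three_refs()
  cube <- pure_pixel_cube(refs, n_pixels = 400, seed = 2)
  expect_gte(estimate_snr(cube$X, 3), 300)   # exact low rank: residual-free

  ## pure noise at p = 1 estimates near-zero SNR
  for (s in 1:5) {
    set.seed(s)
    N <- matrix(rnorm(2000 * 100), 2000, 100)
    expect_lte(estimate_snr(N, 1), 3)
  }

  ## constructed 20 dB instance
  set.seed(3)
  X <- pure_pixel_cube(refs, n_pixels = 2000, seed = 3, snr_db = 20)$X
  expect_lt(abs(estimate_snr(X, 3) - 20), 2)

  expect_error(estimate_snr(cube$X, 500), "p must")
})

test_that("VCA recovers pure-pixel endmembers exactly and matches the simplex oracle", {
  refs <- three_refs()
  cube <- pure_pixel_cube(refs, n_pixels = 1024, seed = 1)
  E <- run_vca(cube$X, 3, seed = 1)
  expect_true(all(min_angles(E, cube$S) < 1e-6))

  ## brute-force maximum-volume triple over the convex hull of the rank-2
  ## projection: VCA's pick must span at least 0.999x the optimal volume
  oracle <- max_simplex_area(cube$X)
  vca_area <- oracle$project(E$source_pixel_indices)
  expect_gte(vca_area, 0.999 * oracle$area)

  ## permutation stability: different seeds, same endmember set up to order
  E2 <- run_vca(cube$X, 3, seed = 99)
  expect_setequal(E$source_pixel_indices, E2$source_pixel_indices)

  ## 30 dB with depth-attenuated mixed pixels: angles below 0.01 rad
  noisy <- pure_pixel_cube(refs, n_pixels = 1024, seed = 1, snr_db = 30,
                           mix_total_range = c(0.1, 0.5))
  En <- run_vca(noisy$X, 3, seed = 1)
  expect_true(all(min_angles(En, cube$S) < 0.01))

  expect_error(run_vca(cube$X, 2000, seed = 1), "p must")
  expect_error(run_vca(matrix(1, 50, 20), 3, seed = 1), "degenerate")
})

test_that("VCA with p = 1 returns the dominant-projection pixel", {
  refs <- three_refs()[1]
  set.seed(4)
  amp <- runif(200, 0.1, 3)
  X <- amp %o% refs[[1]]$spectrum$intensities
  E <- run_vca(X, 1, seed = 1)
  ## with one spectral direction, the extreme pixel is the largest amplitude
  expect_equal(E$source_pixel_indices, which.max(amp))
})

test_that("spectral_angle matches closed forms", {
  expect_equal(spectral_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(spectral_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(spectral_angle(c(1, 0), c(1, 1)), pi / 4, tolerance = 1e-12)
  expect_error(spectral_angle(c(0, 0), c(1, 1)), "zero")
  expect_error(spectral_angle(c(1, 2), c(1, 2, 3)), "length")
})

test_that("endmember matching is an optimal one-to-one assignment", {
  refs <- three_refs()
  S <- do.call(rbind, lapply(refs, function(r) r$spectrum$intensities))

  ## identity case
  E <- endmember_set(S)
  m <- match_endmembers(E, refs)
  expect_identical(m$names, names(refs))
  expect_equal(sum(attr(m, "match_angle")), 0, tolerance = 1e-12)

  ## an extra broad-baseline endmember is labeled background
  bl <- 100 * exp(-(unclass(tiny_axis()) - 1300)^2 / (2 * 500^2))
  E2 <- endmember_set(rbind(S, bl))
  m2 <- match_endmembers(E2, refs, max_angle = 0.2)
  expect_identical(m2$names[4], "background")
  expect_identical(m2$names[1:3], names(refs))

  ## brute-force assignment oracle on random small cost instances
  set.seed(8)
  for (rep in 1:20) {
    p <- sample(2:4, 1); r <- sample(2:4, 1)
    E3 <- endmember_set(matrix(runif(p * 161, 0.1, 1), p, 161))
    refs3 <- lapply(seq_len(r), function(j) {
      sp <- new_spectrum(tiny_axis(), runif(161, 0.1, 1))
      reference_spectrum(paste0("ref", j), sp,
                         data.frame(center = 1000, half_window = 10))
    })
    cost <- outer(seq_len(p), seq_len(r), Vectorize(function(i, j)
      spectral_angle(E3$S[i, ], refs3[[j]]$spectrum$intensities)))
    ## enumerate all one-to-one assignments of min(p, r) pairs
    k <- min(p, r)
    best <- Inf
    rows <- utils::combn(p, k, simplify = FALSE)
    for (rw in rows) for (cl in utils::combn(r, k, simplify = FALSE)) {
      for (pp in all_perms(k)) best <- min(best, sum(cost[cbind(rw, cl[pp])]))
    }
    m3 <- match_endmembers(E3, refs3, max_angle = Inf)
    got <- sum(attr(m3, "match_angle"), na.rm = TRUE)
    expect_equal(got, best, tolerance = 1e-12)
  }
})

test_that("abundance_nnls solves each pixel exactly", {
  refs <- three_refs()
  cube <- pure_pixel_cube(refs, n_pixels = 200, seed = 6)
  C <- abundance_nnls(cube$X, cube$S)
  expect_lt(max(abs(C - cube$C)), 1e-8)

  ## a pixel orthogonal to all endmembers gets zero coefficients
  S <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  x <- matrix(c(0, 0, 3, 4), 1)
  expect_true(all(abundance_nnls(x, S) == 0))

  ## random 5-channel instances: never worse than a dense 0.01-lattice search
  set.seed(12)
  for (rep in 1:10) {
    S5 <- matrix(runif(2 * 5), 2, 5)
    x5 <- runif(5, -0.2, 1)
    got <- abundance_nnls(matrix(x5, 1), S5)
    obj <- sum((x5 - as.numeric(got %*% S5))^2)
    grid <- seq(0, 2, by = 0.01)
    best <- Inf
    for (a in grid) {
      resid <- x5 - a * S5[1, ]
      b <- grid[which.min(vapply(grid, function(b)
        sum((resid - b * S5[2, ])^2), 0))]
      best <- min(best, sum((resid - b * S5[2, ])^2))
    }
    expect_lte(obj, best + 1e-12)
  }

  ## independent oracle: pracma's NNLS agrees
  set.seed(13)
  Sp <- matrix(runif(3 * 30), 3, 30)
  xs <- matrix(runif(5 * 30, -0.1, 1), 5, 30)
  mine <- abundance_nnls(xs, Sp)
  for (i in 1:5) {
    ora <- pracma::lsqnonneg(t(Sp), xs[i, ])$x
    expect_equal(as.numeric(mine[i, ]), ora, tolerance = 1e-8)
  }
})
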