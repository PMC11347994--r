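grid_geo <- function(n_depth = 40L, n_lateral = 10L, step = 5) {
  list(n_depth = n_depth, n_lateral = n_lateral, depth_step_um = step,
       time_h = 2)
}

test_that("depth_profile is an exact conditional mean over depth bins", {
  geo <- grid_geo()
  ## uniform content: every bin mean equals the constant
  prof <- depth_profile(rep(3.5, 400), geo)
  expect_true(all(prof$mean_content == 3.5))
  expect_equal(nrow(prof$depth_bins), 40)

  ## a single nonzero pixel lights up exactly one bin
  content <- numeric(400)
  content[(12 - 1) * 10 + 3] <- 7      # depth row 12
  prof1 <- depth_profile(content, geo)
  expect_equal(which(prof1$mean_content > 0), 12)

  ## mass identity: sum(bin mean * bin count) = sum(content)
  set.seed(14)
  cnt <- runif(400)
  prof2 <- depth_profile(cnt, geo, bin_um = 25)
  expect_equal(sum(prof2$mean_content * prof2$n_pixels), sum(cnt),
               tolerance = 1e-9)

  expect_error(depth_profile(cnt, geo, bin_um = 0), "bin_um")
  expect_error(depth_profile(cnt, geo, bin_um = 1e5), "extent")
})

test_that("an exponential content field yields its decay length", {
  geo <- grid_geo(n_depth = 41L)
  z <- rep((0:40) * 5, each = 10)
  prof <- depth_profile(exp(-z / 50), geo)
  mid <- rowMeans(prof$depth_bins)
  fit <- lm(log(prof$mean_content) ~ mid)
  decay <- -1 / coef(fit)[["mid"]]
  expect_lt(abs(decay - 50) / 50, 0.05)
})

test_that("total_content_curve aggregates and scales linearly", {
  geo <- grid_geo()
  mk <- function(content, t) {
    p <- depth_profile(content, geo)
    p$time_h <- t
    p
  }
  profs <- lapply(1:4, function(t) mk(rep(2, 400), t))
  curve <- total_content_curve(profs)
  expect_equal(curve$total_content, rep(2, 4))

  set.seed(15)
  cont <- lapply(1:4, function(i) runif(400))
  c1 <- total_content_curve(lapply(1:4, function(i) mk(cont[[i]], i)))
  c2 <- total_content_curve(lapply(1:4, function(i) mk(2 * cont[[i]], i)))
  expect_equal(c2$total_content, 2 * c1$total_content, tolerance = 1e-12)

  bad <- lapply(1:3, function(t) mk(rep(1, 400), t))
  bad[[2]] <- depth_profile(rep(1, 400), geo, bin_um = 25)
  bad[[2]]$time_h <- 2
  expect_error(total_content_curve(bad), "binning")
  expect_error(total_content_curve(bad[1]), "2 time points")
})

test_that("the synthetic time course's content curve is non-monotone", {
  ## ground-truth concentration fields over the standard 10 times
  sc <- scene_config()
  f <- simulate_penetration_field(sc, 2)   # the systemic component
  geo <- list(n_depth = sc$n_depth, n_lateral = 1L,
              depth_step_um = sc$depth_step_um, time_h = 0)
  profs <- lapply(seq_along(sc$times_h), function(k) {
    p <- depth_profile(f$values[k, ], geo)
    p$time_h <- sc$times_h[k]
    p
  })
  curve <- total_content_curve(profs)
  expect_lt(min(diff(curve$total_content)), 0)  # at least one local decrease
  expect_gt(max(diff(curve$total_content)), 0)
})

test_that("bspline_trend reproduces polynomials and interpolates at df = n", {
  x <- c(2, 4, 6, 8, 10, 12, 24, 48, 72, 96)
  y <- 3 + 0.5 * x
  tr <- bspline_trend(x, y, df = 6)
  expect_equal(tr$fitted, y, tolerance = 1e-9)
  expect_equal(tr$values, 3 + 0.5 * tr$grid, tolerance = 1e-8)

  set.seed(16)
  y2 <- runif(10)
  tr2 <- bspline_trend(x, y2, df = 10)
  expect_lt(max(abs(tr2$fitted - y2)), 1e-9)

  ## smoothing at small df keeps the trend inside the data envelope
  y3 <- c(1, 1.2, 0.9, 1.1, 1, 9, 1.05, 0.95, 1.1, 1)
  tr3 <- bspline_trend(x, y3, df = 4)
  expect_lte(max(abs(tr3$values)), max(abs(y3)))

  expect_error(bspline_trend(x, y, df = 11), "df")
  expect_error(bspline_trend(x, y, df = 3), "df")
})

test_that("peak_content reads per-pixel band maxima from a cube", {
  axis <- tiny_axis(701)
  ref <- pesticide_library(axis, "thiram")$thiram
  amp <- c(0.5, 1, 2, 4)
  X <- amp %o% ref$spectrum$intensities
  cube <- hypermap(X, axis, 4, 1, 5, 5, 2)
  pc <- peak_content(cube, 1380, 10)
  expect_equal(pc / pc[2], amp, tolerance = 1e-9)
})
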