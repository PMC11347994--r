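test_that("pearson similarity matches closed forms", {
  a <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_similarity(a, a), 1)
  expect_equal(pearson_similarity(a, -a + 10), -1)
  expect_equal(pearson_similarity(a, 2 * a), 1)
  expect_error(pearson_similarity(a, rep(1, 5)), "variance")
})

test_that("euclidean distance and its similarity transform behave", {
  a <- c(3, 4); b <- c(3, 4)
  expect_equal(euclidean_distance(a, b), 0)
  expect_equal(ed_to_similarity(0), 1)

  ## orthonormal pair in normalized mode
  expect_equal(euclidean_distance(c(1, 0), c(0, 1)), sqrt(2))
  expect_equal(ed_to_similarity(sqrt(2)), 1 / (1 + sqrt(2)))

  set.seed(5)
  x <- runif(10); y <- runif(10)
  expect_equal(euclidean_distance(x, y, normalize = FALSE),
               sqrt(sum((x - y)^2)), tolerance = 1e-12)
  ## symmetry and common channel permutation invariance
  expect_equal(euclidean_distance(x, y), euclidean_distance(y, x))
  pr <- sample(10)
  expect_equal(ed_to_similarity(euclidean_distance(x[pr], y[pr])),
               ed_to_similarity(euclidean_distance(x, y)), tolerance = 1e-12)

  expect_error(euclidean_distance(x, y[1:5]), "length")
  expect_error(ed_to_similarity(-1), ">= 0")
})

## build a cube whose pixels are explicit mixtures of two references
mixture_cube <- function(fracA, fracB, noise_sd = 0, seed = 1,
                         axis = tiny_axis()) {
  refs <- pesticide_library(axis, c("chlorpyrifos", "acetamiprid"))
  sA <- refs$chlorpyrifos$spectrum$intensities
  sB <- refs$acetamiprid$spectrum$intensities
  set.seed(seed)
  X <- t(vapply(seq_along(fracA), function(i)
    fracA[i] * sA + fracB[i] * sB + rnorm(length(sA), sd = noise_sd),
    numeric(length(sA))))
  list(map = hypermap(X, axis, n_depth = length(fracA), n_lateral = 1,
                      depth_step_um = 5, lateral_step_um = 5, time_h = 2),
       refs = refs)
}

test_that("similarity maps localize the reference signature", {
  axis <- tiny_axis()
  refs <- pesticide_library(axis, "thiram")
  s <- refs$thiram$spectrum$intensities
  ## every pixel equals the reference up to vanishing noise
  set.seed(2)
  X <- matrix(rep(s, 12), 12, byrow = TRUE) + rnorm(12 * length(s), sd = 1e-6)
  cube <- hypermap(X, axis, 4, 3, 5, 5, 2)
  sm <- similarity_map(cube, refs$thiram, metric = "pearson")
  expect_true(all(sm$values > 0.999))
  sme <- similarity_map(cube, refs$thiram, metric = "ed")
  expect_true(all(sme$values > 0.999))

  ## background-only cube: low similarity everywhere
  bg <- 150 * exp(-(unclass(axis) - 1300)^2 / (2 * 500^2))
  set.seed(3)
  Xb <- matrix(rep(bg, 30), 30, byrow = TRUE) + rnorm(30 * length(bg), sd = 5)
  cubeb <- hypermap(Xb - rowMeans(Xb), axis, 6, 5, 5, 5, 2)
  smb <- similarity_map(cubeb, refs$thiram, metric = "pearson")
  expect_lt(mean(smb$values), 0.3)

  ## a single seeded pixel is the argmax
  Xs <- Xb
  Xs[17, ] <- s
  cubes <- hypermap(Xs, axis, 6, 5, 5, 5, 2)
  sms <- similarity_map(cubes, refs$thiram, metric = "pearson")
  expect_equal(which.max(t(sms$values)), 17)  # row-major pixel 17

  ## axis mismatch instructs resampling
  refs2 <- pesticide_library(build_axis(400, 1800, 81), "thiram")
  expect_error(similarity_map(cube, refs2$thiram), "resample")
})

test_that("similarity thresholds partition pixels as specified", {
  cfg <- pipeline_config()
  sim <- matrix(c(0.85, 0.65, 0.80, 0.49, 0.5, 0.95), 2, 3)
  lm <- classify_similarity(sim, cfg)
  expect_identical(as.vector(lm$labels),
                   c("pesticide", "suspected", "suspected",
                     "background", "suspected", "pesticide"))
  ## exact partition: category counts sum to the pixel count
  expect_equal(sum(table(factor(lm$labels, lm$categories))), 6)
  expect_identical(sort(unique(as.vector(lm$color_values))), c(0L, 1L, 2L))
})

test_that("mixed overlap maps encode presence additively", {
  ## fractions chosen so the four presence configurations all occur at a
  ## relaxed call threshold (pure A, pure B, balanced mixture, nothing)
  cube <- mixture_cube(fracA = c(1, 0, 0.55, 0),
                       fracB = c(0, 1, 0.55, 0))
  cfg <- pipeline_config(pesticide_threshold = 0.45, suspected_threshold = 0.2)
  om <- mixed_overlap_map(cube$map, cube$refs$chlorpyrifos,
                          cube$refs$acetamiprid, cfg)
  expect_identical(as.vector(om$color_values), c(10, 20, 30, 0))
  expect_identical(as.vector(om$labels), c("A", "B", "A+B", "none"))

  ## default 0.8 threshold: pure pixels get their own codes, nothing else
  om2 <- mixed_overlap_map(cube$map, cube$refs$chlorpyrifos,
                           cube$refs$acetamiprid, pipeline_config())
  expect_identical(as.vector(om2$color_values)[1:2], c(10, 20))
  expect_true(all(om2$color_values %in% c(0, 10, 20, 30)))

  ## custom code sets stay additive
  cfg3 <- pipeline_config(pesticide_threshold = 0.45, suspected_threshold = 0.2,
                          color_codes = c(none = 0, pesticide_a = 1,
                                          pesticide_b = 2))
  om3 <- mixed_overlap_map(cube$map, cube$refs$chlorpyrifos,
                           cube$refs$acetamiprid, cfg3)
  expect_identical(as.vector(om3$color_values), c(1, 2, 3, 0))

  expect_error(mixed_overlap_map(cube$map, cube$refs$chlorpyrifos,
                                 cube$refs$chlorpyrifos, cfg), "identical")
})

test_that("pipeline_config enforces its invariants", {
  expect_error(pipeline_config(pesticide_threshold = 0.5,
                               suspected_threshold = 0.8), "config error")
  expect_error(pipeline_config(train_fraction = 1), "train_fraction")
  expect_error(pipeline_config(color_codes = c(none = 0, pesticide_a = 10,
                                               pesticide_b = 10)), "color codes")
})
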