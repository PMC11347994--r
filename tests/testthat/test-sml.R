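two_blob_data <- function(n = 60, d = 8, sep = 20, seed = 21) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * d), n, d),
             matrix(rnorm(n * d, mean = sep / sqrt(d)), n, d))
  list(X = X, truth = rep(1:2, each = n))
}

test_that("kmeans_cluster honors its limiting cases", {
  set.seed(17)
  X <- matrix(rnorm(50 * 4), 50, 4)
  k1 <- kmeans_cluster(X, 1, seed = 1)
  expect_equal(as.numeric(k1$centroids), colMeans(X), tolerance = 1e-9)
  expect_equal(k1$inertia, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-9)

  kn <- kmeans_cluster(X, nrow(X), seed = 1)
  expect_equal(kn$inertia, 0)

  expect_error(kmeans_cluster(X, 51, seed = 1), "k must")
})

test_that("well-separated blobs are clustered perfectly", {
  blobs <- two_blob_data()
  km <- kmeans_cluster(blobs$X, 2, seed = 3)
  tab <- table(km$assignments, blobs$truth)
  ## one-to-one cluster/class correspondence (ARI = 1)
  expect_equal(unname(sort(colSums(tab > 0))), c(1, 1))
  expect_equal(unname(sort(rowSums(tab > 0))), c(1, 1))
})

test_that("curation transfers endmember labels by centroid similarity", {
  axis <- tiny_axis()
  refA <- pesticide_library(axis, "chlorpyrifos")$chlorpyrifos
  sA <- refA$spectrum$intensities
  bg <- 100 * sin(seq(0, 3 * pi, length.out = length(sA)))^2
  set.seed(22)
  X <- rbind(t(replicate(40, sA * runif(1, 0.8, 1.2) + rnorm(length(sA), sd = 2))),
             t(replicate(40, bg + rnorm(length(sA), sd = 2))))
  em <- endmember_set(rbind(sA), names = "chlorpyrifos")
  cur <- curate_training_set(X, em, k = 2, seed = 1, correct_baseline = FALSE)
  expect_equal(nrow(cur$X), 80)                       # zero discards
  expect_setequal(unique(cur$labels), c("chlorpyrifos", "background"))
  expect_equal(sum(cur$labels == "chlorpyrifos"), 40)

  ## every centroid in the ambiguous band: empty-dataset error; pick the
  ## blend weight that lands the centroid correlation inside (0.5, 0.8]
  blend <- function(w) w * sA / sqrt(sum(sA^2)) +
    (1 - w) * bg / sqrt(sum(bg^2))
  w_mid <- uniroot(function(w) cor(blend(w), sA) - 0.65, c(0, 1))$root
  mid <- blend(w_mid)
  Xm <- t(replicate(30, mid * 50 + rnorm(length(sA), sd = 1e-3)))
  expect_error(curate_training_set(Xm, em, k = 1, seed = 1,
                                   correct_baseline = FALSE),
               "ambiguous")

  ## labels depend only on the centroid, not on cluster numbering
  cur2 <- curate_training_set(X[sample(80), ], em, k = 2, seed = 9,
                              correct_baseline = FALSE)
  expect_equal(sort(table(cur2$labels)), sort(table(cur$labels)))
})

test_that("stratified splitting is exact, disjoint and seeded", {
  set.seed(23)
  ds <- spectra_dataset(matrix(rnorm(300 * 4), 300, 4),
                        rep(c("a", "b", "c"), each = 100))
  sp <- split_dataset(ds, 0.7, seed = 4)
  expect_true(all(table(sp$train$labels) == 70))
  expect_true(all(table(sp$test$labels) == 30))

  ## round-half-up on odd class sizes at fraction 0.5
  ds5 <- spectra_dataset(matrix(rnorm(10 * 3), 10, 3),
                         rep(c("a", "b"), each = 5))
  sp5 <- split_dataset(ds5, 0.5, seed = 1)
  expect_true(all(table(sp5$train$labels) == 3))
  expect_true(all(table(sp5$test$labels) == 2))

  sp_a <- split_dataset(ds, 0.7, seed = 11)
  sp_b <- split_dataset(ds, 0.7, seed = 11)
  sp_c <- split_dataset(ds, 0.7, seed = 12)
  expect_identical(sp_a$train$X, sp_b$train$X)
  expect_false(identical(sp_a$train$X, sp_c$train$X))
  expect_equal(table(sp_c$train$labels), table(sp_a$train$labels))

  ds_bad <- spectra_dataset(matrix(rnorm(12), 3, 4), c("a", "a", "b"))
  expect_error(split_dataset(ds_bad, 0.7), "at least 2")
})

test_that("classifier families separate a linearly separable fixture", {
  blobs <- two_blob_data(n = 50, seed = 24)
  ds <- spectra_dataset(blobs$X, c("neg", "pos")[blobs$truth])
  for (fam in c("lda", "logistic", "linear_svm")) {
    model <- train_classifier(ds, fam, seed = 1)
    scores <- predict(model, ds)
    pred <- model$classes[max.col(scores)]
    expect_equal(mean(pred == ds$labels), 1, label = fam)
  }
  ## determinism: retraining gives identical scores
  m1 <- train_classifier(ds, "random_forest", seed = 7)
  m2 <- train_classifier(ds, "random_forest", seed = 7)
  expect_equal(predict(m1, ds), predict(m2, ds))

  single <- spectra_dataset(blobs$X[1:10, ], rep("a", 10))
  expect_error(train_classifier(single, "lda"), "2 classes")
})

test_that("shuffled labels give chance-level held-out AUC", {
  aucs <- vapply(1:5, function(s) {
    set.seed(s)
    X <- matrix(rnorm(300 * 6), 300, 6)
    labels <- sample(rep(c("a", "b"), each = 150))
    ds <- spectra_dataset(X, labels)
    sp <- split_dataset(ds, 0.7, seed = s)
    model <- train_classifier(sp$train, "lda", seed = s)
    rep <- evaluate(model, sp$test)
    mean(rep$auc)
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("roc_auc equals the pairwise comparison statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE))$auc, 0)

  pairwise_auc <- function(scores, pos) {
    sp <- scores[pos]; sn <- scores[!pos]
    mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
  }
  set.seed(25)
  for (rep in 1:25) {
    scores <- sample(seq(0, 1, by = 0.05), 50, replace = TRUE)  # forces ties
    pos <- runif(50) > 0.5
    if (!any(pos) || all(pos)) next
    r <- roc_auc(scores, pos)
    expect_equal(r$auc, pairwise_auc(scores, pos), tolerance = 1e-12)
    ## curve anchored at (0,0) and (1,1), monotone in both coordinates
    expect_equal(r$roc[1, ], data.frame(fpr = 0, tpr = 0))
    expect_equal(as.numeric(r$roc[nrow(r$roc), ]), c(1, 1))
    expect_true(all(diff(r$roc$fpr) >= 0) && all(diff(r$roc$tpr) >= 0))
  }
  expect_error(roc_auc(c(1, 2), c(TRUE, TRUE)), "positive")
})

test_that("evaluate produces a coherent report", {
  blobs <- two_blob_data(n = 40, seed = 26)
  labels <- c("neg", "pos")[blobs$truth]
  groups <- rep(c("g1", "g2"), 40)
  ds <- spectra_dataset(blobs$X, labels, group = groups)
  sp <- split_dataset(ds, 0.7, seed = 2)
  model <- train_classifier(sp$train, "lda", seed = 1)
  rep <- evaluate(model, sp$test)

  expect_true(all(rep$auc == 1))
  expect_equal(sum(diag(rep$confusion)), sum(rep$confusion))  # perfect
  expect_equal(unname(rowSums(rep$confusion)),
               as.numeric(table(sp$test$labels)))
  ## proportional scores: per-group fractions summing to 1
  expect_true(all(abs(rowSums(rep$proportional_scores) - 1) < 1e-9))

  ## counting semantics on a constructed prediction pattern
  counts <- table(factor(c(rep("A", 7), rep("B", 3)), levels = c("A", "B")))
  expect_equal(as.numeric(prop.table(counts)), c(0.7, 0.3))

  bad <- spectra_dataset(blobs$X[1:4, ], rep("zz", 4))
  expect_error(evaluate(model, bad), "unknown")
})
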