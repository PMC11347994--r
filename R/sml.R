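#' K-means clustering with k-means++ seeding and restarts
#'
#' Lloyd's algorithm started from k-means++-style seeds, best of `n_init`
#' restarts by within-cluster sum of squares; the returned inertia is the
#' minimum across restarts.
#'
#' @param X numeric matrix, observations in rows.
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param seed integer seed.
#' @param n_init number of restarts (default 5).
#' @return list with `assignments` (integer vector), `centroids`
#'   (`k x ncol(X)`), `inertia` (total within-cluster sum of squares).
#' @export
kmeans_cluster <- function(X, k, seed = 1L, n_init = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 1 || k > n) stop_domain("k must satisfy 1 <= k <= nrow(X)")
  if (k == n) {
    return(list(assignments = seq_len(n), centroids = X, inertia = 0))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_init)) {
      centers <- kmeanspp_seeds(X, k)
      km <- suppressWarnings(
        stats::kmeans(X, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  list(assignments = as.integer(best$cluster),
       centroids = unname(best$centers),
       inertia = best$tot.withinss)
}

## k-means++ seeding: first center uniform, then proportional to squared
## distance to the nearest chosen center
kmeanspp_seeds <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[idx[1L], ])^2)
  for (i in seq_len(k - 1L)) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      cand <- setdiff(seq_len(n), idx[seq_len(i)])
      idx[i + 1L] <- cand[sample.int(length(cand), 1L)]
    } else {
      idx[i + 1L] <- sample.int(n, 1L, prob = p)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx[i + 1L], ])^2))
  }
  X[idx, , drop = FALSE] + matrix(stats::runif(k * ncol(X), 0, 1e-9), k)
}

#' Curate a training set from unlabeled spectra
#'
#' The label-transfer step of the spatial-machine-learning stage: cluster
#' the unlabeled spectra with K-means, compute the Pearson similarity of
#' each cluster centroid to every labeled (matched) VCA endmember, and
#' transfer labels by the same threshold semantics as the maps — clusters
#' whose best similarity exceeds `pesticide_threshold` inherit that
#' pesticide label, clusters below `suspected_threshold` become
#' `"background"`, and clusters in the ambiguous band in between are
#' discarded from training.
#'
#' @param X unlabeled spectra matrix (rows) or a [spectra_dataset].
#' @param endmembers a labeled [endmember_set] (see [match_endmembers]);
#'   rows labeled `"background"` are ignored for pesticide transfer.
#' @param cfg a [pipeline_config].
#' @param k number of clusters; default 2x the number of pesticide labels
#'   (over-clustering then labeling).
#' @param seed integer seed.
#' @param group optional per-spectrum group carried through.
#' @param correct_baseline baseline-correct the cluster centroids (AsLS,
#'   see [baseline_correct]) before computing their similarity to the
#'   endmembers (default TRUE): raw spectra carry the fluorescence
#'   background while VCA endmembers from corrected cubes do not, and only
#'   the k centroids need correcting.
#' @return a [spectra_dataset] with provenance `"curated"` containing only
#'   the retained spectra.
#' @export
curate_training_set <- function(X, endmembers, cfg = pipeline_config(),
                                k = NULL, seed = 1L, group = NULL,
                                correct_baseline = TRUE) {
  if (inherits(X, "spectra_dataset")) { group <- X$group; X <- X$X }
  X <- as.matrix(X)
  stopifnot(inherits(endmembers, "endmember_set"))
  if (is.null(endmembers$names))
    stop_domain("endmembers must carry labels: run match_endmembers() first")
  pest <- which(endmembers$names != "background")
  if (!length(pest)) stop_domain("no pesticide-labeled endmember")
  if (is.null(k)) k <- 2L * length(pest) + 2L
  km <- kmeans_cluster(X, k, seed = seed)
  cents <- km$centroids
  if (correct_baseline)
    for (cl in seq_len(k))
      cents[cl, ] <- cents[cl, ] - whittaker_asls(cents[cl, ],
                                                  cfg$baseline_smoothness,
                                                  cfg$baseline_asymmetry,
                                                  cfg$baseline_iter)
  keep <- logical(nrow(X))
  labels <- character(nrow(X))
  for (cl in seq_len(k)) {
    cen <- cents[cl, ]
    sims <- vapply(pest, function(i)
      suppressWarnings(stats::cor(cen, endmembers$S[i, ])), 0)
    sims[!is.finite(sims)] <- -1
    best <- which.max(sims)
    in_cl <- km$assignments == cl
    if (sims[best] > cfg$pesticide_threshold) {
      keep[in_cl] <- TRUE
      labels[in_cl] <- endmembers$names[pest[best]]
    } else if (sims[best] < cfg$suspected_threshold) {
      keep[in_cl] <- TRUE
      labels[in_cl] <- "background"
    }                                  # ambiguous band: discarded
  }
  if (!any(keep))
    stop_domain("curation produced an empty dataset: every cluster fell in ",
                "the ambiguous similarity band")
  spectra_dataset(X[keep, , drop = FALSE], labels[keep],
                  group = if (!is.null(group)) group[keep] else NULL,
                  provenance = "curated")
}

#' Stratified train/test split
#'
#' Splits a labeled dataset per class: each class contributes
#' `round(train_fraction * n_class)` spectra (round-half-up) to the training
#' set, drawn by a seeded permutation, and the remainder to the test set;
#' the split is disjoint and exhaustive and deterministic by seed.
#'
#' @param ds a [spectra_dataset]; every class needs >= 2 members.
#' @param train_fraction fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `test` [spectra_dataset]s.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(ds, "spectra_dataset"))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop_domain("train_fraction must lie in (0, 1)")
  tab <- table(ds$labels)
  if (any(tab < 2L))
    stop_domain("every class needs at least 2 spectra before splitting")
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(ds$labels == cl)
      n_tr <- floor(train_fraction * length(idx) + 0.5)   # round half up
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)        # both sides non-empty
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(ds$X)), train_idx)
  subset_ds <- function(i) spectra_dataset(ds$X[i, , drop = FALSE], ds$labels[i],
                                           group = if (!is.null(ds$group)) ds$group[i],
                                           axis = ds$axis, provenance = ds$provenance)
  list(train = subset_ds(train_idx), test = subset_ds(test_idx))
}

#' Train a spectral classifier
#'
#' One of four standard chemometric families, all exposing per-class
#' continuous scores for ROC analysis: linear discriminant analysis,
#' ridge-regularized multinomial logistic regression, linear-kernel support
#' vector machine (with Platt probability scores), or random forest.
#' Deterministic given `seed`.
#'
#' @param train a [spectra_dataset] with >= 2 classes.
#' @param family `"lda"`, `"logistic"`, `"linear_svm"` or `"random_forest"`.
#' @param seed integer seed.
#' @param ... passed to the underlying fitter.
#' @return a `spectral_classifier`: list with `family`, `classes`, `model`.
#' @export
train_classifier <- function(train, family = c("lda", "logistic", "linear_svm",
                                               "random_forest"),
                             seed = 1L, ...) {
  family <- match.arg(family)
  stopifnot(inherits(train, "spectra_dataset"))
  classes <- sort(unique(train$labels))
  if (length(classes) < 2L) stop_domain("training set must contain >= 2 classes")
  y <- factor(train$labels, levels = classes)
  X <- train$X
  model <- with_seed(seed, switch(family,
    lda = suppressWarnings(MASS::lda(X, grouping = y)),
    logistic = glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                              lambda = 0.01, standardize = TRUE, ...),
    linear_svm = e1071::svm(X, y, kernel = "linear", probability = TRUE,
                            scale = FALSE, ...),
    random_forest = randomForest::randomForest(X, y, ntree = 100L, ...)))
  structure(list(family = family, classes = classes, model = model),
            class = "spectral_classifier")
}

#' @export
print.spectral_classifier <- function(x, ...) {
  cat(sprintf("<spectral_classifier> %s over classes: %s\n",
              x$family, paste(x$classes, collapse = ", ")))
  invisible(x)
}

#' Per-class continuous scores for new spectra
#' @param object a `spectral_classifier`.
#' @param newdata spectra matrix or [spectra_dataset].
#' @param ... unused.
#' @return matrix `n x n_classes` of scores (class posterior/probability).
#' @export
predict.spectral_classifier <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_dataset")) newdata$X else as.matrix(newdata)
  scores <- switch(object$family,
    lda = predict(object$model, X)$posterior,
    logistic = {
      pr <- predict(object$model, X, type = "response")
      matrix(pr[, , 1L], nrow(X), dimnames = dimnames(pr)[1:2])
    },
    linear_svm = {
      pr <- attr(predict(object$model, X, probability = TRUE), "probabilities")
      pr[, order(colnames(pr)), drop = FALSE]
    },
    random_forest = predict(object$model, X, type = "prob"))
  scores <- as.matrix(scores)[, object$classes, drop = FALSE]
  unname_rows <- scores
  rownames(unname_rows) <- NULL
  unname_rows
}

#' ROC curve and trapezoidal AUC
#'
#' Threshold sweep over the unique score values, grouping ties into a single
#' step; AUC by the trapezoid rule, equal to the pairwise probability
#' `P(score+ > score-) + 0.5 P(tie)`.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positives logical (or 0/1) labels; at least one of each.
#' @return list with `roc` (data.frame `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, positives) {
  positives <- as.logical(positives)
  if (length(scores) != length(positives)) stop_domain("length mismatch")
  nP <- sum(positives); nN <- sum(!positives)
  if (nP == 0L || nN == 0L)
    stop_domain("need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positives[ord]
  ## group tied scores into single steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / nP)
  fpr <- c(0, fp[last] / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a classifier on held-out spectra
#'
#' Produces the full evaluation bundle: per-class one-vs-rest ROC and AUC,
#' the confusion matrix of argmax predictions, overall accuracy, and — when
#' the dataset carries groups — per-group proportional scores (the fraction
#' of each group's spectra predicted as each class).
#'
#' @param model a `spectral_classifier`.
#' @param test a non-empty [spectra_dataset]; its classes must be a subset
#'   of the model's.
#' @return a `classifier_report`: list with `roc` (per class), `auc` (named
#'   vector), `confusion` (true x predicted counts), `accuracy`,
#'   `proportional_scores` (group x class fractions, rows summing to 1), and
#'   `family`.
#' @export
evaluate <- function(model, test) {
  stopifnot(inherits(model, "spectral_classifier"),
            inherits(test, "spectra_dataset"))
  if (nrow(test$X) == 0L) stop_domain("test set is empty")
  unknown <- setdiff(unique(test$labels), model$classes)
  if (length(unknown))
    stop_domain("test contains class(es) unknown to the model: ",
                paste(unknown, collapse = ", "))
  scores <- predict(model, test)
  pred <- model$classes[max.col(scores, ties.method = "first")]
  classes <- model$classes
  rocs <- list(); aucs <- stats::setNames(numeric(0), character(0))
  for (cl in classes) {
    pos <- test$labels == cl
    if (any(pos) && !all(pos)) {
      r <- roc_auc(scores[, cl], pos)
      rocs[[cl]] <- r$roc
      aucs[cl] <- r$auc
    }
  }
  confusion <- table(true = factor(test$labels, levels = classes),
                     predicted = factor(pred, levels = classes))
  prop <- NULL
  if (!is.null(test$group)) {
    prop <- prop.table(table(group = test$group,
                             predicted = factor(pred, levels = classes)),
                       margin = 1L)
  }
  structure(list(roc = rocs, auc = aucs, confusion = confusion,
                 accuracy = mean(pred == test$labels),
                 proportional_scores = prop, family = model$family),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %s: accuracy %.3f\n", x$family, x$accuracy))
  cat("  per-class AUC:",
      paste(names(x$auc), sprintf("%.4f", x$auc), sep = "=", collapse = ", "), "\n")
  cat("  confusion matrix:\n")
  print(x$confusion)
  invisible(x)
}

#' @export
plot.classifier_report <- function(x, ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("One-vs-rest ROC (%s)", x$family), ...)
  cols <- grDevices::hcl.colors(max(3L, length(x$roc)), "Dark 3")
  for (i in seq_along(x$roc))
    graphics::lines(x$roc[[i]]$fpr, x$roc[[i]]$tpr, col = cols[i], lwd = 2)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", names(x$roc), x$auc),
                   col = cols[seq_along(x$roc)], lwd = 2, bty = "n")
  invisible(x)
}
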