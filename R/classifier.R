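# Species identification: an RBF-kernel SVM over the silhouette feature
# vector, with pairwise-coupling probability calibration providing the
# per-object confidence. The kernel and calibration are reconstructions;
# the original system documents only that an SVM with per-object
# confidence was used.

#' Train the species identifier
#'
#' Fits a radial-basis support vector machine (via \pkg{e1071}) on a
#' labeled feature library. Features are standardized using the training
#' data only (the scaling is part of the fitted model), and probability
#' calibration is enabled so predictions carry a confidence: the maximum
#' posterior class probability.
#'
#' @param features numeric matrix, one row per labeled silhouette
#'   (columns as produced by [feature_vector()]).
#' @param labels species labels (character or factor), one per row.
#' @param cost SVM regularization parameter.
#' @param gamma RBF kernel width; default `1 / ncol(features)`.
#' @param seed integer seed (the probability calibration uses internal
#'   cross-validation, so the seed makes training deterministic).
#' @return object of class `fish_svm`.
#' @export
train_classifier <- function(features, labels, cost = 10, gamma = NULL,
                             seed = 1L) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  bad <- which(!apply(features, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite features in rows: ", paste(head(bad, 5L), collapse = ", "))
  tab <- table(labels)
  if (length(tab) < 2L) stop("training needs >= 2 distinct species labels")
  if (any(tab < 3L))
    stop("each species needs >= 3 examples; short: ",
         paste(names(tab)[tab < 3L], collapse = ", "))
  if (is.null(gamma)) gamma <- 1 / ncol(features)
  # constant columns break e1071's internal scaling; freeze them out
  keep <- apply(features, 2L, function(x) stats::var(x) > 0)
  model <- with_seed(seed, e1071::svm(
    x = features[, keep, drop = FALSE], y = factor(labels),
    kernel = "radial", cost = cost, gamma = gamma,
    probability = TRUE, scale = TRUE))
  structure(list(model = model, keep = keep,
                 feature_names = colnames(features),
                 classes = names(tab), seed = seed),
            class = "fish_svm")
}

#' Predict species with confidence
#'
#' @param object a [train_classifier()] fit.
#' @param newdata numeric matrix (or single named vector) of features with
#'   the training columns.
#' @param ... unused.
#' @return data.frame with `species` (argmax posterior class),
#'   `confidence` (maximum class probability, in `[0, 1]`); the full
#'   probability matrix (rows summing to 1) is attached as attribute
#'   `"probabilities"`.
#' @export
predict.fish_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$feature_names))
    stop("feature length mismatch: expected ", length(object$feature_names),
         ", got ", ncol(newdata))
  pr <- predict(object$model, newdata[, object$keep, drop = FALSE],
                probability = TRUE)
  probs <- attr(pr, "probabilities")
  probs <- probs[, order(colnames(probs)), drop = FALSE]
  out <- data.frame(
    species = colnames(probs)[max.col(probs, ties.method = "first")],
    confidence = apply(probs, 1L, max),
    stringsAsFactors = FALSE)
  attr(out, "probabilities") <- probs
  out
}

#' @export
print.fish_svm <- function(x, ...) {
  cat("Species identifier (RBF SVM):", length(x$classes), "classes:",
      paste(x$classes, collapse = ", "), "\n")
  cat("  ", x$model$tot.nSV, "support vectors;",
      sum(x$keep), "of", length(x$keep), "features active\n")
  invisible(x)
}

#' Identify tracked objects
#'
#' @param model a [train_classifier()] fit.
#' @param features matrix from [track_features()] (rownames = track ids).
#' @return data.frame `track_id`, `species`, `confidence`,
#'   `override_confidence` (NA; reserved for human-assigned confidence).
#' @export
classify_tracks <- function(model, features) {
  pred <- predict(model, features)
  data.frame(track_id = rownames(features), species = pred$species,
             confidence = pred$confidence, override_confidence = NA_real_,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' k-fold evaluation protocols
#'
#' Splits the library into `k` seeded, label-stratified folds. Under the
#' `"standard"` protocol each fold is held out for testing and the model
#' is trained on the remainder. Under the `"inverted"` protocol the model
#' is trained on the (small) fold itself and tested on the remaining
#' items — the protocol the original field evaluation describes, where
#' each 10% subset served as the training set for the other 90%. Folds in
#' which the training side lacks two classes (or three examples of any
#' class) are skipped with a warning.
#'
#' @param features feature matrix.
#' @param labels species labels.
#' @param k number of folds (>= 2, < number of items).
#' @param protocol `"inverted"` or `"standard"`.
#' @param seed fold-assignment seed.
#' @param cost,gamma passed to [train_classifier()].
#' @return list with `per_fold` (success rate per evaluated fold),
#'   `average` (mean over evaluated folds) and `skipped` (fold indices).
#' @export
crossval_kfold <- function(features, labels, k = 10L,
                           protocol = c("inverted", "standard"),
                           seed = 1L, cost = 10, gamma = NULL) {
  protocol <- match.arg(protocol)
  features <- as.matrix(features)
  labels <- as.character(labels)
  n <- nrow(features)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k may not exceed the library size")
  if (k == n)
    stop("k equal to the library size leaves single-item folds, which ",
         "cannot contain two classes; choose a smaller k")
  folds <- with_seed(seed, {
    f <- integer(n)
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      f[idx] <- rep_len(sample(k), length(idx))
    }
    f
  })
  per_fold <- rep(NA_real_, k)
  skipped <- integer(0)
  for (i in seq_len(k)) {
    train_idx <- if (protocol == "inverted") which(folds == i) else
      which(folds != i)
    test_idx <- setdiff(seq_len(n), train_idx)
    tab <- table(labels[train_idx])
    if (length(tab) < 2L || any(tab < 3L) || !length(test_idx)) {
      warning("fold ", i, " skipped: training side lacks two classes ",
              "with >= 3 examples each")
      skipped <- c(skipped, i)
      next
    }
    fit <- train_classifier(features[train_idx, , drop = FALSE],
                            labels[train_idx], cost = cost, gamma = gamma,
                            seed = seed + i)
    pred <- predict(fit, features[test_idx, , drop = FALSE])
    per_fold[i] <- mean(pred$species == labels[test_idx])
  }
  list(per_fold = per_fold, average = mean(per_fold, na.rm = TRUE),
       skipped = skipped, protocol = protocol, k = k)
}

#' Hold-out evaluation with per-species success rates
#'
#' @param model a [train_classifier()] fit.
#' @param features test feature matrix.
#' @param labels true species labels for the test items.
#' @return list with `per_species` (recall: correct / total per species
#'   present in the test set), `overall` accuracy and the `confusion`
#'   table (true x predicted).
#' @export
holdout_evaluate <- function(model, features, labels) {
  labels <- as.character(labels)
  pred <- predict(model, as.matrix(features))
  confusion <- table(true = labels, predicted = pred$species)
  per_species <- vapply(sort(unique(labels)), function(s)
    mean(pred$species[labels == s] == s), 0)
  list(per_species = per_species,
       overall = mean(pred$species == labels),
       confusion = confusion)
}

#' Write identifications to CSV
#' @param identifications data.frame from [classify_tracks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_identifications <- function(identifications, path) {
  write.csv(identifications, path, row.names = FALSE)
  invisible(path)
}
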