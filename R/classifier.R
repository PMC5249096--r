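#' Train the random-forest motion-type classifier
#'
#' Fits a bagged ensemble of classification trees (a random forest) to a
#' labelled feature table. The defaults follow standard random-forest
#' practice for this problem: 500 trees and `mtry = 3` (about the square
#' root of the nine features) candidate features per split, unlimited depth.
#' Features are used as-is - all nine are dimensionless and tree ensembles
#' are invariant to monotone rescaling - so no standardization is applied.
#'
#' @param features A feature table as returned by [track_features()]: a
#'   `true_class` factor column plus numeric feature columns (any numeric
#'   columns other than `id` are used, in their column order).
#' @param ntree Number of trees.
#' @param mtry Number of candidate features per split.
#' @param importance Also compute permutation (mean-decrease-in-accuracy)
#'   importance per class during training; needed by
#'   [feature_importance_mda()].
#' @param seed Optional integer seed; fixed seeds give identical forests.
#' @param metadata Optional named list stored with the model (for example the
#'   training parameter ranges).
#' @return An object of class `motion_classifier` wrapping the fitted forest
#'   with the feature order, class levels and metadata.
#' @examples
#' set.seed(1)
#' feats <- track_features(simulate_training_set(30))
#' clf <- train_motion_classifier(feats, ntree = 50, seed = 1)
#' clf
#' @export
train_motion_classifier <- function(features, ntree = 500, mtry = 3,
                                    importance = FALSE, seed = NULL,
                                    metadata = list()) {
  if (!"true_class" %in% names(features)) {
    abort("`features` needs a `true_class` column",
          class = "sptmotion_schema_error")
  }
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                       "id")
  if (length(feat_cols) < 1) {
    abort("no numeric feature columns found", class = "sptmotion_schema_error")
  }
  X <- as.matrix(features[feat_cols])
  bad <- which(!stats::complete.cases(X))
  if (length(bad) > 0) {
    abort(paste0("missing feature values in row(s): ",
                 paste(head(bad, 10), collapse = ", "),
                 if (length(bad) > 10) ", ..."),
          class = "sptmotion_training_error")
  }
  y <- droplevels(factor(features$true_class,
                         levels = intersect(motion_classes(),
                                            unique(as.character(features$true_class)))))
  if (nlevels(y) < 2) {
    abort("need at least 2 classes to train", class = "sptmotion_training_error")
  }
  mtry <- min(mtry, length(feat_cols))
  forest <- with_seed_if(seed,
    randomForest::randomForest(x = X, y = y, ntree = ntree, mtry = mtry,
                               importance = importance))
  structure(list(forest = forest, feature_names = feat_cols,
                 classes = levels(y), ntree = ntree, mtry = mtry,
                 seed = seed, metadata = metadata,
                 version = as.character(packageVersion("sptmotion"))),
            class = "motion_classifier")
}

#' @export
print.motion_classifier <- function(x, ...) {
  cat("<motion_classifier>", x$ntree, "trees, mtry =", x$mtry, "\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  features:", paste(x$feature_names, collapse = ", "), "\n")
  err <- x$forest$err.rate[x$forest$ntree, "OOB"]
  cat("  OOB error:", sprintf("%.2f%%", 100 * err), "\n")
  invisible(x)
}

#' Predict motion types
#'
#' Classifies trajectories (or precomputed feature rows) with a trained
#' forest. The predicted class is the majority vote over trees and the
#' confidence is the fraction of trees voting for it.
#'
#' @param object A `motion_classifier`.
#' @param newdata A track table or a feature table with the training feature
#'   columns.
#' @param ... Unused.
#' @return A tibble with one row per trajectory: `id`, `class` (factor in the
#'   fixed class order), `confidence`, and one `p_<class>` vote-fraction
#'   column per class (the fractions sum to 1).
#' @export
predict.motion_classifier <- function(object, newdata, ...) {
  if ("x" %in% names(newdata) && "frame" %in% names(newdata)) {
    newdata <- track_features(newdata)
  }
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("feature column(s) missing from newdata: ",
                 paste(missing_cols, collapse = ", ")),
          class = "sptmotion_schema_error")
  }
  X <- as.matrix(newdata[object$feature_names])
  votes <- predict(object$forest, X, type = "vote", norm.votes = TRUE)
  cls <- object$classes[max.col(votes, ties.method = "first")]
  out <- tibble(
    id = if ("id" %in% names(newdata)) newdata$id else seq_len(nrow(X)),
    class = factor(cls, levels = object$classes),
    confidence = votes[cbind(seq_len(nrow(votes)),
                             max.col(votes, ties.method = "first"))])
  vote_cols <- as_tibble(as.data.frame(votes))
  names(vote_cols) <- paste0("p_", colnames(votes))
  dplyr::bind_cols(out, vote_cols)
}

#' Out-of-bag evaluation of a trained classifier
#'
#' Each trajectory is left out of the bootstrap sample of roughly a third of
#' the trees; the vote of those trees gives an unbiased error estimate
#' without a held-out set. Reports the per-class out-of-bag error, its macro
#' average, and the row-normalized out-of-bag confusion matrix (rows =
#' reference class, columns = prediction, in percent).
#'
#' @param clf A `motion_classifier`.
#' @return An object of class `motion_oob` with `tidy()` (per-class errors)
#'   and `glance()` (macro-average and overall error) methods; the `$confusion`
#'   element holds the row-normalized confusion matrix in percent.
#' @export
oob_evaluation <- function(clf) {
  stopifnot(inherits(clf, "motion_classifier"))
  conf <- clf$forest$confusion[, clf$classes, drop = FALSE]
  conf_pct <- sweep(conf, 1, rowSums(conf), "/") * 100
  class_error <- 100 * clf$forest$confusion[, "class.error"]
  overall <- 100 * clf$forest$err.rate[clf$forest$ntree, "OOB"]
  structure(list(confusion = conf_pct, class_error = class_error,
                 macro_error = mean(class_error), overall_error = unname(overall),
                 n = sum(conf)),
            class = "motion_oob")
}

#' @export
print.motion_oob <- function(x, ...) {
  cat("<motion_oob> n =", x$n, "\n")
  cat(sprintf("  macro-average OOB error: %.2f%% (overall %.2f%%)\n",
              x$macro_error, x$overall_error))
  print(round(x$confusion, 2))
  invisible(x)
}

#' @describeIn oob_evaluation One row per class: `class`, `oob_error` (%)
#'   and `diagonal` (% of the class predicted correctly).
#' @param x A `motion_oob` object.
#' @param ... Unused.
#' @method tidy motion_oob
#' @export
tidy.motion_oob <- function(x, ...) {
  tibble(class = rownames(x$confusion),
         oob_error = unname(x$class_error),
         diagonal = diag(x$confusion))
}

#' @describeIn oob_evaluation One row: `macro_error`, `overall_error`, `n`.
#' @method glance motion_oob
#' @export
glance.motion_oob <- function(x, ...) {
  tibble(macro_error = x$macro_error, overall_error = x$overall_error, n = x$n)
}

#' Stratified k-fold cross validation
#'
#' Splits the feature table into `k` class-stratified folds, trains a forest
#' on each training portion and pools the held-out predictions. Reports
#' overall accuracy, Cohen's kappa and one-vs-rest sensitivity/specificity
#' per class.
#'
#' @inheritParams train_motion_classifier
#' @param k Number of folds.
#' @return An object of class `motion_cv` with `tidy()` (per-class
#'   sensitivity/specificity) and `glance()` (accuracy, kappa) methods; the
#'   pooled predictions are in `$predictions`.
#' @export
cross_validate_motion <- function(features, k = 10, ntree = 500, mtry = 3,
                                  seed = NULL) {
  if (k < 2) abort("`k` must be >= 2", class = "sptmotion_config_error")
  if (!"true_class" %in% names(features)) {
    abort("`features` needs a `true_class` column",
          class = "sptmotion_schema_error")
  }
  with_seed_if(seed, {
    y <- factor(features$true_class,
                levels = intersect(motion_classes(),
                                   unique(as.character(features$true_class))))
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(k)) {
      test <- fold == f
      clf <- train_motion_classifier(features[!test, , drop = FALSE],
                                     ntree = ntree, mtry = mtry)
      pred[test] <- as.character(predict(clf, features[test, , drop = FALSE])$class)
    }
    tab <- table(reference = y, prediction = pred)
    n <- sum(tab)
    accuracy <- sum(diag(tab)) / n
    pe <- sum(rowSums(tab) * colSums(tab)) / n^2
    kappa <- (accuracy - pe) / (1 - pe)
    by_class <- dplyr::bind_rows(lapply(levels(y), function(cl) {
      tp <- tab[cl, cl]
      fn <- sum(tab[cl, ]) - tp
      fp <- sum(tab[, cl]) - tp
      tn <- n - tp - fn - fp
      tibble(class = cl, sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp))
    }))
    structure(list(predictions = tibble(id = if ("id" %in% names(features))
                                          features$id else seq_along(y),
                                        truth = y, prediction = pred,
                                        fold = fold),
                   table = tab, accuracy = accuracy, kappa = kappa,
                   by_class = by_class, k = k),
              class = "motion_cv")
  })
}

#' @export
print.motion_cv <- function(x, ...) {
  cat("<motion_cv>", x$k, "folds, n =", sum(x$table), "\n")
  cat(sprintf("  accuracy %.3f, kappa %.3f\n", x$accuracy, x$kappa))
  print(x$by_class)
  invisible(x)
}

#' @describeIn cross_validate_motion Per-class sensitivity and specificity.
#' @param x A `motion_cv` object.
#' @param ... Unused.
#' @method tidy motion_cv
#' @export
tidy.motion_cv <- function(x, ...) x$by_class

#' @describeIn cross_validate_motion One row: `accuracy`, `kappa`, `k`, `n`.
#' @method glance motion_cv
#' @export
glance.motion_cv <- function(x, ...) {
  tibble(accuracy = x$accuracy, kappa = x$kappa, k = x$k, n = sum(x$table))
}

#' Per-class permutation importance (mean decrease in accuracy)
#'
#' For each feature, the out-of-bag accuracy is recomputed after permuting
#' that feature's values; the mean drop, per class and overall, measures how
#' much the classifier relies on the feature. Requires a classifier trained
#' with `importance = TRUE`.
#'
#' @param clf A `motion_classifier` trained with `importance = TRUE`.
#' @return A tibble with one row per feature: `feature`, one column per
#'   class, and `overall` (all mean decreases in accuracy, unscaled).
#' @export
feature_importance_mda <- function(clf) {
  stopifnot(inherits(clf, "motion_classifier"))
  imp <- clf$forest$importance
  if (!"MeanDecreaseAccuracy" %in% colnames(imp)) {
    abort("classifier was trained without `importance = TRUE`",
          class = "sptmotion_config_error")
  }
  out <- as_tibble(as.data.frame(imp[, c(clf$classes, "MeanDecreaseAccuracy"),
                                     drop = FALSE]))
  names(out) <- c(clf$classes, "overall")
  dplyr::bind_cols(tibble(feature = rownames(imp)), out)
}

#' Persist and restore trained classifiers
#'
#' `write_motion_classifier()` serializes the model (forest, feature order,
#' class levels, metadata and package version) to an RDS file;
#' `read_motion_classifier()` restores it and validates the payload. A
#' restored model reproduces predictions exactly.
#'
#' @param clf A `motion_classifier`.
#' @param path File path.
#' @return `write_motion_classifier()` returns `path` invisibly;
#'   `read_motion_classifier()` returns the `motion_classifier`.
#' @export
write_motion_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "motion_classifier"))
  saveRDS(list(format = "sptmotion_motion_classifier", payload = clf), path)
  invisible(path)
}

#' @rdname write_motion_classifier
#' @export
read_motion_classifier <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(paste0("cannot read model file: ", conditionMessage(e)),
          class = "sptmotion_load_error")
  })
  if (!is.list(obj) || !identical(obj$format, "sptmotion_motion_classifier") ||
      !inherits(obj$payload, "motion_classifier")) {
    abort("file is not a saved motion classifier",
          class = "sptmotion_load_error")
  }
  obj$payload
}
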