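#' Fit a supervised behavior classifier over pose windows
#'
#' The main model-fitting entry point. Takes labelled raw pose windows,
#' egocentrically aligns and flattens them, fits the feature pipeline
#' (normalization + PCA) on the training data only, and trains one of
#' three classifiers over the projected features: a random forest (1000
#' trees by default), k-nearest-neighbour, or a support-vector classifier
#' with a radial kernel. Deterministic for a given seed.
#'
#' @param windows List of raw pose windows ([make_windows()] /
#'   [make_training_corpus()] output).
#' @param labels Character or factor vector of behavior classes, one per
#'   window (from the five-class vocabulary, [behavior_classes()]).
#' @param algorithm `"random_forest"`, `"k_nearest"` or `"support_vector"`.
#' @param hyperparams Named list: `ntree` (forest, default 1000), `mtry`
#'   (forest, default `sqrt(p)`), `k` (KNN, default 5), `cost` and `gamma`
#'   (SVC, e1071 defaults). The KNN has no training iterations; the SVC
#'   optimizer runs to convergence.
#' @param pipeline A pre-fitted [fit_pipeline()]; `NULL` fits one on
#'   `windows`.
#' @param var_target Explained-variance target when fitting the pipeline.
#' @param skeleton A [skeleton_spec()].
#' @param seed Integer seed.
#' @return Object of class `behavior_model` with `print`, `summary` and
#'   `predict` methods.
#' @export
fit_behavior_classifier <- function(windows, labels,
                                    algorithm = c("random_forest", "k_nearest",
                                                  "support_vector"),
                                    hyperparams = list(),
                                    pipeline = NULL, var_target = 0.95,
                                    skeleton = skeleton_spec(), seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(length(windows) == length(labels), length(windows) >= 2L)
  labels <- factor(as.character(labels))
  X <- windows_to_features(windows, skeleton)
  if (is.null(pipeline)) pipeline <- fit_pipeline(X, var_target)
  if (pipeline$n_components == 0L)
    stop("feature pipeline is degenerate (no training variance)")
  Z <- predict(pipeline, X)
  colnames(Z) <- paste0("PC", seq_len(ncol(Z)))
  set.seed(seed)
  fit <- switch(algorithm,
    random_forest = {
      ntree <- hyperparams$ntree %||% 1000L
      mtry <- hyperparams$mtry %||% max(1L, floor(sqrt(ncol(Z))))
      randomForest::randomForest(x = Z, y = labels, ntree = ntree, mtry = mtry)
    },
    k_nearest = {
      list(train = Z, cl = labels, k = hyperparams$k %||% 5L)
    },
    support_vector = {
      e1071::svm(x = Z, y = labels,
                 cost = hyperparams$cost %||% 1,
                 gamma = hyperparams$gamma %||% (1 / ncol(Z)),
                 kernel = "radial")
    })
  structure(list(algorithm = algorithm, fit = fit, pipeline = pipeline,
                 classes = levels(labels), skeleton = skeleton,
                 hyperparams = hyperparams, seed = seed,
                 n_train = length(labels)),
            class = "behavior_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# align + flatten a list of raw windows into a feature matrix
windows_to_features <- function(windows, skeleton = skeleton_spec()) {
  t(vapply(windows,
           function(w) flatten_features(egocentric_align(w, skeleton)),
           numeric(dim(if (is.array(windows[[1]])) windows[[1]]
                       else windows[[1]]$coords)[1] * 16L)))
}

#' @export
print.behavior_model <- function(x, ...) {
  cat(sprintf("behavior_model (%s): %d classes, trained on %d windows\n",
              x$algorithm, length(x$classes), x$n_train))
  print(x$pipeline)
  invisible(x)
}

#' @export
summary.behavior_model <- function(object, ...) {
  print(object)
  cat("  classes:", paste(object$classes, collapse = ", "), "\n")
  if (object$algorithm == "random_forest")
    cat(sprintf("  forest: %d trees, OOB error %.3f\n",
                object$fit$ntree, mean(object$fit$err.rate[, "OOB"])))
  invisible(object)
}

#' Predict behavior classes for pose windows
#'
#' @param object A [fit_behavior_classifier()] model.
#' @param newdata List of raw pose windows, or a matrix of already
#'   flattened (aligned) feature vectors.
#' @param ... Unused.
#' @return Factor of predicted classes.
#' @export
predict.behavior_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata
       else windows_to_features(newdata, object$skeleton)
  Z <- predict(object$pipeline, X)
  colnames(Z) <- paste0("PC", seq_len(ncol(Z)))
  pred <- switch(object$algorithm,
    random_forest = predict(object$fit, Z),
    k_nearest = class::knn(object$fit$train, Z, object$fit$cl,
                           k = object$fit$k),
    support_vector = predict(object$fit, Z))
  factor(as.character(pred), levels = object$classes)
}

#' Evaluate a behavior classifier on a labelled test set
#'
#' Builds the confusion matrix (rows = true class, columns = predicted)
#' and computes per-class precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)` with their macro averages, the overall accuracy, and
#' the multiclass F1 score computed literally from the confusion-matrix
#' sums: diagonal total over (diagonal total + half the two off-diagonal
#' totals). For a single-label confusion matrix the two off-diagonal sums
#' coincide, making this identical to overall accuracy.
#'
#' @param model A `behavior_model`.
#' @param windows Test windows (list) or feature matrix.
#' @param labels True classes.
#' @return Object of class `eval_report`.
#' @export
evaluate_classifier <- function(model, windows, labels) {
  if ((is.matrix(windows) && nrow(windows) == 0L) ||
      (!is.matrix(windows) && length(windows) == 0L))
    stop("empty test set")
  pred <- predict(model, windows)
  truth <- factor(as.character(labels), levels = model$classes)
  eval_report(table(truth = truth, predicted = pred))
}

#' Evaluation report from a confusion matrix
#'
#' @param M Square confusion matrix, rows = true class, columns =
#'   predicted class (same class order).
#' @return Object of class `eval_report` with the matrix, per-class
#'   precision/recall, macro averages, overall accuracy and the F1 score.
#'   Classes absent from the test set get `NaN` precision/recall and are
#'   flagged in `undefined_classes`.
#' @export
eval_report <- function(M) {
  M <- as.matrix(unclass(M))
  stopifnot(nrow(M) == ncol(M))
  tp <- diag(M)
  precision <- tp / colSums(M)
  recall <- tp / rowSums(M)
  f1 <- f1_from_confusion(M)
  structure(list(confusion = M,
                 precision = precision, recall = recall,
                 macro_precision = mean(precision, na.rm = TRUE),
                 macro_recall = mean(recall, na.rm = TRUE),
                 accuracy = sum(tp) / sum(M),
                 f1 = f1,
                 per_class_accuracy = recall,
                 n_test = sum(M),
                 undefined_classes = rownames(M)[rowSums(M) == 0]),
            class = "eval_report")
}

#' Multiclass F1 from a confusion matrix
#'
#' Literal evaluation: `sum_i M_ii / (sum_i M_ii + 0.5 * (sum_{i != j}
#' M_ij + sum_{i != j} M_ji))`. Both off-diagonal double sums are written
#' out as printed; they are equal for any square matrix, so the value
#' algebraically equals `trace(M) / sum(M)`.
#'
#' @param M Square confusion matrix.
#' @return F1 score in `[0, 1]`.
#' @export
f1_from_confusion <- function(M) {
  M <- as.matrix(unclass(M))
  n <- nrow(M)
  tp_sum <- sum(diag(M))
  off_ij <- 0; off_ji <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    off_ij <- off_ij + M[i, j]
    off_ji <- off_ji + M[j, i]
  }
  tp_sum / (tp_sum + 0.5 * (off_ij + off_ji))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d test windows\n", x$n_test))
  print(x$confusion)
  cat(sprintf("  accuracy %.3f | F1 %.3f | macro precision %.3f | macro recall %.3f\n",
              x$accuracy, x$f1, x$macro_precision, x$macro_recall))
  if (length(x$undefined_classes))
    cat("  classes absent from test set:",
        paste(x$undefined_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Macro F1 (harmonic per-class average)
#'
#' Companion summary to the confusion-sum F1: mean over classes of the
#' per-class harmonic mean of precision and recall. Reported alongside
#' because "average F score" is ambiguous between the two.
#'
#' @param report An [eval_report()].
#' @return Macro-averaged per-class F1.
#' @export
macro_f1 <- function(report) {
  p <- report$precision; r <- report$recall
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  mean(f, na.rm = TRUE)
}

#' Predict a per-window class sequence for a whole track
#'
#' Windows the cleaned track, drops windows overlapping removed frames,
#' and classifies each retained window.
#'
#' @param model A `behavior_model`.
#' @param track A cleaned [pose_track()].
#' @param params A [windowing_params()].
#' @return Data frame `start_frame` (0-based), `class`; zero rows (with a
#'   warning) when no window is retainable.
#' @export
predict_track <- function(model, track, params = windowing_params()) {
  wins <- make_windows(track, params)
  if (!length(wins)) {
    warning("no retainable windows in track '", track$well_id, "'")
    return(data.frame(start_frame = integer(0),
                      class = character(0)))
  }
  pred <- predict(model, wins)
  data.frame(start_frame = vapply(wins, `[[`, integer(1), "start_frame"),
             class = as.character(pred))
}

#' Save / load a behavior model bundle
#'
#' The bundle is a directory holding the pipeline parameters and model as
#' an RDS plus a JSON sidecar of the pipeline scalars for inspection.
#'
#' @param model A `behavior_model`.
#' @param dir Bundle directory (created if needed).
#' @return `dir`, invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  meta <- list(algorithm = model$algorithm, classes = model$classes,
               n_components = model$pipeline$n_components,
               var_target = model$pipeline$var_target,
               n_train = model$n_train, seed = model$seed)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "pipeline.json"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) readRDS(file.path(dir, "model.rds"))
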