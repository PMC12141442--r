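#' Fit the feature normalization + projection pipeline
#'
#' Fitted on the training split only (never the test split): each feature
#' is centred by its training mean and divided by its maximum absolute
#' value after centring (features with zero spread divide by 1), then an
#' orthogonal principal-component projection retains the smallest number of
#' components whose cumulative explained variance reaches the target
#' (default 95%).
#'
#' @param train_vectors Numeric matrix, one row per training window
#'   (columns = flattened features); at least 2 rows.
#' @param var_target Cumulative explained-variance target in `(0, 1]`.
#' @return Object of class `feature_pipeline` with the normalizers, the
#'   rotation basis, `n_components` (0 when the training set has no
#'   variance, flagged by `degenerate = TRUE`).
#' @export
fit_pipeline <- function(train_vectors, var_target = 0.95) {
  X <- as.matrix(train_vectors)
  if (nrow(X) < 2L) stop("pipeline needs at least 2 training vectors")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  mx <- apply(abs(Xc), 2L, max)
  mx[mx == 0] <- 1
  Xn <- sweep(Xc, 2L, mx, `/`)
  pc <- stats::prcomp(Xn, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  tot <- sum(ev)
  if (tot <= 0 || !any(ev > 0)) {
    return(structure(list(mean = mu, max_abs = mx, rotation = NULL,
                          n_components = 0L, var_target = var_target,
                          explained = numeric(0), degenerate = TRUE,
                          fitted_on_train_only = TRUE),
                     class = "feature_pipeline"))
  }
  k <- which(cumsum(ev) / tot >= var_target)[1]
  structure(list(mean = mu, max_abs = mx,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 n_components = k, var_target = var_target,
                 explained = cumsum(ev)[k] / tot, degenerate = FALSE,
                 fitted_on_train_only = TRUE),
            class = "feature_pipeline")
}

#' @export
print.feature_pipeline <- function(x, ...) {
  if (x$degenerate) {
    cat("feature_pipeline: degenerate (no training variance), 0 components\n")
  } else {
    cat(sprintf("feature_pipeline: %d features -> %d components (%.1f%% variance)\n",
                length(x$mean), x$n_components, 100 * x$explained))
  }
  invisible(x)
}

#' Apply a fitted pipeline to feature vectors
#'
#' Uses the training-set normalizers and basis bitwise-identically for any
#' input split.
#'
#' @param object A [fit_pipeline()] result.
#' @param newdata Matrix of feature vectors (rows) or a single vector.
#' @param ... Unused.
#' @return Matrix of projected features (`n x n_components`).
#' @export
predict.feature_pipeline <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  Xn <- sweep(sweep(X, 2L, object$mean), 2L, object$max_abs, `/`)
  if (object$n_components == 0L)
    return(matrix(numeric(0), nrow(X), 0L))
  Xn %*% object$rotation
}

#' Class-balanced train/test split of labelled clips
#'
#' For each behavior class, 90% of clips (by default) are randomly assigned
#' to training and 10% to test; the test set is then balanced by keeping,
#' per class, only as many clips as the smallest class contributed, and the
#' surplus test clips are returned to the training set. Deterministic for a
#' given seed.
#'
#' @param labels Factor or character vector of clip labels.
#' @param test_frac Test fraction per class (default 0.10).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (into
#'   `labels`) and `per_class_test`, the balanced per-class test count.
#' @export
balanced_test_split <- function(labels, test_frac = 0.10, seed = 1L) {
  labels <- as.character(labels)
  classes <- unique(labels)
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("every class needs at least 2 clips; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  set.seed(seed)
  test_by_class <- list()
  train <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_test <- max(1L, floor(length(idx) * test_frac))
    shuf <- sample(idx)
    test_by_class[[cl]] <- shuf[seq_len(n_test)]
    train <- c(train, shuf[-seq_len(n_test)])
  }
  n_bal <- min(lengths(test_by_class))
  test <- integer(0)
  for (cl in classes) {
    tc <- test_by_class[[cl]]
    test <- c(test, tc[seq_len(n_bal)])
    if (length(tc) > n_bal) train <- c(train, tc[-seq_len(n_bal)])
  }
  list(train = sort(train), test = sort(test), per_class_test = n_bal)
}
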