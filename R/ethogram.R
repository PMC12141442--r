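#' Build a per-frame ethogram from overlapping window predictions
#'
#' Each frame's label is the majority vote over the windows covering it;
#' ties break toward the less severe class in the fixed order stationary <
#' normal_swim < whirlpool < convulsion < posture_loss (avoiding inflation
#' of seizure calls). Frames covered by no window are `"unscored"`.
#' Class fractions are computed over scored frames and sum to 1.
#'
#' @param predictions Data frame with `start_frame` (0-based) and `class`
#'   ([predict_track()] output).
#' @param n_frames Total frame count of the track.
#' @param params The [windowing_params()] used for prediction.
#' @param well_id,epoch_label Identifiers carried on the result.
#' @return Object of class `ethogram`: `labels` (length `n_frames`
#'   character), `fractions` (named numeric over the five classes, summing
#'   to 1 over scored frames), `n_scored`.
#' @export
ethogram_from_predictions <- function(predictions, n_frames,
                                      params = windowing_params(),
                                      well_id = "well",
                                      epoch_label = "other") {
  if (!nrow(predictions)) stop("need at least one window prediction")
  classes <- behavior_classes()
  w <- params$window_len
  votes <- matrix(0L, n_frames, length(classes),
                  dimnames = list(NULL, classes))
  for (r in seq_len(nrow(predictions))) {
    s <- predictions$start_frame[r]
    cl <- predictions$class[r]
    idx <- (s + 1L):min(s + w, n_frames)
    votes[idx, cl] <- votes[idx, cl] + 1L
  }
  covered <- rowSums(votes) > 0L
  labels <- rep("unscored", n_frames)
  if (any(covered)) {
    # max.col with ties.method "first" picks the lowest column index,
    # which is the less severe class in the fixed ordering
    labels[covered] <- classes[max.col(votes[covered, , drop = FALSE],
                                       ties.method = "first")]
  }
  tab <- table(factor(labels[covered], levels = classes))
  fractions <- as.numeric(tab) / sum(tab)
  names(fractions) <- classes
  structure(list(labels = labels, fractions = fractions,
                 n_scored = sum(covered), well_id = well_id,
                 epoch_label = epoch_label),
            class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("ethogram '%s' (%s): %d frames scored of %d\n",
              x$well_id, x$epoch_label, x$n_scored, length(x$labels)))
  for (cl in names(x$fractions))
    cat(sprintf("  %-12s %5.1f%%\n", cl, 100 * x$fractions[[cl]]))
  invisible(x)
}

#' Plot an ethogram as a coloured class raster over time
#'
#' @param x An [ethogram_from_predictions()] result.
#' @param fps Frame rate used to label the time axis.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.ethogram <- function(x, fps = 160, ...) {
  classes <- behavior_classes()
  cols <- c(stationary = "#1f2e7a", normal_swim = "#35b0ab",
            whirlpool = "#f2a541", convulsion = "#d7263d",
            posture_loss = "#7b2d8b", unscored = "grey85")
  z <- match(x$labels, c(classes, "unscored"))
  graphics::image(x = seq_along(z) / fps, y = 1, z = matrix(z, ncol = 1),
                  col = cols, zlim = c(1, 6), xlab = "time (s)", ylab = "",
                  yaxt = "n", main = sprintf("%s (%s)", x$well_id,
                                             x$epoch_label), ...)
  invisible(x)
}
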