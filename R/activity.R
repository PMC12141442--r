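#' Activity-metric parameters
#'
#' The activity metric counts, for each pair of sequential frames, the
#' pixels whose change is large both relative to their brightness and in
#' absolute terms: a pixel counts iff
#' `2*|P_i - P_{i-1}| / (P_i + P_{i-1}) > t_rel` AND `|P_i - P_{i-1}| > d_abs`.
#' Both comparisons are strict. Pixels with `P_i + P_{i-1} = 0` contribute
#' nothing: the relative change is undefined there but `|delta| = 0` already
#' fails the absolute condition.
#'
#' @param t_rel Relative-change threshold (unitless; default 0.1).
#' @param d_abs Absolute-change threshold (pixel-value units; default 20).
#' @param exclusion_threshold Total-activity cutoff in pixels below which a
#'   larva is flagged inactive (default 20000).
#' @return Object of class `activity_params`.
#' @export
activity_params <- function(t_rel = 0.1, d_abs = 20, exclusion_threshold = 20000) {
  stopifnot(t_rel > 0, d_abs >= 0, exclusion_threshold >= 0)
  structure(list(t_rel = t_rel, d_abs = d_abs,
                 exclusion_threshold = exclusion_threshold),
            class = "activity_params")
}

#' Pixel-change activity between two frames
#'
#' @param prev,curr Grayscale frames (numeric matrices of the same shape,
#'   non-negative values).
#' @param params An [activity_params()].
#' @return Integer count of pixels passing both thresholds.
#' @export
frame_pair_activity <- function(prev, curr, params = activity_params()) {
  if (!identical(dim(prev), dim(curr)))
    stop("frames differ in shape: ", paste(dim(prev), collapse = "x"),
         " vs ", paste(dim(curr), collapse = "x"))
  d <- abs(as.numeric(curr) - as.numeric(prev))
  s <- as.numeric(curr) + as.numeric(prev)
  rel <- ifelse(s > 0, 2 * d / s, 0)
  sum(rel > params$t_rel & d > params$d_abs)
}

#' Activity trace over a frame stack
#'
#' Applies [frame_pair_activity()] to each sequential frame pair, yielding a
#' length `T - 1` trace and its sum, the total activity for the epoch.
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @param params An [activity_params()].
#' @param epoch_label Epoch tag carried on the result.
#' @return Object of class `activity_trace` with fields `activity`
#'   (integer vector), `total_activity`, `well_id`, `epoch_label`.
#' @export
activity_trace <- function(stack, params = activity_params(),
                           epoch_label = "other") {
  n <- length(stack$frames)
  if (n < 2L) stop("activity trace needs at least 2 frames")
  a <- integer(n - 1L)
  for (i in 2:n)
    a[i - 1L] <- frame_pair_activity(stack$frames[[i - 1L]],
                                     stack$frames[[i]], params)
  structure(list(activity = a, total_activity = sum(a),
                 well_id = stack$well_id, epoch_label = epoch_label),
            class = "activity_trace")
}

#' @export
print.activity_trace <- function(x, ...) {
  cat(sprintf("activity_trace '%s' (%s): %d frame pairs, total %d px\n",
              x$well_id, x$epoch_label, length(x$activity),
              x$total_activity))
  invisible(x)
}

#' Inactivity exclusion rule
#'
#' Larvae whose total activity during the late treatment epoch (TP2) falls
#' below the exclusion threshold (default 20,000 pixels) are excluded from
#' pose-track analysis; the rule flags larvae that did not survive
#' treatment.
#'
#' @param trace_tp2 An [activity_trace()] from the TP2 epoch.
#' @param params An [activity_params()].
#' @return `TRUE` if the larva should be excluded (strictly below threshold).
#' @export
flag_inactive <- function(trace_tp2, params = activity_params()) {
  trace_tp2$total_activity < params$exclusion_threshold
}

#' Write an activity trace as CSV
#'
#' Columns `frame_pair,activity` plus a final `total` summary row.
#' @param trace An [activity_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_activity_trace <- function(trace, path) {
  d <- data.frame(frame_pair = seq_along(trace$activity) - 1L,
                  activity = trace$activity)
  d <- rbind(d, data.frame(frame_pair = "total",
                           activity = trace$total_activity))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
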