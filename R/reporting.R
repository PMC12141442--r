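#' Speed-banded trajectory table for tracking plots
#'
#' Per-frame COM position, speed and speed band: frames at 0-50 mm/s fall
#' on a blue-to-red gradient (`"gradient"` band plus a 0-1 `gradient_pos`
#' column), frames above 50 mm/s form a distinct `"fast"` band (plotted
#' green).
#'
#' @param kin A [kinematic_series()].
#' @param fast_cutoff Fast-band threshold in mm/s (default 50).
#' @return Data frame `frame, x, y, speed, band, gradient_pos`.
#' @export
tracking_plot_data <- function(kin, fast_cutoff = 50) {
  f <- kin$frames[kin$frames$valid, ]
  band <- ifelse(is.na(f$speed), "gradient",
                 ifelse(f$speed > fast_cutoff, "fast", "gradient"))
  gp <- pmin(ifelse(is.na(f$speed), 0, f$speed), fast_cutoff) / fast_cutoff
  data.frame(frame = f$frame, x = f$com_x, y = f$com_y,
             speed = f$speed, band = band, gradient_pos = gp)
}

#' Per-larva epoch summary table
#'
#' One row per larva/epoch: total activity and its `log10(x + 1)` display
#' value, total distance (m), maximum speed (mm/s), mean inter-eye
#' distance (mm), and tail-angle / absolute heading-change quantiles.
#'
#' @param kin A [kinematic_series()].
#' @param activity An optional [activity_trace()] for the same epoch.
#' @return One-row data frame.
#' @export
epoch_summary <- function(kin, activity = NULL) {
  s <- kin$summary
  total_act <- if (is.null(activity)) NA_real_ else activity$total_activity
  d <- data.frame(well_id = kin$well_id, epoch = kin$epoch_label,
                  total_activity = total_act,
                  log10_activity = log10(total_act + 1),
                  total_distance_m = s$total_distance_m,
                  max_speed = s$max_speed,
                  mean_inter_eye = s$mean_inter_eye)
  for (q in names(s$tail_angle_q))
    d[[paste0("tail_angle_q", sub("%", "", q))]] <- s$tail_angle_q[[q]]
  for (q in names(s$heading_change_abs_q))
    d[[paste0("heading_abs_q", sub("%", "", q))]] <- s$heading_change_abs_q[[q]]
  d
}

#' Compare a per-larva metric between two groups or epochs
#'
#' Paired designs (the same larvae across epochs) use the Wilcoxon
#' matched-pairs signed-rank test; unpaired designs (e.g. mutant vs
#' wild-type sibling) use the two-sample t-test. Both report two-tailed
#' p-values; Shapiro-Wilk and Kolmogorov-Smirnov normality screens on each
#' group are reported alongside so the test choice can be audited.
#' Identical paired vectors (all zero differences) return p = 1 by
#' convention.
#'
#' @param values_a,values_b Numeric vectors (equal length when paired).
#' @param design `"paired"` or `"unpaired"`.
#' @param metric Name of the compared metric, carried on the result.
#' @return Object of class `group_comparison` with the statistic, p-value
#'   and normality screens.
#' @export
compare_groups <- function(values_a, values_b,
                           design = c("paired", "unpaired"),
                           metric = "metric") {
  design <- match.arg(design)
  if (design == "paired" && length(values_a) != length(values_b))
    stop("paired design requires equal-length matched vectors")
  norm_screen <- function(x) {
    sw <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
    z <- (x - mean(x)) / stats::sd(x)
    ks <- tryCatch(suppressWarnings(stats::ks.test(z, "pnorm")$p.value),
                   error = function(e) NA_real_)
    c(shapiro_p = sw, ks_p = ks)
  }
  if (design == "paired") {
    diffs <- values_b - values_a
    if (all(diffs == 0)) {
      test <- list(statistic = c(V = 0), p.value = 1,
                   method = "Wilcoxon signed rank (all differences zero)")
    } else {
      test <- suppressWarnings(
        stats::wilcox.test(values_a, values_b, paired = TRUE,
                           alternative = "two.sided"))
    }
  } else {
    test <- stats::t.test(values_a, values_b, alternative = "two.sided",
                          var.equal = FALSE)
  }
  structure(list(metric = metric, design = design,
                 statistic = unname(test$statistic),
                 statistic_name = names(test$statistic),
                 p_value = test$p.value, method = test$method,
                 n_a = length(values_a), n_b = length(values_b),
                 normality_a = norm_screen(values_a),
                 normality_b = norm_screen(values_b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison '%s' (%s): %s = %.4g, p = %.4g (two-tailed)\n",
              x$metric, x$design, x$statistic_name, x$statistic, x$p_value))
  cat(sprintf("  n = %d vs %d; normality (Shapiro p): %.3g / %.3g\n",
              x$n_a, x$n_b, x$normality_a[["shapiro_p"]],
              x$normality_b[["shapiro_p"]]))
  invisible(x)
}

#' Speed-threshold diagnostic over a cohort
#'
#' Pools per-frame speeds over a cohort of cleaned-or-raw tracks and
#' returns a log-scale histogram table, the diagnostic behind choosing a
#' biologically plausible speed gate.
#'
#' @param tracks List of [pose_track()] objects in mm.
#' @param breaks Histogram breaks in mm/s.
#' @return Data frame `speed_lo, speed_hi, count`.
#' @export
speed_histogram <- function(tracks, breaks = c(0, 2^(0:9))) {
  sp <- unlist(lapply(tracks, function(tr) {
    s <- speed_series(tr)$speed
    s[is.finite(s)]
  }))
  h <- graphics::hist(pmin(sp, max(breaks)), breaks = breaks, plot = FALSE)
  data.frame(speed_lo = h$breaks[-length(h$breaks)],
             speed_hi = h$breaks[-1], count = h$counts)
}
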