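#' Read a pose table from CSV
#'
#' The pose table dialect is a CSV with header
#' `frame,kp0_x,kp0_y,...,kp7_x,kp7_y` preceded by optional metadata comment
#' lines of the form `# key=value` (`fps`, `unit`, `mm_per_px`,
#' `well_center` as `x;y`, `well_radius`, `well_id`, `epoch_label`).
#' Missing coordinates (empty fields or `NaN`) mark the whole frame invalid.
#'
#' @param path Path to the CSV file.
#' @param skeleton A [skeleton_spec()].
#' @param fps,mm_per_px Calibration overrides; `NULL` takes the file header
#'   (or the [pose_track()] defaults if the header is silent).
#' @return A [pose_track()].
#' @export
read_pose_table <- function(path, skeleton = skeleton_spec(),
                            fps = NULL, mm_per_px = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0)
      meta[[trimws(substr(kv, 1, eq - 1))]] <- trimws(substr(kv, eq + 1, nchar(kv)))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("pose table has no header row: ", path)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  expected <- c("frame", paste0("kp", rep(0:7, each = 2), c("_x", "_y")))
  if (length(header) != 17L || !all(trimws(header) == expected))
    stop("malformed pose table header in ", path,
         " (expected 'frame,kp0_x,kp0_y,...,kp7_y')")
  rows <- body[-1]
  n <- length(rows)
  mat <- matrix(NA_real_, n, 17L)
  for (i in seq_len(n)) {
    f <- strsplit(rows[i], ",", fixed = TRUE)[[1]]
    if (length(f) == 16L && endsWith(rows[i], ",")) f <- c(f, "")
    if (length(f) != 17L)
      stop("row ", i, " of ", path, " has ", length(f),
           " fields; 17 expected (frame + 8 key-points x 2)")
    f[!nzchar(trimws(f))] <- "NaN"
    mat[i, ] <- suppressWarnings(as.numeric(f))
  }
  if (anyNA(mat[, 1]) || (n > 1 && any(diff(mat[, 1]) <= 0)))
    stop("non-monotonic or missing frame index in ", path,
         " (first offending row: ",
         if (anyNA(mat[, 1])) which(is.na(mat[, 1]))[1]
         else which(diff(mat[, 1]) <= 0)[1] + 1L, ")")
  coords <- array(NA_real_, c(n, 8L, 2L))
  for (k in 0:7) {
    coords[, k + 1L, 1L] <- mat[, 2L + 2L * k]
    coords[, k + 1L, 2L] <- mat[, 3L + 2L * k]
  }
  num <- function(key, default) if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
  fps <- if (!is.null(fps)) fps else num("fps", 160)
  mm_per_px <- if (!is.null(mm_per_px)) mm_per_px else num("mm_per_px", 0.0249)
  wc <- if (!is.null(meta$well_center))
    as.numeric(strsplit(meta$well_center, ";", fixed = TRUE)[[1]]) else NULL
  pose_track(coords, fps = fps,
             unit = if (!is.null(meta$unit)) meta$unit else "mm",
             mm_per_px = mm_per_px,
             well_id = if (!is.null(meta$well_id)) meta$well_id else "well",
             epoch_label = if (!is.null(meta$epoch_label)) meta$epoch_label else "other",
             well_center = wc, well_radius = num("well_radius", NULL),
             skeleton = skeleton)
}

#' Write a pose track to CSV
#'
#' Inverse of [read_pose_table()]: metadata is persisted as `# key=value`
#' comment lines and invalid frames are written as rows of empty coordinate
#' fields, so a read/write round trip reproduces the coordinates (to the
#' written precision) and the mask exactly.
#'
#' @param track A [pose_track()].
#' @param path Output file path.
#' @param digits Significant digits written for coordinates.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(track, path, digits = 10) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fps=%.10g", track$fps),
               sprintf("# unit=%s", track$unit),
               sprintf("# mm_per_px=%.10g", track$mm_per_px),
               sprintf("# well_id=%s", track$well_id),
               sprintf("# epoch_label=%s", track$epoch_label)), con)
  if (!is.null(track$well_center))
    writeLines(sprintf("# well_center=%.10g;%.10g",
                       track$well_center[1], track$well_center[2]), con)
  if (!is.null(track$well_radius))
    writeLines(sprintf("# well_radius=%.10g", track$well_radius), con)
  writeLines(paste(c("frame", paste0("kp", rep(0:7, each = 2), c("_x", "_y"))),
                   collapse = ","), con)
  n <- n_frames(track)
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  for (i in seq_len(n)) {
    if (track$valid[i]) {
      xy <- as.vector(t(track$coords[i, , ]))  # kp-major, (x, y) pairs
      writeLines(paste(c(i - 1L, fmt(xy)), collapse = ","), con)
    } else {
      writeLines(paste(c(i - 1L, rep("", 16L)), collapse = ","), con)
    }
  }
  invisible(path)
}

#' Frame stack container
#'
#' An ordered list of identically sized grayscale frames from one well; the
#' substrate of the pixel-change activity metric.
#'
#' @param frames List of numeric matrices (rows x cols), non-negative
#'   integer pixel values.
#' @param well_id Well identifier.
#' @param fps Frame rate in frames/s.
#' @return Object of class `frame_stack`.
#' @export
frame_stack <- function(frames, well_id = "well", fps = 160) {
  if (!length(frames)) stop("frame stack is empty")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same shape")
  if (any(vapply(frames, function(f) any(f < 0), logical(1))))
    stop("pixel values must be non-negative")
  structure(list(frames = frames, well_id = well_id, fps = fps),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame_stack '%s': %d frames of %d x %d @ %g fps\n",
              x$well_id, length(x$frames), d[1], d[2], x$fps))
  invisible(x)
}

#' Read a grayscale frame stack from multi-page TIFF
#'
#' @param path Path to an 8- or 16-bit grayscale (single-channel) TIFF.
#' @param fps Frame rate to record on the stack.
#' @return A [frame_stack()] with integer pixel values preserved.
#' @export
read_frame_stack <- function(path, fps = 160) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] > 1L)
        stop("multi-channel (RGB) TIFF: convert to grayscale before reading")
      p <- p[, , 1L]
    }
    storage.mode(p) <- "double"
    p
  })
  frame_stack(frames, well_id = sub("\\.[^.]*$", "", basename(path)), fps = fps)
}

#' Write a frame stack to multi-page TIFF
#'
#' @param stack A [frame_stack()]; pixel values must fit the chosen bit depth.
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path, bits = 16L) {
  maxv <- 2^bits - 1
  imgs <- lapply(stack$frames, function(f) {
    if (any(f > maxv)) stop("pixel values exceed ", bits, "-bit range")
    f / maxv
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a labelled-clip table
#'
#' CSV with columns `clip_id,track_file,start_frame,label`; labels must be
#' drawn from the five-class vocabulary.
#'
#' @param path CSV path.
#' @return Data frame with the four columns, labels validated.
#' @export
read_clip_labels <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clip_id", "track_file", "start_frame", "label")
  if (!all(need %in% names(d)))
    stop("label file must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(d$label), behavior_classes())
  if (length(bad))
    stop("unknown behavior labels: ", paste(bad, collapse = ", "))
  if (anyDuplicated(d[, c("track_file", "start_frame")]))
    stop("duplicate (track_file, start_frame) identities in label set")
  d
}

#' The five-class behavior vocabulary
#'
#' Ordered from least to most severe; the ordering is used for ethogram
#' vote tie-breaking.
#' @return Character vector of the five class names.
#' @export
behavior_classes <- function() {
  c("stationary", "normal_swim", "whirlpool", "convulsion", "posture_loss")
}
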