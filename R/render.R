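#' Render a pose track as a grayscale frame stack
#'
#' Draws each frame as a bright background with the larva body as dark
#' capsules along the midline key-points (plus eye dots), at the pixel
#' scale of the well. The rendering exists to exercise the pixel-change
#' activity metric end-to-end, not to look photorealistic. Pixel (row,
#' col) covers the square with centre `((col - 0.5) * mm_per_px,
#' (row - 0.5) * mm_per_px)` in track coordinates.
#'
#' @param track A [pose_track()] in mm.
#' @param well A [sim_well()]; supplies frame size and pixel scale.
#' @param background,body Background and body pixel values.
#' @param body_radius_mm Capsule radius around the midline.
#' @return A [frame_stack()] of `frame_px x frame_px` frames.
#' @export
render_frames <- function(track, well = sim_well(), background = 220,
                          body = 30, body_radius_mm = 0.12) {
  track <- convert_unit(track, "mm")
  px <- well$frame_px
  s <- well$mm_per_px
  mid <- track$skeleton$midline
  eyes <- setdiff(seq_len(8L), mid)
  frames <- vector("list", n_frames(track))
  for (i in seq_len(n_frames(track))) {
    img <- matrix(background, px, px)
    if (track$valid[i]) {
      pts <- track$coords[i, , ]
      img <- draw_capsules(img, pts[mid, , drop = FALSE], body_radius_mm, s,
                           body, chain = TRUE)
      img <- draw_capsules(img, pts[eyes, , drop = FALSE], 0.05, s, body,
                           chain = FALSE)
    }
    frames[[i]] <- img
  }
  frame_stack(frames, well_id = track$well_id, fps = track$fps)
}

# paint dark capsules onto img: around each chain segment (chain = TRUE)
# or each point (chain = FALSE); works on the pixel bounding box only
draw_capsules <- function(img, pts, radius_mm, mm_per_px, value, chain) {
  px <- nrow(img)
  segs <- if (chain && nrow(pts) > 1L)
    lapply(seq_len(nrow(pts) - 1L), function(j) rbind(pts[j, ], pts[j + 1L, ]))
  else lapply(seq_len(nrow(pts)), function(j) rbind(pts[j, ], pts[j, ]))
  for (sg in segs) {
    lo <- pmin(sg[1, ], sg[2, ]) - radius_mm
    hi <- pmax(sg[1, ], sg[2, ]) + radius_mm
    c0 <- max(1L, floor(lo[1] / mm_per_px) + 1L)
    c1 <- min(px, ceiling(hi[1] / mm_per_px))
    r0 <- max(1L, floor(lo[2] / mm_per_px) + 1L)
    r1 <- min(px, ceiling(hi[2] / mm_per_px))
    if (c0 > c1 || r0 > r1) next
    xs <- (c0:c1 - 0.5) * mm_per_px
    ys <- (r0:r1 - 0.5) * mm_per_px
    gx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    gy <- matrix(ys, length(ys), length(xs))
    d <- dist_to_segment(gx, gy, sg[1, ], sg[2, ])
    blk <- img[r0:r1, c0:c1, drop = FALSE]
    blk[d <= radius_mm] <- value
    img[r0:r1, c0:c1] <- blk
  }
  img
}

# elementwise distance from grid points to the segment a-b
dist_to_segment <- function(gx, gy, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((gx - a[1])^2 + (gy - a[2])^2))
  t <- ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((gx - (a[1] + t * ab[1]))^2 + (gy - (a[2] + t * ab[2]))^2)
}
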