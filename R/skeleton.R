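#' Skeleton convention for 8-key-point larval pose
#'
#' Defines the ordered key-point roles used throughout the pipeline. The
#' convention must name exactly eight points including `snout`, `eye_left`,
#' `eye_right`, `center` and `caudal_fin`; the six non-eye points form the
#' midline used for the centre of mass (the eye points bias the COM
#' rostrally and are excluded from it).
#'
#' @param roles Character vector of length 8 mapping key-point index
#'   (1-based in R) to role name.
#' @return An object of class `skeleton_spec` with elements `roles` and
#'   `midline` (integer indices of the 6 midline points).
#' @examples
#' sk <- skeleton_spec()
#' sk$roles
#' @export
skeleton_spec <- function(roles = c("snout", "eye_left", "eye_right",
                                    "rostral_trunk", "center",
                                    "caudal_trunk", "mid_tail",
                                    "caudal_fin")) {
  if (length(roles) != 8L || anyDuplicated(roles))
    stop("skeleton must name exactly 8 distinct key-points")
  required <- c("snout", "eye_left", "eye_right", "center", "caudal_fin")
  missing <- setdiff(required, roles)
  if (length(missing))
    stop("skeleton is missing required roles: ", paste(missing, collapse = ", "))
  midline <- which(!roles %in% c("eye_left", "eye_right"))
  stopifnot(length(midline) == 6L)
  structure(list(roles = roles, midline = midline), class = "skeleton_spec")
}

#' @export
print.skeleton_spec <- function(x, ...) {
  cat("8-key-point skeleton:\n")
  cat(" ", paste(sprintf("[%d] %s", seq_along(x$roles) - 1L, x$roles),
                 collapse = ", "), "\n")
  cat("  midline indices (0-based):",
      paste(x$midline - 1L, collapse = ", "), "\n")
  invisible(x)
}

# index helpers (1-based, internal)
kp_index <- function(skeleton, role) {
  i <- match(role, skeleton$roles)
  if (is.na(i)) stop("skeleton has no role '", role, "'")
  i
}
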