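# Periodized orthogonal discrete wavelet transform and shrinkage denoising.
# Implemented in-package: the analysis needs only 1-D multilevel DWT with a
# handful of orthonormal filters, soft thresholding and MAD noise scaling.

#' Orthonormal wavelet filter coefficients
#'
#' @param name One of `"sym4"` (symlet-4, the default used for track
#'   denoising), `"db4"` or `"haar"`.
#' @return List with `lo` and `hi` decomposition filters (orthonormal;
#'   `sum(lo^2) == 1`).
#' @export
wavelet_filters <- function(name = "sym4") {
  lo <- switch(name,
    sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
             0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
             -0.01260396726203783, 0.03222310060404270),
    db4 = c(-0.01059740178499728, 0.03288301166698295, 0.03084138183598697,
            -0.18703481171888114, -0.02798376941698385, 0.63088076792959036,
            0.71484657055254153, 0.23037781330885523),
    haar = c(1, 1) / sqrt(2),
    stop("unknown wavelet '", name, "' (supported: sym4, db4, haar)"))
  L <- length(lo)
  hi <- (-1)^(seq_len(L) - 1L) * rev(lo)
  list(lo = lo, hi = hi)
}

# one level of the periodized DWT: x (even length >= filter length) ->
# list(a, d), each length n/2. a[k] = sum_m lo[m] x[(2(k-1)+m-1) mod n + 1].
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt$lo)
  half <- n %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], half, L)
  list(a = drop(xm %*% filt$lo), d = drop(xm %*% filt$hi))
}

# inverse of dwt_step (transpose of the orthogonal analysis operator)
idwt_step <- function(a, d, filt) {
  half <- length(a)
  n <- 2L * half
  L <- length(filt$lo)
  x <- numeric(n)
  for (m in seq_len(L)) {
    j <- (2L * (seq_len(half) - 1L) + (m - 1L)) %% n + 1L
    x[j] <- x[j] + a * filt$lo[m] + d * filt$hi[m]
  }
  x
}

#' Multilevel periodized wavelet decomposition
#'
#' @param x Numeric vector; length must be divisible by `2^levels`.
#' @param wavelet Filter name for [wavelet_filters()].
#' @param levels Number of decomposition levels; `NULL` picks the deepest
#'   level at which the approximation stays at least as long as the filter.
#' @return List with `approx` (coarsest approximation), `details` (list of
#'   detail vectors, finest first) and the transform metadata.
#' @export
wavelet_decompose <- function(x, wavelet = "sym4", levels = NULL) {
  filt <- wavelet_filters(wavelet)
  L <- length(filt$lo)
  n <- length(x)
  max_lev <- 0L
  len <- n
  while (len %% 2L == 0L && len %/% 2L >= L) {
    max_lev <- max_lev + 1L
    len <- len %/% 2L
  }
  if (is.null(levels)) levels <- max_lev
  if (levels > max_lev)
    stop("requested ", levels, " levels but length ", n, " supports ", max_lev)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a, filt)
    details[[j]] <- s$d
    a <- s$a
  }
  list(approx = a, details = details, wavelet = wavelet, n = n)
}

#' Reconstruct a series from its wavelet decomposition
#' @param dec Result of [wavelet_decompose()].
#' @return Numeric vector of the original length.
#' @export
wavelet_reconstruct <- function(dec) {
  filt <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (j in rev(seq_along(dec$details)))
    a <- idwt_step(a, dec$details[[j]], filt)
  a
}

#' Robust noise-scale estimate for a time series
#'
#' Estimates the standard deviation of additive noise as the median absolute
#' deviation of the finest-level wavelet detail coefficients divided by
#' 0.6745 (the classic MAD estimator: smooth signal content lives in the
#' approximation band, so the finest details are essentially noise).
#'
#' @param series Numeric vector with at least 8 finite samples (non-finite
#'   entries are dropped).
#' @param wavelet Filter name.
#' @return Estimated noise standard deviation (same units as `series`).
#' @export
estimate_sigma <- function(series, wavelet = "sym4") {
  x <- series[is.finite(series)]
  if (length(x) < 8L)
    stop("sigma estimation needs at least 8 valid samples")
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  filt <- wavelet_filters(wavelet)
  d <- dwt_step(x, filt)$d
  stats::median(abs(d)) / 0.6745
}

#' Wavelet shrinkage denoising of a 1-D series
#'
#' Soft-thresholds all detail coefficients of a multilevel periodized
#' decomposition at the universal threshold `sigma * sqrt(2 * log(n))` and
#' reconstructs. Series whose length is not a multiple of `2^levels` are
#' extended by symmetric reflection at the end and trimmed after
#' reconstruction. Constant series and `sigma = 0` pass through unchanged
#' (up to floating round-off).
#'
#' @param series Numeric vector.
#' @param sigma Noise scale; `"estimate"` uses [estimate_sigma()].
#' @param wavelet Filter name (default `"sym4"`).
#' @param levels Decomposition depth, `NULL` for the maximum supported.
#' @param threshold_levels How many of the finest detail levels to
#'   threshold (default 2). White tracking noise concentrates in the
#'   finest bands, which is also where the sigma estimate is taken;
#'   coarser bands carry the behavioral signal and are left untouched.
#'   `Inf` thresholds every level.
#' @return Denoised series, same length as the input. Series shorter than
#'   the filter support are returned unchanged with a warning.
#' @export
wavelet_denoise <- function(series, sigma = "estimate", wavelet = "sym4",
                            levels = NULL, threshold_levels = 2L) {
  n <- length(series)
  filt <- wavelet_filters(wavelet)
  L <- length(filt$lo)
  if (n < 2L * L) {
    warning("series of length ", n, " is shorter than the minimum support (",
            2L * L, "); returned unchanged")
    return(series)
  }
  if (identical(sigma, "estimate")) sigma <- estimate_sigma(series, wavelet)
  stopifnot(is.numeric(sigma), sigma >= 0)
  if (sigma == 0) return(series)
  # depth so the coarsest approximation stays at least one filter long,
  # then pad by end-reflection to a multiple of 2^depth
  lev <- max(1L, floor(log2(n / L)))
  if (!is.null(levels)) lev <- min(lev, levels)
  block <- 2L^lev
  pad_to <- as.integer(ceiling(n / block) * block)
  x <- if (pad_to > n) c(series, rev(series)[seq_len(pad_to - n)]) else series
  dec <- wavelet_decompose(x, wavelet, levels = lev)
  lambda <- sigma * sqrt(2 * log(length(x)))
  soft <- function(w) sign(w) * pmax(abs(w) - lambda, 0)
  jmax <- min(length(dec$details), threshold_levels)
  for (j in seq_len(jmax)) dec$details[[j]] <- soft(dec$details[[j]])
  out <- wavelet_reconstruct(dec)
  out[seq_len(n)]
}
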