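#' Sample-entropy parameters
#'
#' Bundles the parameters of the sample-entropy estimator: the embedding
#' (pattern) dimension `m`, the tolerance expressed as a fraction of the
#' segment's standard deviation, and the largest coarse-graining scale factor
#' for a multiscale entropy curve. Defaults are `m = 2`, `r_frac = 0.2`,
#' `max_sf = 40`, the convention used throughout clinical MSE work.
#'
#' `r_mode` controls how the absolute tolerance is derived when computing a
#' multiscale curve: `"fixed"` (default) takes `r_frac` times the standard
#' deviation of the *original* (scale-factor 1) segment and holds it constant
#' across scales, so that the entropy-versus-scale profile reflects the
#' redistribution of variance under coarse-graining; `"per_scale"` recomputes
#' the tolerance from each coarse-grained series' own standard deviation.
#'
#' @param m Embedding dimension, a positive integer.
#' @param r_frac Tolerance as a fraction of the standard deviation, in (0, 1).
#' @param max_sf Largest scale factor, a positive integer.
#' @param r_mode `"fixed"` or `"per_scale"` (see Details).
#' @return An object of class `entropy_params`.
#' @examples
#' entropy_params()
#' entropy_params(m = 1, r_frac = 0.15, max_sf = 20)
#' @export
entropy_params <- function(m = 2, r_frac = 0.2, max_sf = 40,
                           r_mode = c("fixed", "per_scale")) {
  r_mode <- match.arg(r_mode)
  if (length(m) != 1L || m < 1 || m != round(m))
    stop("m must be a positive integer")
  if (length(r_frac) != 1L || !is.finite(r_frac) || r_frac <= 0 || r_frac >= 1)
    stop("r_frac must lie strictly between 0 and 1")
  if (length(max_sf) != 1L || max_sf < 1 || max_sf != round(max_sf))
    stop("max_sf must be a positive integer")
  structure(list(m = as.integer(m), r_frac = r_frac,
                 max_sf = as.integer(max_sf), r_mode = r_mode),
            class = "entropy_params")
}

#' @export
print.entropy_params <- function(x, ...) {
  cat(sprintf("entropy_params: m = %d, r = %.3g * SD (%s), max SF = %d\n",
              x$m, x$r_frac, x$r_mode, x$max_sf))
  invisible(x)
}

#' Coarse-grain a time series
#'
#' Replaces non-overlapping windows of `sf` consecutive samples with their
#' mean, giving the scale-`sf` coarse-grained series of length
#' `floor(length(x) / sf)`. Trailing samples that do not fill a whole window
#' are discarded. At `sf = 1` the series is returned unchanged.
#'
#' @param x Numeric vector.
#' @param sf Scale factor (window length), a positive integer not exceeding
#'   `length(x)`.
#' @return An object of class `coarse_grained` with fields `values`, `sf`, and
#'   `source_n` (the original length).
#' @examples
#' coarse_grain(c(2, 4, 6, 8), 2)$values  # 3 7
#' @export
coarse_grain <- function(x, sf) {
  if (length(sf) != 1L || sf < 1 || sf != round(sf))
    stop("sf must be a positive integer")
  sf <- as.integer(sf)
  n <- length(x)
  if (sf > n) stop("sf exceeds series length")
  nw <- n %/% sf
  if (sf == 1L) {
    vals <- as.numeric(x)
  } else {
    vals <- colMeans(matrix(x[seq_len(nw * sf)], nrow = sf, ncol = nw))
  }
  structure(list(values = vals, sf = sf, source_n = n),
            class = "coarse_grained")
}

#' Sample entropy of a time series
#'
#' SampEn(m, r) is the negative natural log of the conditional probability
#' that two sequences of `m` consecutive points that are similar (Chebyshev
#' distance strictly below the tolerance, excluding self-matches) remain
#' similar at the next point. Matching is counted over ordered template pairs
#' (i, j), i != j, drawn from the `N - m` templates that can be extended to
#' length `m + 1`, and the estimate is `-log(A / B)` where `B` and `A` are the
#' length-`m` and length-`m + 1` match counts.
#'
#' When either count is zero the conditional probability is undefined and
#' `NA` is returned (with a warning), never an error: undefined entries are
#' propagated as tagged missing values through curve construction and
#' downstream averaging.
#'
#' @param x Numeric vector, length at least `m + 2`, finite, non-constant.
#' @param params An [entropy_params()] object (its `m` and `r_frac` are used).
#' @param r_abs Absolute tolerance overriding `params$r_frac * sd(x)`; used by
#'   [mse_curve()] to hold the tolerance fixed across scale factors.
#' @return A single non-negative number, or `NA` if no template matches exist.
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(500))          # irregular: close to 2.19 at large N
#' sample_entropy(rep(c(0, 1), 50))    # fully predictable: 0
#' @export
sample_entropy <- function(x, params = entropy_params(), r_abs = NULL) {
  stopifnot(inherits(params, "entropy_params"))
  x <- as.numeric(x)
  if (anyNA(x) || any(!is.finite(x))) stop("series contains non-finite values")
  if (length(x) < params$m + 2) stop("series too short for m = ", params$m)
  if (is.null(r_abs)) {
    s <- sd(x)
    if (!(s > 0)) stop("zero-variance series: tolerance degenerate")
    r_abs <- params$r_frac * s
  }
  if (!(r_abs > 0)) stop("tolerance must be positive")
  cnt <- .sampen_counts(x, params$m, r_abs)
  if (cnt$B == 0 || cnt$A == 0) {
    warning("no template matches at m = ", params$m,
            "; sample entropy undefined")
    return(NA_real_)
  }
  -log(cnt$A / cnt$B)
}

#' Multiscale entropy curve
#'
#' Computes SampEn on coarse-grained versions of one segment for scale
#' factors 1..`max_sf`. Under the default tolerance mode the absolute
#' tolerance is `r_frac` times the SD of the raw (scale-factor 1) segment and
#' is held fixed across scales. Undefined entries (no template matches) are
#' kept as `NA`, not dropped.
#'
#' @param seg An `eeg_segment` (see [segment()]) or plain numeric vector.
#' @param params An [entropy_params()] object.
#' @param sfs Integer vector of scale factors to evaluate (default all of
#'   `1:max_sf`); unevaluated entries are `NA` in the result. Restricting
#'   `sfs` is a pure computational shortcut for band summaries.
#' @return An object of class `mse_curve`: `sampen` (length `max_sf`),
#'   `channel`, `segment_index`, `params`.
#' @export
mse_curve <- function(seg, params = entropy_params(), sfs = NULL) {
  x <- if (inherits(seg, "eeg_segment")) seg$samples else as.numeric(seg)
  stopifnot(inherits(params, "entropy_params"))
  if (is.null(sfs)) sfs <- seq_len(params$max_sf)
  sfs <- as.integer(sfs)
  if (any(sfs < 1L) || any(sfs > params$max_sf))
    stop("sfs must lie in 1..max_sf")
  if (length(x) %/% params$max_sf < params$m + 2)
    stop("segment too short for max_sf = ", params$max_sf)
  s0 <- sd(x)
  if (!(s0 > 0)) stop("zero-variance segment")
  sampen <- rep(NA_real_, params$max_sf)
  for (sf in sfs) {
    y <- coarse_grain(x, sf)$values
    r_abs <- if (params$r_mode == "fixed") params$r_frac * s0 else NULL
    sampen[sf] <- tryCatch(
      sample_entropy(y, params, r_abs = r_abs),
      warning = function(w) NA_real_)
  }
  structure(list(sampen = sampen,
                 channel = if (inherits(seg, "eeg_segment")) seg$channel else NA_character_,
                 segment_index = if (inherits(seg, "eeg_segment")) seg$segment_index else NA_integer_,
                 params = params),
            class = "mse_curve")
}

#' @export
print.mse_curve <- function(x, ...) {
  n_ok <- sum(!is.na(x$sampen))
  cat(sprintf("mse_curve: channel %s segment %s, %d/%d SFs defined\n",
              x$channel, x$segment_index, n_ok, length(x$sampen)))
  if (n_ok) {
    rng <- range(x$sampen, na.rm = TRUE)
    cat(sprintf("  SampEn range: %.3f .. %.3f\n", rng[1], rng[2]))
  }
  invisible(x)
}

#' Average the MSE curves of a session's two segments
#'
#' Each session contributes two artifact-free segments per channel; their MSE
#' curves are averaged element-wise into the session's per-channel curve. An
#' entry undefined in either curve is undefined in the mean.
#'
#' @param a,b `mse_curve` objects sharing parameters and channel.
#' @return An `mse_curve` with `segment_index = NA`.
#' @export
average_segments <- function(a, b) {
  stopifnot(inherits(a, "mse_curve"), inherits(b, "mse_curve"))
  if (!identical(unclass(a$params), unclass(b$params)))
    stop("cannot average curves with different entropy parameters")
  if (!identical(a$channel, b$channel))
    stop("cannot average curves from different channels")
  m <- (a$sampen + b$sampen) / 2  # NA in either operand propagates
  structure(list(sampen = m, channel = a$channel, segment_index = NA_integer_,
                 params = a$params),
            class = "mse_curve")
}
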