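#' Default clinical EEG frequency bands (Hz)
#'
#' Standard band edges used for band power and the alpha-dominance check:
#' theta 4-8, alpha 8-13, beta 13-30, gamma 30-60. All band intervals are
#' half-open, `[lo, hi)`.
#'
#' @return Named list of `c(lo, hi)` pairs.
#' @export
default_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 60))
}

#' Hanning-windowed FFT power spectrum of a segment
#'
#' The segment is split into consecutive non-overlapping epochs
#' (`epoch_s` seconds each; the canonical 30 s segment gives 15 two-second
#' epochs and 0.5 Hz resolution). Each epoch is tapered with a Hanning window
#' and Fourier transformed; one-sided absolute power is averaged across
#' epochs and log-transformed last (log10 by default). Power is compensated
#' for the window's power loss (divided by the mean squared window) so a
#' white-noise spectrum is flat and total power matches the unwindowed
#' signal's mean square.
#'
#' @param seg An `eeg_segment`.
#' @param epoch_s Epoch length in seconds (default 2).
#' @param log_base `"log10"` (default) or `"ln"` for the final transform.
#' @return An object of class `power_spectrum`: `freqs_hz`, `power`
#'   (pre-log, averaged across epochs), `log_power`, `channel`, `n_epochs`,
#'   `df_hz`.
#' @export
power_spectrum <- function(seg, epoch_s = 2, log_base = c("log10", "ln")) {
  stopifnot(inherits(seg, "eeg_segment"))
  log_base <- match.arg(log_base)
  fs <- seg$sampling_rate_hz
  L <- epoch_s * fs
  if (abs(L - round(L)) > 1e-9) stop("epoch length must be a whole number of samples")
  L <- as.integer(round(L))
  if (seg$n %% L != 0)
    stop("segment length must be a whole number of ", epoch_s, " s epochs")
  n_epochs <- seg$n %/% L
  w <- as.numeric(signal::hanning(L))
  wnorm <- mean(w^2)                     # window power-loss compensation
  half <- L %/% 2L
  freqs <- (0:half) * fs / L
  acc <- numeric(half + 1L)
  for (e in seq_len(n_epochs)) {
    xe <- seg$samples[((e - 1L) * L + 1L):(e * L)]
    X <- fft(xe * w)
    p <- Mod(X[1:(half + 1L)])^2 / (L^2 * wnorm)   # mean-square per bin
    # fold negative frequencies into the one-sided spectrum
    p[2:half] <- 2 * p[2:half]
    if (L %% 2L == 0L) p[half + 1L] <- p[half + 1L] else p[half + 1L] <- 2 * p[half + 1L]
    acc <- acc + p
  }
  pow <- acc / n_epochs
  logp <- if (log_base == "log10") log10(pow) else log(pow)
  structure(list(freqs_hz = freqs, power = pow, log_power = logp,
                 channel = seg$channel, n_epochs = n_epochs,
                 df_hz = fs / L, log_base = log_base),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power_spectrum: channel %s, %d epochs, %g Hz resolution, 0-%g Hz\n",
              x$channel, x$n_epochs, x$df_hz, max(x$freqs_hz)))
  invisible(x)
}

#' Mean band power
#'
#' Mean of the absolute (pre-log) power over frequency bins in the half-open
#' band `[lo, hi)`.
#'
#' @param ps A `power_spectrum`.
#' @param band `c(lo_hz, hi_hz)` with `lo < hi`, inside the spectrum's range.
#' @return A single number (µV² scale).
#' @export
band_power <- function(ps, band) {
  stopifnot(inherits(ps, "power_spectrum"))
  lo <- band[[1]]; hi <- band[[2]]
  if (!(lo < hi)) stop("band must have lo < hi")
  if (lo < min(ps$freqs_hz) || hi > max(ps$freqs_hz) + ps$df_hz)
    stop("band outside spectrum range")
  sel <- ps$freqs_hz >= lo & ps$freqs_hz < hi
  if (!any(sel)) stop("empty band: no frequency bins in [", lo, ", ", hi, ")")
  mean(ps$power[sel])
}

#' Posterior alpha-dominance wakefulness check
#'
#' Automated stand-in for the visual confirmation of eyes-closed wakefulness:
#' returns `TRUE` iff, in both occipital channels, mean alpha-band power
#' exceeds `ratio_threshold` times the mean of the flanking theta and beta
#' band powers.
#'
#' @param ps_o1,ps_o2 `power_spectrum` objects for O1 and O2.
#' @param bands Band-edge list as from [default_bands()].
#' @param ratio_threshold Required alpha-to-flanker ratio (default 1.0).
#' @return `TRUE` or `FALSE`.
#' @export
alpha_dominance_check <- function(ps_o1, ps_o2, bands = default_bands(),
                                  ratio_threshold = 1.0) {
  ok <- vapply(list(ps_o1, ps_o2), function(ps) {
    a <- band_power(ps, bands$alpha)
    flank <- mean(c(band_power(ps, bands$theta), band_power(ps, bands$beta)))
    a > ratio_threshold * flank
  }, logical(1))
  all(ok)
}
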