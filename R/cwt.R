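# Continuous wavelet transform with an analytic Morlet wavelet.
#
# FFT-accelerated: the transform of scale s is ifft(X(w) * Psi_s*(w)) with
# Psi_s(w) = sqrt(2*pi*s) * pi^(-1/4) * exp(-(s*w - omega0)^2 / 2) on the
# positive frequencies. Scales map to centre frequencies via
# f = omega0 * fs / (2*pi*s), the peak of the wavelet's frequency response.
# L2 normalization makes white noise roughly flat across scales.

#' Compute a Morlet CWT scalogram
#'
#' Computes the magnitude of the analytic-Morlet continuous wavelet
#' transform of an event segment on a log-spaced frequency grid. The
#' scalogram is the time-frequency representation used to inspect puncture
#' events and to assess whether a burst is broadband.
#'
#' @param segment A `va_segment`, `va_recording`, or numeric vector.
#' @param fmin,fmax Frequency grid limits in Hz; defaults 100 Hz to fs/2.
#' @param voices Voices per octave (default 12).
#' @param omega0 Morlet centre frequency parameter (default 6).
#' @param fs Sampling rate, required only for bare numeric input.
#' @return An object of class `va_scalogram`: list with `magnitude`
#'   (matrix, frequencies x times), `frequencies` (Hz, ascending), `times`
#'   (seconds, relative to segment start), `fs`.
#' @export
compute_cwt <- function(segment, fmin = 100, fmax = NULL, voices = 12,
                        omega0 = 6, fs = NULL) {
  x <- .as_samples(segment)
  n <- length(x)
  if (n == 0L) stop("empty segment", call. = FALSE)
  fs <- .get_fs(segment, fs)
  if (is.null(fmax)) fmax <- fs / 2
  stopifnot(fmin > 0, fmax <= fs / 2, fmax > fmin, voices >= 1)

  n_oct <- log2(fmax / fmin)
  nfreq <- floor(n_oct * voices) + 1L
  freqs <- fmin * 2^((seq_len(nfreq) - 1L) / voices)

  # zero-pad to at least 2n (next power of two) to limit circular wrap of
  # the long low-frequency wavelets
  nfft <- 2^ceiling(log2(2 * n))
  X <- stats::fft(c(x, numeric(nfft - n)))
  w <- 2 * pi * (0:(nfft - 1L)) / nfft          # rad/sample
  pos <- w > 0 & w <= pi
  mag <- matrix(0, nrow = nfreq, ncol = n)
  for (i in seq_len(nfreq)) {
    s <- omega0 * fs / (2 * pi * freqs[i])      # scale in samples
    psi <- numeric(nfft)
    psi[pos] <- sqrt(2 * pi * s) * pi^(-0.25) *
      exp(-((s * w[pos] - omega0)^2) / 2)
    W <- stats::fft(X * psi, inverse = TRUE) / nfft
    mag[i, ] <- Mod(W[seq_len(n)])
  }
  t0 <- if (inherits(segment, "va_segment")) segment$t0 else 0
  structure(list(magnitude = mag, frequencies = freqs,
                 times = t0 + (seq_len(n) - 1L) / fs, fs = fs,
                 omega0 = omega0),
            class = "va_scalogram")
}

#' @export
print.va_scalogram <- function(x, ...) {
  cat(sprintf("<va_scalogram> %d frequencies (%.0f-%.0f Hz) x %d times\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              length(x$times)))
  invisible(x)
}

#' Plot a scalogram
#'
#' Displays the CWT magnitude as an image over time and log-frequency.
#'
#' @param x A `va_scalogram`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.va_scalogram <- function(x, ...) {
  graphics::image(x$times, log2(x$frequencies), t(x$magnitude),
                  xlab = "time (s)", ylab = "log2 frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
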