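# Short-time Fourier transform and overlap-add inverse (internal).
#
# Periodic Hann analysis and synthesis windows; reconstruction divides by
# the accumulated squared-window envelope, so ISTFT(STFT(x)) == x for any
# hop that covers every sample.

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

# Returns list(S = complex matrix [nbins x nframes], starts, frame, hop, n).
.stft <- function(x, frame = 1024L, hop = 256L) {
  n <- length(x)
  w <- .hann(frame)
  # reflect-pad half a frame on both sides so edge samples get full window mass
  padl <- frame %/% 2L
  xp <- c(rev(x[seq_len(min(padl, n))]), x, rev(x[n + 1L - seq_len(min(padl, n))]))
  if (length(xp) < frame) xp <- c(xp, numeric(frame - length(xp)))
  np <- length(xp)
  starts <- seq(1L, np - frame + 1L, by = hop)
  nb <- frame %/% 2L + 1L
  S <- matrix(0 + 0i, nrow = nb, ncol = length(starts))
  for (k in seq_along(starts)) {
    seg <- xp[starts[k]:(starts[k] + frame - 1L)] * w
    S[, k] <- stats::fft(seg)[seq_len(nb)]
  }
  list(S = S, starts = starts, frame = frame, hop = hop, n = n, padl = padl,
       np = np)
}

.istft <- function(st) {
  frame <- st$frame
  w <- .hann(frame)
  nb <- nrow(st$S)
  y <- numeric(st$np)
  wsum <- numeric(st$np)
  for (k in seq_along(st$starts)) {
    spec <- st$S[, k]
    full <- c(spec, Conj(spec[(nb - 1L):2L]))  # hermitian completion
    seg <- Re(stats::fft(full, inverse = TRUE)) / frame
    idx <- st$starts[k]:(st$starts[k] + frame - 1L)
    y[idx] <- y[idx] + seg * w
    wsum[idx] <- wsum[idx] + w^2
  }
  y <- y / pmax(wsum, 1e-12)
  y[(st$padl + 1L):(st$padl + st$n)]
}
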