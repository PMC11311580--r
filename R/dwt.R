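# Multilevel discrete wavelet transform with Daubechies filters.
#
# The transform is the periodized orthogonal DWT: analysis rows are even
# circular shifts of the decomposition filters, synthesis is the transpose.
# Orthonormality of the Daubechies filters makes reconstruction exact to
# machine precision, which the filtering contract relies on. Signals are
# first extended by reflection to a multiple of 2^levels and trimmed after
# reconstruction.

# Daubechies scaling (lowpass decomposition) filters; standard published
# coefficients, lowest index first.
.db_scaling <- list(
  db2 = c(-0.12940952255092145, 0.22414386804185735,
          0.836516303737469, 0.48296291314469025),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

.wt_filters <- function(wavelet = "db4") {
  h <- .db_scaling[[wavelet]]
  if (is.null(h)) {
    stop("unknown wavelet '", wavelet, "'; available: ",
         paste(names(.db_scaling), collapse = ", "), call. = FALSE)
  }
  L <- length(h)
  g <- (-1)^(seq_len(L)) * rev(h)  # quadrature mirror highpass
  list(lo = h, hi = g, len = L)
}

# One analysis level (periodic): cA[k] = sum_m lo[m] x[(2k+m-2) mod n + 1]
.dwt_step <- function(x, filt) {
  n <- length(x)
  n2 <- n %/% 2L
  base <- 2L * (seq_len(n2) - 1L)
  cA <- numeric(n2)
  cD <- numeric(n2)
  for (m in seq_len(filt$len)) {
    idx <- (base + (m - 1L)) %% n + 1L
    xs <- x[idx]
    cA <- cA + filt$lo[m] * xs
    cD <- cD + filt$hi[m] * xs
  }
  list(cA = cA, cD = cD)
}

# One synthesis level: transpose of the analysis operator.
.idwt_step <- function(cA, cD, filt) {
  n2 <- length(cA)
  n <- 2L * n2
  x <- numeric(n)
  base <- 2L * (seq_len(n2) - 1L)
  for (m in seq_len(filt$len)) {
    idx <- (base + (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + filt$lo[m] * cA + filt$hi[m] * cD
  }
  x
}

# Reflect-extend x to length n_target (n_target >= length(x)).
.reflect_pad <- function(x, n_target) {
  extra <- n_target - length(x)
  if (extra <= 0L) return(x)
  n <- length(x)
  pad <- x[n - (seq_len(extra) - 1L)]  # mirrored tail (repeats if needed)
  if (extra > n) pad <- rep_len(c(rev(x), x), extra)
  c(x, pad[seq_len(extra)])
}

#' Multilevel discrete wavelet decomposition
#'
#' Decomposes a signal into `levels` detail bands plus one approximation
#' using a periodized orthogonal Daubechies transform. Detail level 1 is the
#' highest half-band (fs/4 to fs/2), level `j` spans fs/2^(j+1) to fs/2^j.
#'
#' @param x Numeric signal.
#' @param levels Decomposition depth; requires `length(x) >= 2^levels`.
#' @param wavelet Wavelet name, `"db4"` (default) or `"db2"`.
#' @return A list with `details` (list of length `levels`, finest first),
#'   `approx`, `n` (original length) and the transform parameters.
#' @export
wt_dec <- function(x, levels = 10L, wavelet = "db4") {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2^levels) {
    stop(sprintf("signal too short for %d levels (need >= %d samples, have %d)",
                 levels, 2^levels, n), call. = FALSE)
  }
  filt <- .wt_filters(wavelet)
  block <- 2^levels
  n_pad <- as.integer(ceiling(n / block) * block)
  xp <- .reflect_pad(x, n_pad)
  details <- vector("list", levels)
  cur <- xp
  for (j in seq_len(levels)) {
    s <- .dwt_step(cur, filt)
    details[[j]] <- s$cD
    cur <- s$cA
  }
  structure(list(details = details, approx = cur, n = n, n_pad = n_pad,
                 levels = levels, wavelet = wavelet),
            class = "va_wt_dec")
}

#' Multilevel wavelet reconstruction
#'
#' Inverse of [wt_dec()]. Coefficient bands can be zeroed beforehand to
#' realize a band-selective filter.
#'
#' @param dec A `va_wt_dec` object.
#' @return Numeric signal of the original length.
#' @export
wt_rec <- function(dec) {
  filt <- .wt_filters(dec$wavelet)
  cur <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    cur <- .idwt_step(cur, dec$details[[j]], filt)
  }
  cur[seq_len(dec$n)]
}
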