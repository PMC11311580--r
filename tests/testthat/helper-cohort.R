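# Shared fixtures, built in code and memoised across test files.

.cohort_cache <- new.env(parent = emptyenv())

# Segment + measure a cohort of synthetic cavity events. The first
# `n_suppressed` events are generated without the tissue-breakage burst.
analyzed_cohort <- function(n = 154, n_suppressed = 13, seed = 20260921) {
  key <- paste(n, n_suppressed, seed, sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  rows <- lapply(seq_len(n), function(i) {
    cfg <- sim_event_config(ph2_present = i > n_suppressed)
    ev <- simulate_event(cfg, seed = seed + i)
    pb <- segment_phases(ev$segment)
    m <- compute_event_metrics(ev$segment, pb)
    m$true_friction_ms <- ev$truth$friction_duration_ms
    m$true_ph2 <- ev$truth$ph2_present
    m$ph1_onset_err_ms <- if (pb$phases$present[1]) {
      (pb$phases$onset[1] - ev$truth$ph1_onset) * 1000
    } else NA_real_
    m$ph2_onset_err_ms <- if (pb$phases$present[2]) {
      (pb$phases$onset[2] - ev$truth$ph2_onset) * 1000
    } else NA_real_
    m$ph3_onset_err_ms <- (pb$phases$onset[3] - ev$truth$ph3_onset) * 1000
    m
  })
  out <- do.call(rbind, rows)
  .cohort_cache[[key]] <- out
  out
}

# Brute-force time-domain Morlet CWT magnitude at one (frequency, time)
# point; the independent oracle for the FFT implementation.
cwt_oracle_mag <- function(x, fs, freq, t_idx, omega0 = 6) {
  n <- length(x)
  s <- omega0 * fs / (2 * pi * freq)
  tt <- seq_len(n) - t_idx
  psi <- s^(-0.5) * pi^(-0.25) * exp(-tt^2 / (2 * s^2)) *
    exp(1i * omega0 * tt / s)
  abs(sum(x * psi))
}

# Sort-based order-statistic oracle (quantile type 7) for box_stats.
quartile_oracle <- function(v, p) {
  v <- sort(v[!is.na(v)])
  h <- (length(v) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# Minimal hand-built 16-bit PCM mono WAVE writer (header laid out by hand),
# independent of write_wave().
write_pcm16_raw <- function(ints, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  ds <- length(ints) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + ds), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")
  writeBin(as.integer(c(fs, fs * 2)), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(ds, con, size = 4, endian = "little")
  writeBin(as.integer(ints), con, size = 2, endian = "little")
  path
}
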