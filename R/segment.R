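# Event extraction, excitation detection, and six-phase segmentation.
#
# Phase taxonomy of a cavity puncture event:
#   Ph1  inner/outer-core friction (band-limited, 1800-7000 Hz)
#   Ph2  peritoneum tissue breakage (short broadband burst)
#   Ph3  click attack (rapid energy rise to the excitation peak)
#   Ph4  fast recovery (peak -> 90% of post-peak energy)
#   Ph5  slow recovery (90% -> 98%)
#   Ph6  post-puncture settling (98% -> envelope back at the noise floor)

#' Extract the 400 ms analysis segment around an annotation
#'
#' Returns a window of `round(window_s * fs)` samples centred on the
#' annotated instant (half before, half after). No padding is performed: an
#' annotation closer than half a window to either edge is a boundary error.
#'
#' @param rec A `va_recording`.
#' @param t_annot Annotation time in seconds from recording start.
#' @param window_s Window length in seconds (default 0.4).
#' @return A `va_segment` with fields `samples`, `fs`, `t0` (absolute start
#'   time in the parent recording) and `annotation_time`.
#' @export
extract_segment <- function(rec, t_annot, window_s = 0.4) {
  x <- .as_samples(rec)
  fs <- .get_fs(rec)
  n <- length(x)
  if (t_annot < 0 || t_annot >= n / fs) {
    stop("annotation time outside recording", call. = FALSE)
  }
  n_w <- round(window_s * fs)
  half <- n_w %/% 2L
  i_ann <- round(t_annot * fs) + 1L
  i1 <- i_ann - half
  i2 <- i1 + n_w - 1L
  if (i1 < 1L || i2 > n) {
    stop(sprintf("annotation at %.3f s too close to a recording edge for a %.0f ms window",
                 t_annot, window_s * 1000), call. = FALSE)
  }
  structure(list(samples = x[i1:i2], fs = fs, t0 = (i1 - 1L) / fs,
                 annotation_time = t_annot,
                 recording_id = if (inherits(rec, "va_recording")) rec$recording_id else "segment"),
            class = "va_segment")
}

#' @export
print.va_segment <- function(x, ...) {
  cat(sprintf("<va_segment> %d samples @ %g Hz, t0=%.3f s, annotation=%.3f s\n",
              length(x$samples), x$fs, x$t0, x$annotation_time))
  invisible(x)
}

# Centred moving RMS with window `width` samples; returns one value per
# sample, computed with cumulative sums.
.moving_rms <- function(x, width) {
  n <- length(x)
  cs <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(i - (width %/% 2L), 0L)
  hi <- pmin(i + ((width - 1L) %/% 2L), n)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

# Framed short-time RMS: frame/hop in samples; returns list(times, rms)
# with times at frame centres.
.st_rms <- function(x, fs, frame, hop) {
  n <- length(x)
  if (n < frame) stop("signal shorter than one envelope frame", call. = FALSE)
  cs <- c(0, cumsum(x^2))
  starts <- seq(1L, n - frame + 1L, by = hop)
  rms <- sqrt((cs[starts + frame] - cs[starts]) / frame)
  list(times = (starts - 1L + frame / 2) / fs, rms = rms)
}

#' Excitation detector parameters
#'
#' @param frame_ms,hop_ms Short-time RMS envelope frame and hop in ms.
#' @param mad_mult Threshold is `median(env) + mad_mult * mad(env)`.
#' @param refractory_ms Minimum separation between reported events.
#' @param cavity_mult A peak is a cavity candidate when its envelope exceeds
#'   `cavity_mult` times the largest other transient peak (or the threshold,
#'   whichever is larger).
#' @param min_decay_ms Minimum post-peak decay duration of a cavity
#'   candidate: time for the envelope to fall below `decay_frac` of the
#'   peak. Tissue-tissue transients are rapidly damped and fail this.
#' @param decay_frac Envelope fraction defining the end of the decay.
#' @return A list of class `detector_params`.
#' @export
detector_params <- function(frame_ms = 2, hop_ms = 0.5, mad_mult = 8,
                            refractory_ms = 300, cavity_mult = 3,
                            min_decay_ms = 5, decay_frac = 0.2) {
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms, mad_mult = mad_mult,
                 refractory_ms = refractory_ms, cavity_mult = cavity_mult,
                 min_decay_ms = min_decay_ms, decay_frac = decay_frac),
            class = "detector_params")
}

#' Detect transient excitations in a (preprocessed) recording
#'
#' Computes a short-time RMS envelope, thresholds it at a robust noise scale
#' (median plus `mad_mult` MADs), and returns envelope local maxima above
#' the threshold, separated by a refractory period. A peak is flagged as a
#' cavity-puncture candidate when its envelope dominates every other
#' detected transient by at least `cavity_mult` and its post-peak decay
#' lasts at least `min_decay_ms` - the free (undamped) needle vibration
#' after cavity entry, as opposed to the rapidly damped tissue-tissue
#' transients.
#'
#' @param rec A `va_recording` (normally after [preprocess()]).
#' @param params A [detector_params()] object.
#' @return A data frame with columns `event_time` (s), `peak_envelope`,
#'   `decay_ms`, `is_cavity_candidate`; zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_excitations <- function(rec, params = detector_params()) {
  x <- .as_samples(rec)
  fs <- .get_fs(rec)
  frame <- max(2L, round(params$frame_ms / 1000 * fs))
  hop <- max(1L, round(params$hop_ms / 1000 * fs))
  env <- .st_rms(x, fs, frame, hop)
  e <- env$rms
  thr <- stats::median(e) + params$mad_mult * stats::mad(e)

  empty <- data.frame(event_time = numeric(0), peak_envelope = numeric(0),
                      decay_ms = numeric(0), is_cavity_candidate = logical(0))
  m <- length(e)
  if (m < 3L) return(empty)
  is_pk <- c(FALSE, e[2:(m - 1)] >= e[1:(m - 2)] & e[2:(m - 1)] > e[3:m], FALSE) & e > thr
  cand <- which(is_pk)
  if (length(cand) == 0L) return(empty)

  # greedy refractory suppression, strongest first
  cand <- cand[order(e[cand], decreasing = TRUE)]
  kept <- integer(0)
  ref_frames <- params$refractory_ms / 1000 * fs / hop
  for (i in cand) {
    if (length(kept) == 0L || min(abs(kept - i)) > ref_frames) kept <- c(kept, i)
  }
  kept <- sort(kept)

  decay_ms <- vapply(kept, function(i) {
    # decay ends when the envelope falls below a fifth of the peak or back
    # into the noise band, whichever is higher
    below <- which(e[i:m] < max(params$decay_frac * e[i], thr))
    if (length(below) == 0L) (m - i) * hop / fs * 1000
    else (below[1] - 1L) * hop / fs * 1000
  }, numeric(1))

  is_cav <- vapply(seq_along(kept), function(k) {
    # the free click excitation must dominate every other transient in the
    # recording: compare against the largest envelope outside this peak's
    # own refractory window
    i <- kept[k]
    excl <- seq(max(1L, floor(i - ref_frames)), min(m, ceiling(i + ref_frames)))
    ref <- max(thr, e[-excl])
    e[i] >= params$cavity_mult * ref && decay_ms[k] >= params$min_decay_ms
  }, logical(1))

  data.frame(event_time = env$times[kept], peak_envelope = e[kept],
             decay_ms = decay_ms, is_cavity_candidate = is_cav)
}

#' Phase segmentation parameters
#'
#' Operational thresholds of the six-phase segmentation; see
#' [segment_phases()] for how each is used.
#'
#' @param env_fine_ms Fine RMS envelope window (ms) used for the attack peak
#'   and Ph3/Ph6 boundaries; must resolve the sub-millisecond gap between
#'   burst end and click onset.
#' @param env_ph1_ms RMS envelope window (ms) for the Ph1/Ph2 searches.
#' @param ph3_onset_frac Ph3 onset is the last rising crossing of this
#'   fraction of the peak envelope before the peak.
#' @param ph2_window_ms Length of the pre-Ph3 search window for the burst.
#' @param ph2_median_mult,ph2_peak_frac The burst gate: envelope must exceed
#'   `max(ph2_median_mult * median(window env), ph2_peak_frac * peak env)`.
#' @param ph2_min_run_ms Minimum burst duration above the gate.
#' @param ph2_broadband_octaves,ph2_broadband_rel A burst is broadband when
#'   scalogram magnitudes within `ph2_broadband_rel` of the column maximum
#'   span at least this many octaves.
#' @param ph1_band Friction band in Hz.
#' @param ph1_floor_pct Percentile (0-1) of the pre-peak band envelope used
#'   as the band noise floor.
#' @param ph1_thresh_mult,ph1_peak_frac Friction gate: band envelope must
#'   exceed `max(ph1_thresh_mult * floor, ph1_peak_frac * max band env)`.
#' @param ph1_min_run_ms Minimum sustained friction duration.
#' @param ph1_max_gap_ms Dropouts shorter than this are bridged.
#' @param noise_ref_ms Initial stretch of the segment used to estimate the
#'   segment noise floor.
#' @param peak_gate_mult,peak_gate_mad Not-an-event gate: the peak envelope
#'   must exceed `peak_gate_mult * noise median + peak_gate_mad * noise MAD`.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(env_fine_ms = 0.25, env_ph1_ms = 1.0,
                                ph3_onset_frac = 0.05, ph2_window_ms = 15,
                                ph2_median_mult = 6, ph2_peak_frac = 0.10,
                                ph2_min_run_ms = 0.5,
                                ph2_broadband_octaves = 2,
                                ph2_broadband_rel = 0.25,
                                ph1_band = c(1800, 7000),
                                ph1_floor_pct = 0.10, ph1_thresh_mult = 3,
                                ph1_peak_frac = 0.05, ph1_min_run_ms = 5,
                                ph1_max_gap_ms = 2, noise_ref_ms = 20,
                                peak_gate_mult = 6, peak_gate_mad = 8) {
  structure(as.list(environment()), class = "segmentation_params")
}

# FFT brick-wall bandpass (zero-phase) used for the Ph1 band envelope.
.bandpass_fft <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1L)) * fs / n
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2]] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

.not_event <- function(msg) {
  stop(structure(class = c("veressva_not_event", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Segment the six phases of a cavity puncture event
#'
#' Identifies the phase boundaries within a 400 ms event segment:
#' \enumerate{
#'   \item the attack peak is the maximum of a fine RMS amplitude envelope;
#'   \item Ph3 onset is the last rising crossing of `ph3_onset_frac` of the
#'     peak envelope before the peak; Ph3 spans onset to peak;
#'   \item post-peak cumulative energy defines the recovery boundaries:
#'     Ph4 = peak to t(0.90), Ph5 = t(0.90) to t(0.98), Ph6 = t(0.98) until
#'     the envelope returns below the segment noise floor + 3 MAD;
#'   \item Ph2 is searched in a `ph2_window_ms` window before Ph3 onset: a
#'     sustained envelope run above the burst gate whose scalogram column is
#'     broadband (spread >= `ph2_broadband_octaves` octaves);
#'   \item Ph1 is searched before the Ph2 onset (or Ph3 onset when no burst
#'     is found): the last interval where the 1800-7000 Hz band envelope
#'     stays above the band gate for at least `ph1_min_run_ms`.
#' }
#'
#' @param segment A `va_segment` containing a detected excitation.
#' @param scalogram Optional precomputed [compute_cwt()] scalogram of the
#'   segment; computed on demand when needed and not supplied.
#' @param params A [segmentation_params()] object.
#' @return An object of class `va_phase_bounds`: list with `phases` (data
#'   frame with rows ph1..ph6 and columns `phase`, `onset`, `offset`,
#'   `present`; times in seconds relative to the segment start),
#'   `attack_peak_time`, `noise_median`, `noise_mad`, `fs`.
#' @export
segment_phases <- function(segment, scalogram = NULL,
                           params = segmentation_params()) {
  x <- .as_samples(segment)
  fs <- .get_fs(segment)
  n <- length(x)
  envF <- .moving_rms(x, max(2L, round(params$env_fine_ms / 1000 * fs)))
  env1 <- .moving_rms(x, max(2L, round(params$env_ph1_ms / 1000 * fs)))

  nf_idx <- seq_len(min(n, round(params$noise_ref_ms / 1000 * fs)))
  nf_med <- stats::median(envF[nf_idx])
  nf_mad <- stats::mad(envF[nf_idx])

  pk <- which.max(envF)
  pk_env <- envF[pk]
  if (pk_env <= params$peak_gate_mult * nf_med + params$peak_gate_mad * nf_mad ||
      pk_env <= 0) {
    .not_event("no envelope peak above the noise gate: not a puncture event")
  }
  t_pk <- (pk - 1L) / fs

  # (b) Ph3 onset: last rising crossing of the onset fraction before the peak
  thr3 <- params$ph3_onset_frac * pk_env
  below <- envF[seq_len(pk)] < thr3
  cross <- which(below[-pk] & !below[-1])  # rising edges, index i -> onset i+1
  i3 <- if (length(cross) > 0) min(cross[length(cross)] + 1L, pk - 1L) else 1L
  t3 <- (i3 - 1L) / fs

  # (c) post-peak cumulative energy boundaries
  cum <- cumsum(x[pk:n]^2)
  tot <- cum[length(cum)]
  if (tot <= 0) .not_event("zero post-peak energy")
  i90 <- pk - 1L + which(cum >= 0.90 * tot)[1]
  i98 <- pk - 1L + which(cum >= 0.98 * tot)[1]
  t90 <- (i90 - 1L) / fs
  t98 <- (i98 - 1L) / fs
  thr6 <- nf_med + 3 * nf_mad
  after <- which(envF[i98:n] < thr6)
  i_end <- if (length(after) > 0) i98 + after[1] - 1L else n
  t_end <- max((i_end - 1L) / fs, t98 + 1 / fs)

  # (d) Ph2: burst search in the pre-Ph3 window
  w1 <- max(1L, i3 - round(params$ph2_window_ms / 1000 * fs))
  wend <- i3 - 1L - round(params$env_ph1_ms / 2000 * fs)  # keep clear of attack
  ph2_present <- FALSE
  ph2_on <- NA_real_; ph2_off <- NA_real_
  if (wend > w1 + 4L) {
    wenv <- env1[w1:wend]
    thr2 <- max(params$ph2_median_mult * stats::median(wenv),
                params$ph2_peak_frac * pk_env)
    r <- rle(wenv >= thr2)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    min_run <- round(params$ph2_min_run_ms / 1000 * fs)
    good <- which(r$values & r$lengths >= min_run)
    if (length(good) > 0) {
      # strongest run is the burst candidate
      peaks <- vapply(good, function(g) max(wenv[starts[g]:ends[g]]), numeric(1))
      g <- good[which.max(peaks)]
      i_b1 <- w1 + starts[g] - 1L
      i_b2 <- w1 + ends[g] - 1L
      i_bpk <- w1 + starts[g] - 2L + which.max(wenv[starts[g]:ends[g]])
      if (is.null(scalogram)) scalogram <- compute_cwt(segment)
      col <- scalogram$magnitude[, min(i_bpk, ncol(scalogram$magnitude))]
      strong <- scalogram$frequencies[col >= params$ph2_broadband_rel * max(col)]
      broadband <- length(strong) > 1 &&
        log2(max(strong) / min(strong)) >= params$ph2_broadband_octaves
      if (broadband) {
        ph2_present <- TRUE
        # refine the onset on the fine envelope: the 1 ms window smears the
        # burst edge outward by ~0.5 ms, which would leak burst energy into
        # the preceding friction interval
        lo <- max(2L, i_b1 - round(0.001 * fs))
        fine_above <- which(envF[lo:i_bpk] >= thr2)
        i_on <- if (length(fine_above) > 0) lo + fine_above[1] - 1L else i_b1
        # move to the foot of the rise: the envelope minimum in the trailing
        # 0.5 ms, where the burst emerges from the friction/noise level
        win <- max(lo, i_on - round(0.0005 * fs)):i_on
        i_on <- win[which.min(envF[win])]
        ph2_on <- (i_on - 1L) / fs
        ph2_off <- min(i_b2 / fs, t3)
      }
    }
  }

  # (e) Ph1: sustained band-limited friction before the burst (or click)
  t_ref <- if (ph2_present) ph2_on else t3
  i_ref <- max(1L, round(t_ref * fs))
  ph1_present <- FALSE
  ph1_on <- NA_real_; ph1_off <- NA_real_
  if (i_ref > 8L) {
    # band-limit only the pre-burst portion: a brick-wall filter of the whole
    # segment would leak sinc tails of the high-energy click backwards into
    # the friction region
    xb <- .bandpass_fft(x[seq_len(i_ref - 1L)], fs, params$ph1_band)
    envb <- .moving_rms(xb, max(2L, round(params$env_ph1_ms / 1000 * fs)))
    region <- seq_along(envb)
    floor_b <- stats::quantile(envb, params$ph1_floor_pct, names = FALSE)
    thr1 <- max(params$ph1_thresh_mult * floor_b,
                params$ph1_peak_frac * max(envb))
    above <- envb[region] >= thr1
    # bridge short dropouts
    r <- rle(above)
    gap <- round(params$ph1_max_gap_ms / 1000 * fs)
    r$values[!r$values & r$lengths <= gap] <- TRUE
    r <- rle(inverse.rle(r))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    min_run <- round(params$ph1_min_run_ms / 1000 * fs)
    good <- which(r$values & r$lengths >= min_run)
    if (length(good) > 0) {
      g <- good[length(good)]  # the run leading up to the burst/click
      ph1_present <- TRUE
      ph1_on <- (starts[g] - 1L) / fs
      ph1_off <- min(ends[g] / fs, t_ref)
    }
  }

  phases <- data.frame(
    phase = c("ph1", "ph2", "ph3", "ph4", "ph5", "ph6"),
    onset = c(ph1_on, ph2_on, t3, t_pk, t90, t98),
    offset = c(ph1_off, ph2_off, t_pk, t90, t98, t_end),
    present = c(ph1_present, ph2_present, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(phases = phases, attack_peak_time = t_pk,
                 noise_median = nf_med, noise_mad = nf_mad, fs = fs,
                 n = n),
            class = "va_phase_bounds")
}

#' @export
print.va_phase_bounds <- function(x, ...) {
  cat("<va_phase_bounds> attack peak at", sprintf("%.4f s", x$attack_peak_time), "\n")
  print(x$phases, row.names = FALSE)
  invisible(x)
}
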