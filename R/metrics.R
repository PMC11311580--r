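# Per-event metrics and cohort summaries.
#
# Energies are sums of squared samples over phase intervals (dimensionless
# sample^2 units). Ratios follow the percentage-of-click convention
# (100*E1/E3, 100*E2/E3); the reciprocal fold changes (E3/E1 ~ x200,
# E3/E2 ~ x20 under the generator defaults) are reported alongside.
# Metrics undefined for an event (e.g. latency when no burst is discernible)
# are NA and excluded from cohort statistics, never zero-filled.

.undefined_metric <- function(msg) {
  stop(structure(class = c("veressva_undefined_metric", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.phase_row <- function(bounds, phase) {
  stopifnot(inherits(bounds, "va_phase_bounds"))
  i <- match(phase, bounds$phases$phase)
  if (is.na(i)) stop("unknown phase '", phase, "'", call. = FALSE)
  bounds$phases[i, ]
}

# sum of x[t]^2 for t in [onset, offset), times relative to segment start
.interval_energy <- function(x, fs, onset, offset) {
  i1 <- max(1L, round(onset * fs) + 1L)
  i2 <- min(length(x), round(offset * fs))
  if (i2 < i1) return(0)
  sum(x[i1:i2]^2)
}

#' Energy of one phase
#'
#' Sum of squared samples over the phase interval \[onset, offset). Asking
#' for a phase that is not present signals an undefined-metric error
#' (condition class `veressva_undefined_metric`), not zero.
#'
#' @param segment A `va_segment` (or numeric vector plus `fs`).
#' @param bounds A `va_phase_bounds` from [segment_phases()].
#' @param phase Phase name, one of `"ph1"`..`"ph6"`.
#' @param fs Sampling rate for bare numeric input.
#' @return Energy in sample^2 units.
#' @export
phase_energy <- function(segment, bounds, phase, fs = NULL) {
  row <- .phase_row(bounds, phase)
  if (!row$present) {
    .undefined_metric(paste0("phase ", phase, " not present: energy undefined"))
  }
  x <- .as_samples(segment)
  fs <- .get_fs(segment, fs)
  .interval_energy(x, fs, row$onset, row$offset)
}

#' Post-peak recovery time
#'
#' Smallest time after the attack peak at which the cumulative post-peak
#' energy reaches `fraction` of the total post-peak energy (integrated to
#' the segment end).
#'
#' @param segment A `va_segment` (or numeric vector plus `fs`).
#' @param attack_peak_time Peak time in seconds relative to segment start.
#' @param fraction Energy fraction in (0, 1).
#' @param fs Sampling rate for bare numeric input.
#' @return Recovery time in ms.
#' @export
recovery_time <- function(segment, attack_peak_time, fraction, fs = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  x <- .as_samples(segment)
  fs <- .get_fs(segment, fs)
  pk <- round(attack_peak_time * fs) + 1L
  if (pk < 1L || pk > length(x)) stop("peak outside segment", call. = FALSE)
  cum <- cumsum(x[pk:length(x)]^2)
  tot <- cum[length(cum)]
  if (tot <= 0) .undefined_metric("zero post-peak energy: recovery undefined")
  (which(cum >= fraction * tot)[1] - 1L) / fs * 1000
}

#' Compute all per-event metrics
#'
#' Populates energies E1-E3, energy ratios, friction duration, burst-to-
#' click latency, recovery times and total event duration for one segmented
#' event. E3 is the energy of the whole click component (Ph3 onset through
#' the Ph6 offset, i.e. attack plus both recovery phases), the quantity the
#' friction and burst energies are compared against. Fields undefined for
#' the event (no discernible burst, no friction run) are NA.
#'
#' @param segment A `va_segment`.
#' @param bounds A `va_phase_bounds` from [segment_phases()].
#' @param recovery_fractions Energy thresholds for recovery times.
#' @return A one-row data frame of class `va_event_metrics` with columns
#'   `E1`, `E2`, `E3`, `ratio_pct_1`, `ratio_pct_2`, `fold_3_to_1`,
#'   `fold_3_to_2`, `friction_duration_ms`, `latency_ms`, `recovery90_ms`,
#'   `recovery95_ms`, `recovery98_ms` (per requested fraction),
#'   `total_event_ms`, and presence flags.
#' @export
compute_event_metrics <- function(segment, bounds,
                                  recovery_fractions = c(0.90, 0.95, 0.98)) {
  x <- .as_samples(segment)
  fs <- .get_fs(segment)
  ph <- bounds$phases
  p <- function(name) ph[match(name, ph$phase), ]

  e1 <- if (p("ph1")$present) phase_energy(segment, bounds, "ph1") else NA_real_
  e2 <- if (p("ph2")$present) phase_energy(segment, bounds, "ph2") else NA_real_
  e3 <- .interval_energy(x, fs, p("ph3")$onset, p("ph6")$offset)

  fric_ms <- if (p("ph1")$present) (p("ph1")$offset - p("ph1")$onset) * 1000 else NA_real_
  lat_ms <- if (p("ph2")$present) (p("ph3")$onset - p("ph2")$onset) * 1000 else NA_real_
  rec <- vapply(recovery_fractions, function(f) {
    recovery_time(segment, bounds$attack_peak_time, f)
  }, numeric(1))
  names(rec) <- sprintf("recovery%02d_ms", round(100 * recovery_fractions))
  total_ms <- if (p("ph1")$present) (p("ph6")$onset - p("ph1")$onset) * 1000 else NA_real_

  out <- data.frame(
    E1 = e1, E2 = e2, E3 = e3,
    ratio_pct_1 = 100 * e1 / e3, ratio_pct_2 = 100 * e2 / e3,
    fold_3_to_1 = e3 / e1, fold_3_to_2 = e3 / e2,
    friction_duration_ms = fric_ms, latency_ms = lat_ms,
    t(rec),
    total_event_ms = total_ms,
    ph1_present = p("ph1")$present, ph2_present = p("ph2")$present,
    ph3_present = p("ph3")$present,
    stringsAsFactors = FALSE
  )
  class(out) <- c("va_event_metrics", "data.frame")
  out
}

#' Boxplot-convention distribution statistics
#'
#' Five-number summary with quartiles by linear interpolation of order
#' statistics (R quantile type 7), whiskers at the most extreme points
#' within 1.5 IQR of the quartiles, and outliers beyond.
#'
#' @param v Numeric vector; NAs dropped.
#' @return A list with `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`, `min`, `max`.
#' @export
box_stats <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0) {
    return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                whisker_low = NA_real_, whisker_high = NA_real_,
                outliers = numeric(0), min = NA_real_, max = NA_real_))
  }
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- v[v >= lo & v <= hi]
  list(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(v[v < lo | v > hi]), min = min(v), max = max(v))
}

.metric_cols <- c("E1", "E2", "E3", "ratio_pct_1", "ratio_pct_2",
                  "fold_3_to_1", "fold_3_to_2", "friction_duration_ms",
                  "latency_ms", "recovery90_ms", "recovery95_ms",
                  "recovery98_ms", "total_event_ms")

#' Summarize a cohort of analyzed insertions
#'
#' Takes a per-insertion event table (one row per insertion; metric columns
#' NA for insertions without an analyzed cavity event) and produces
#' per-subject and total counts - insertions, cavity reached, excitation
#' detected, and presence of phases 1-3 among detected excitations - plus
#' boxplot statistics (median, quartiles, whiskers, outliers) for each
#' metric over the events where it is defined.
#'
#' @param events Data frame with at least `subject_id`, `reached_cavity`,
#'   `excitation_detected`, `ph1_present`, `ph2_present`, `ph3_present`,
#'   and any of the per-event metric columns.
#' @return A list of class `va_cohort_summary` with elements `counts` (data
#'   frame, one row per subject plus a Total row, in the column order
#'   insertions / cavity / excitations / Ph1 / Ph2 / Ph3) and `stats` (data
#'   frame of distribution statistics per metric).
#' @export
summarize_cohort <- function(events) {
  if (is.null(events) || nrow(events) == 0) {
    stop("empty cohort: nothing to summarize", call. = FALSE)
  }
  for (col in c("excitation_detected", "ph1_present", "ph2_present",
                "ph3_present")) {
    if (is.null(events[[col]])) events[[col]] <- FALSE
    events[[col]][is.na(events[[col]])] <- FALSE
  }
  if (is.null(events$subject_id)) events$subject_id <- "all"
  if (is.null(events$reached_cavity)) events$reached_cavity <- TRUE

  one <- function(df, label) {
    cav <- df$reached_cavity
    data.frame(
      subject_id = label,
      insertions = nrow(df),
      cavity_reached = sum(cav),
      excitations = sum(cav & df$excitation_detected),
      ph1_present = sum(cav & df$excitation_detected & df$ph1_present),
      ph2_present = sum(cav & df$excitation_detected & df$ph2_present),
      ph3_present = sum(cav & df$excitation_detected & df$ph3_present),
      stringsAsFactors = FALSE
    )
  }
  subjects <- unique(events$subject_id)
  counts <- do.call(rbind, lapply(subjects, function(s) {
    one(events[events$subject_id == s, , drop = FALSE], s)
  }))
  counts <- rbind(counts, one(events, "Total"))

  stats_rows <- lapply(intersect(.metric_cols, names(events)), function(mc) {
    b <- box_stats(events[[mc]])
    data.frame(metric = mc, n = b$n, median = b$median, q1 = b$q1,
               q3 = b$q3, whisker_low = b$whisker_low,
               whisker_high = b$whisker_high,
               n_outliers = length(b$outliers), min = b$min, max = b$max,
               stringsAsFactors = FALSE)
  })
  stats <- if (length(stats_rows) > 0) do.call(rbind, stats_rows) else NULL
  structure(list(counts = counts, stats = stats),
            class = "va_cohort_summary")
}

#' @export
print.va_cohort_summary <- function(x, ...) {
  cat("Cohort counts (insertions / cavity / excitations / Ph1 / Ph2 / Ph3):\n")
  print(x$counts, row.names = FALSE)
  if (!is.null(x$stats)) {
    cat("\nMetric distributions:\n")
    print(x$stats, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
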