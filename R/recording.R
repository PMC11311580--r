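#' Construct a vibroacoustic recording
#'
#' A recording is the unit of input/output: a mono sampled vibroacoustic
#' signal captured at the proximal end of a Veress needle, together with its
#' sampling rate and identifiers. Amplitudes are dimensionless floating point
#' values, nominally in \[-1, 1\] (synthetic click components may exceed full
#' scale; use float32 encoding to store them losslessly).
#'
#' @param samples Numeric vector of finite sample amplitudes (non-empty).
#' @param fs Sampling rate in Hz (default 16000, the acquisition rate of the
#'   sensing prototype).
#' @param recording_id Identifier string for this recording.
#' @param subject_id Subject (cadaver or simulation) label.
#' @param insertion_site Optional entry-point label, e.g. `"sub-umbilicus"`,
#'   `"Lee-Huang"`, `"Palmer"`.
#' @return An object of class `va_recording`.
#' @export
recording <- function(samples, fs = 16000, recording_id = "rec",
                      subject_id = "sim", insertion_site = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("recording has no samples", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, fs = fs,
         recording_id = as.character(recording_id),
         subject_id = as.character(subject_id),
         insertion_site = insertion_site),
    class = "va_recording"
  )
}

#' @export
print.va_recording <- function(x, ...) {
  cat(sprintf("<va_recording '%s'> subject=%s  %d samples @ %g Hz (%.3f s)\n",
              x$recording_id, x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Duration of a recording or segment in seconds
#' @param x A `va_recording` or `va_segment`.
#' @return Duration in seconds.
#' @export
va_duration <- function(x) length(x$samples) / x$fs

# Accept either a va_recording/va_segment or a bare numeric vector (+ fs).
.as_samples <- function(x) {
  if (inherits(x, "va_recording") || inherits(x, "va_segment")) x$samples
  else as.numeric(x)
}

.get_fs <- function(x, fs = NULL) {
  if (inherits(x, "va_recording") || inherits(x, "va_segment")) x$fs
  else if (!is.null(fs)) fs
  else stop("fs required for bare numeric input", call. = FALSE)
}

# Rebuild an object of the same shape with new samples.
.with_samples <- function(x, samples) {
  if (inherits(x, "va_recording") || inherits(x, "va_segment")) {
    x$samples <- samples
    x
  } else samples
}
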