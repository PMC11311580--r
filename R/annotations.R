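# Annotation tables: one row per annotated puncture instant.
# CSV schema: recording_id,t_puncture_s,reached_cavity
# Times are seconds from recording start; decimal point, not comma.

#' Read puncture annotations
#'
#' Reads a CSV annotation table with the header
#' `recording_id,t_puncture_s,reached_cavity`. Each row records the manually
#' annotated instant of a peritoneum puncture (seconds from recording start)
#' and whether the insertion reached the peritoneal cavity. If a list of
#' recordings is supplied, each annotation time is validated against the
#' duration of its recording.
#'
#' @param path Path to the CSV file.
#' @param recordings Optional named list (or plain list) of `va_recording`
#'   objects used as a catalogue to validate annotation times.
#' @return A data frame of class `va_annotations` with columns
#'   `recording_id` (character), `t_puncture_s` (numeric), `reached_cavity`
#'   (logical).
#' @export
read_annotations <- function(path, recordings = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df, recordings)
}

#' Validate an annotation data frame
#' @param df Data frame with the annotation schema.
#' @inheritParams read_annotations
#' @return The validated `va_annotations` data frame.
#' @export
validate_annotations <- function(df, recordings = NULL) {
  req <- c("recording_id", "t_puncture_s", "reached_cavity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("annotation file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[req]
  df$recording_id <- as.character(df$recording_id)
  if (nrow(df) > 0) {
    t <- suppressWarnings(as.numeric(df$t_puncture_s))
    if (any(is.na(t))) stop("non-numeric t_puncture_s", call. = FALSE)
    df$t_puncture_s <- t
    if (any(t < 0)) stop("t_puncture_s must be >= 0", call. = FALSE)
    rc <- df$reached_cavity
    if (is.character(rc)) rc <- toupper(trimws(rc)) %in% c("TRUE", "T", "1", "YES")
    df$reached_cavity <- as.logical(rc)
    if (any(is.na(df$reached_cavity))) {
      stop("reached_cavity must be logical", call. = FALSE)
    }
    if (anyDuplicated(df[c("recording_id", "t_puncture_s")])) {
      stop("duplicate (recording_id, t_puncture_s) annotation rows",
           call. = FALSE)
    }
    if (!is.null(recordings)) {
      ids <- vapply(recordings, function(r) r$recording_id, character(1))
      for (i in seq_len(nrow(df))) {
        j <- match(df$recording_id[i], ids)
        if (!is.na(j) && df$t_puncture_s[i] >= va_duration(recordings[[j]])) {
          stop(sprintf("annotation time %.3f s beyond end of recording '%s'",
                       df$t_puncture_s[i], df$recording_id[i]), call. = FALSE)
        }
      }
    }
  } else {
    df$t_puncture_s <- numeric(0)
    df$reached_cavity <- logical(0)
  }
  class(df) <- c("va_annotations", "data.frame")
  df
}

#' Write an annotation table to CSV
#' @param ann A `va_annotations` data frame (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
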