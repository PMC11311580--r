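# Reproducible end-to-end commands: simulate a cohort to WAVE+CSV, and
# analyze a directory of recordings against an annotation table.

#' Default pipeline configuration
#'
#' A nested list with every tunable parameter block of the pipeline:
#' spectral gate, DWT filter, CWT grid, excitation detector, phase
#' segmentation, synthetic event generator, cohort specification, seed and
#' output settings. It round-trips losslessly through its YAML file
#' representation; unknown keys in a file are rejected.
#'
#' @param seed Integer master seed; all per-recording randomness is derived
#'   from it by a counter scheme, so results are independent of execution
#'   order.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    gate = unclass(spectral_gate_params()),
    dwt = unclass(dwt_filter_params()),
    cwt = list(fmin = 100, voices = 12, omega0 = 6),
    detector = unclass(detector_params()),
    segmentation = unclass(segmentation_params()),
    event = unclass(sim_event_config()),
    cohort = porcine_cohort_spec(),
    duration_range = c(5, 15),
    wave_encoding = "float32"
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of [pipeline_config()];
#' keys that do not exist in the default configuration are an error.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  merge_into <- function(base, upd, prefix = "") {
    for (k in names(upd)) {
      if (!k %in% names(base)) {
        stop("unknown configuration key: ", prefix, k, call. = FALSE)
      }
      if (is.list(base[[k]]) && !is.data.frame(base[[k]]) && is.list(upd[[k]])) {
        base[[k]] <- merge_into(base[[k]], upd[[k]], paste0(prefix, k, "."))
      } else if (k == "cohort") {
        base[[k]] <- as.data.frame(upd[[k]], stringsAsFactors = FALSE)
      } else {
        base[[k]] <- upd[[k]]
      }
    }
    base
  }
  out <- merge_into(unclass(cfg), user)
  class(out) <- "pipeline_config"
  out
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.cfg_event <- function(config) do.call(sim_event_config, config$event)

#' Simulate a cohort to disk
#'
#' Generates the configured cohort one recording at a time and writes WAVE
#' files, the annotation CSV (`annotations.csv`, cavity-reaching insertions
#' only) and a ground-truth CSV (`ground_truth.csv`) with per-recording true
#' phase times and component energies. Prints the cohort counts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the layout table and output paths.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ev_cfg <- .cfg_event(config)
  lay <- cohort_layout(config$cohort, config$seed, config$duration_range)
  anns <- list()
  gts <- list()
  for (i in seq_len(nrow(lay))) {
    cfg_i <- ev_cfg
    cfg_i$ph2_present <- lay$ph2_present[i]
    out <- simulate_insertion(cfg_i, seed = lay$seed[i],
                              reached_cavity = lay$reached_cavity[i],
                              duration_s = lay$duration_s[i],
                              recording_id = lay$recording_id[i],
                              subject_id = lay$subject_id[i])
    write_wave(out$recording,
               file.path(out_dir, paste0(lay$recording_id[i], ".wav")),
               encoding = config$wave_encoding)
    if (!is.null(out$annotation)) anns[[length(anns) + 1L]] <- out$annotation
    if (isTRUE(out$truth$reached_cavity)) {
      tr <- out$truth
      gts[[length(gts) + 1L]] <- data.frame(
        recording_id = lay$recording_id[i], subject_id = lay$subject_id[i],
        ph1_onset = tr$ph1_onset, ph1_offset = tr$ph1_offset,
        ph2_onset = tr$ph2_onset, ph2_offset = tr$ph2_offset,
        ph3_onset = tr$ph3_onset, attack_peak = tr$attack_peak,
        E1 = tr$E1, E2 = tr$E2, E3 = tr$E3,
        friction_duration_ms = tr$friction_duration_ms,
        ph2_present = tr$ph2_present, stringsAsFactors = FALSE)
    }
  }
  ann_df <- if (length(anns) > 0) do.call(rbind, anns) else
    data.frame(recording_id = character(0), t_puncture_s = numeric(0),
               reached_cavity = logical(0))
  ann_path <- file.path(out_dir, "annotations.csv")
  write_annotations(validate_annotations(ann_df), ann_path)
  gt_path <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(if (length(gts) > 0) do.call(rbind, gts) else data.frame(),
                   gt_path, row.names = FALSE)
  message(sprintf("simulated %d insertions (%d reaching cavity, %d with burst) -> %s",
                  nrow(lay), sum(lay$reached_cavity), sum(lay$ph2_present),
                  out_dir))
  invisible(list(layout = lay, annotations = ann_path,
                 ground_truth = gt_path, dir = out_dir))
}

#' Analyze a directory of recordings
#'
#' For each annotated recording: pre-process, extract the 400 ms segment
#' around the annotation, detect excitations, segment the six phases and
#' compute the event metrics. Recordings without an annotation row are
#' skipped with a warning. Writes `events.csv` (one row per insertion),
#' `cohort_summary.csv` (Table-style counts) and `metric_stats.csv`
#' (distribution statistics), plus a JSON run manifest.
#'
#' @param config A [pipeline_config()].
#' @param wav_dir Directory of `.wav` recordings.
#' @param annotations_path Annotation CSV path.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-event table and cohort summary.
#' @export
run_analyze <- function(config = pipeline_config(), wav_dir,
                        annotations_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_annotations(annotations_path)
  wavs <- list.files(wav_dir, pattern = "\\.wav$", full.names = TRUE)
  if (length(wavs) == 0) stop("empty cohort: no .wav files in ", wav_dir,
                              call. = FALSE)
  gp <- do.call(spectral_gate_params, config$gate)
  dp <- do.call(dwt_filter_params, config$dwt)
  det <- do.call(detector_params, config$detector)
  sp <- do.call(segmentation_params, config$segmentation)

  rows <- list()
  for (w in wavs) {
    rec <- read_wave(w)
    rid <- rec$recording_id
    subject <- sub("_ins[0-9]+$", "", rid)
    arow <- ann[ann$recording_id == rid, , drop = FALSE]
    base <- data.frame(recording_id = rid, subject_id = subject,
                       reached_cavity = FALSE, excitation_detected = FALSE,
                       ph1_present = FALSE, ph2_present = FALSE,
                       ph3_present = FALSE, stringsAsFactors = FALSE)
    if (nrow(arow) == 0) {
      warning("no annotation for recording '", rid, "': skipped",
              call. = FALSE)
      rows[[length(rows) + 1L]] <- base
      next
    }
    base$reached_cavity <- isTRUE(arow$reached_cavity[1])
    pre <- preprocess(rec, gp, dp)
    exc <- detect_excitations(pre, det)
    base$excitation_detected <- any(exc$is_cavity_candidate)
    res <- tryCatch({
      seg <- extract_segment(pre, arow$t_puncture_s[1])
      pb <- segment_phases(seg, params = sp)
      m <- compute_event_metrics(seg, pb)
      base$ph1_present <- m$ph1_present
      base$ph2_present <- m$ph2_present
      base$ph3_present <- m$ph3_present
      cbind(base, m[intersect(.metric_cols, names(m))])
    }, error = function(e) {
      warning("recording '", rid, "': ", conditionMessage(e), call. = FALSE)
      base
    })
    # align columns across rows
    rows[[length(rows) + 1L]] <- res
  }
  all_cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (cc in setdiff(all_cols, names(r))) r[[cc]] <- NA
    r[all_cols]
  })
  events <- do.call(rbind, rows)
  summ <- summarize_cohort(events)

  utils::write.csv(events, file.path(out_dir, "events.csv"), row.names = FALSE)
  utils::write.csv(summ$counts, file.path(out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  if (!is.null(summ$stats)) {
    utils::write.csv(summ$stats, file.path(out_dir, "metric_stats.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("veressva")),
    seed = config$seed, n_recordings = length(wavs),
    config_digest = sum(utils::head(utf8ToInt(
      paste(utils::capture.output(utils::str(unclass(config))), collapse = "")), 1e5))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(events = events, summary = summ))
}
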