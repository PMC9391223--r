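#' @importFrom utils read.table write.table
NULL

fmt_full <- function(x) {
  # full-precision decimal text so numeric round trips are lossless
  formatC(x, format = "g", digits = 17)
}

#' Write / read one raw recording
#'
#' The on-disk layout per recording is three plain-text files sharing a
#' path prefix: `<prefix>_raw.tsv` (one column per channel x wavelength,
#' named `chNN_760` / `chNN_850`, full-precision values), `<prefix>_meta.json`
#' (sampling rate, wavelength order, dynamic range, design labels, resting
#' duration), and — for test sessions — `<prefix>_events.tsv` following the
#' BIDS events convention (onset, duration, trial_type, trial_index).
#' Reading normalizes wavelength order to (760, 850) and fails with the
#' offending path when a required file is missing.
#'
#' @param raw a [raw_recording()]
#' @param prefix path prefix (directories are created)
#' @return `write_raw`: the prefix, invisibly; `read_raw`: a
#'   [raw_recording()]
#' @export
write_raw <- function(raw, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  d <- dim(raw$intensity)
  cols <- list()
  for (ch in seq_len(d[1])) {
    for (wl in 1:2) {
      cols[[sprintf("ch%02d_%d", ch, raw$wavelengths[wl])]] <-
        fmt_full(raw$intensity[ch, wl, ])
    }
  }
  tab <- as.data.frame(cols, check.names = FALSE)
  write.table(tab, paste0(prefix, "_raw.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- list(fs = raw$fs, wavelengths = raw$wavelengths,
               dynamic_range = raw$dynamic_range,
               subject_id = raw$subject_id, group = raw$group,
               phase = raw$phase, session_kind = raw$session_kind,
               rest_duration = raw$rest_duration,
               n_channels = d[1], n_samples = d[3])
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(raw$events)) {
    ev <- raw$events[, c("onset", "duration", "trial_type", "trial_index")]
    write.table(ev, paste0(prefix, "_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' @rdname write_raw
#' @export
read_raw <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.json")
  raw_path <- paste0(prefix, "_raw.tsv")
  for (p in c(meta_path, raw_path)) {
    if (!file.exists(p)) stop("missing dataset file: ", p)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tab <- read.table(raw_path, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "numeric")
  nch <- meta$n_channels
  n <- nrow(tab)
  intensity <- array(0, dim = c(nch, 2, n))
  for (ch in seq_len(nch)) {
    for (wl in 1:2) {
      col <- sprintf("ch%02d_%d", ch, meta$wavelengths[wl])
      if (!col %in% names(tab)) stop("missing channel column ", col,
                                     " in ", raw_path)
      intensity[ch, wl, ] <- tab[[col]]
    }
  }
  events <- NULL
  ev_path <- paste0(prefix, "_events.tsv")
  if (identical(meta$session_kind, "test")) {
    if (!file.exists(ev_path)) stop("missing events file: ", ev_path)
    events <- read.table(ev_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  } else if (file.exists(ev_path)) {
    events <- read.table(ev_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  }
  raw_recording(intensity, fs = meta$fs, wavelengths = meta$wavelengths,
                dynamic_range = meta$dynamic_range,
                subject_id = meta$subject_id, group = meta$group,
                phase = meta$phase, session_kind = meta$session_kind,
                events = events, rest_duration = meta$rest_duration)
}

#' Write / read a complete study dataset
#'
#' Serializes a simulated study into the TSV+JSON layout: `study.json`
#' (groups, phases, seed, device constants), `montage.tsv`,
#' `ground_truth.json`, and per subject x phase the three files written by
#' [write_raw()] under `sub-XX/ses-<phase>_*`.
#'
#' @param study a study from [simulate_study()]
#' @param dir dataset root directory
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- study$config
  cfg$mbll <- list(extinction = cfg$mbll$extinction, dpf = cfg$mbll$dpf,
                   log_base = cfg$mbll$log_base)
  cfg$ground_truth <- NULL
  jsonlite::write_json(
    list(config = cfg, seed = study$seed, subjects = study$subjects),
    file.path(dir, "study.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write.table(as.data.frame(study$montage), file.path(dir, "montage.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- study$ground_truth
  gt$noise$oscillators <- as.data.frame(gt$noise$oscillators)
  jsonlite::write_json(unclass_deep(gt), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (sid in study$subjects$subject_id) {
    for (phase in names(study$recordings[[sid]])) {
      write_raw(study$recordings[[sid]][[phase]],
                file.path(dir, sid, paste0("ses-", phase)))
    }
  }
  invisible(dir)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "study.json"),
                              simplifyVector = TRUE)
  montage <- read.table(file.path(dir, "montage.tsv"), header = TRUE,
                        sep = "\t", stringsAsFactors = FALSE)
  class(montage) <- c("nirs_montage", "data.frame")
  subjects <- as.data.frame(meta$subjects)
  recordings <- list()
  for (sid in subjects$subject_id) {
    recordings[[sid]] <- list()
    for (phase in meta$config$phases) {
      recordings[[sid]][[phase]] <-
        read_raw(file.path(dir, sid, paste0("ses-", phase)))
    }
  }
  structure(list(montage = montage, config = meta$config,
                 ground_truth = NULL, subjects = subjects,
                 recordings = recordings, seed = meta$seed),
            class = "study")
}

#' Write / read a trial feature table
#'
#' TSV serialization with a JSON schema sidecar; this is the contract
#' between preprocessing and the statistics layer, and the entry point for
#' users bringing their own preprocessing.
#'
#' @param table feature table from [build_feature_table()]
#' @param path TSV path (the sidecar gets the extension `.json`)
#' @export
write_feature_table <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- table
  for (col in c("mean_amplitude", "peak_latency")) {
    out[[col]] <- fmt_full(out[[col]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  schema <- list(
    columns = list(
      subject_id = "string", group = "string {experimental,active,passive}",
      phase = "string {T0,T1,T2}", channel_id = "integer",
      region = "string", trial_index = "integer",
      stimulus_type = "string {forward,backward}",
      mean_amplitude = "number, umol/l",
      peak_latency = "number, s"),
    rows = nrow(table))
  jsonlite::write_json(schema, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
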