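# File formats: a minimal EDF codec (16-bit samples, 1-s records, pinned
# timestamps for reproducibility), long-format EEG CSV, trial-record CSV,
# and JSON round-tripping for configurations and biomarker models.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stopf("EDF header field '%s' exceeds %d chars", x, width)
  formatC(x, width = -width) # left-justified, space-padded
}

#' Write an EEG recording as EDF
#'
#' One signal per file, one data record per second, 16-bit samples scaled
#' between integer physical bounds covering the data range. The start
#' date/time fields are pinned so identical recordings produce identical
#' files.
#'
#' @param recording an [eeg_recording()]
#' @param path output path
#' @param patient,recording_id free-text header fields
#' @return `path`, invisibly
#' @export
write_eeg_edf <- function(recording, path, patient = "synthetic",
                          recording_id = "cogload") {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  x <- recording$samples
  n_rec <- floor(length(x) / fs)
  if (n_rec < 1) stopf("recording shorter than one 1-s EDF record")
  if (n_rec * fs < length(x)) {
    warnf("truncating %d trailing samples to whole 1-s records",
          length(x) - n_rec * fs)
    x <- x[seq_len(n_rec * fs)]
  }
  pmin <- floor(min(x, -1))
  pmax <- ceiling(max(x, 1))
  dmin <- -32768
  dmax <- 32767
  dig <- round((x - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  label <- paste(recording$channels, collapse = " ")

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient, 80), pad_field(recording_id, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * 2, 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field("1", 4),
    # signal header block (one signal)
    pad_field(label, 16), pad_field("synthetic", 80), pad_field("uV", 8),
    pad_field(pmin, 8), pad_field(pmax, 8),
    pad_field(dmin, 8), pad_field(dmax, 8),
    pad_field("none", 80), pad_field(fs, 8), pad_field("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(as.integer(dig), con, size = 2, endian = "little")
  invisible(path)
}

read_edf_field <- function(con, width) {
  trimws(readChar(con, width, useBytes = TRUE))
}

#' Read an EDF file written by [write_eeg_edf()]
#'
#' Parses the header, checks the single-signal layout, and rescales the
#' 16-bit samples to physical units.
#'
#' @param path EDF file path
#' @return an [eeg_recording()]
#' @export
read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- read_edf_field(con, 8)
  if (version != "0") stopf("malformed EDF header: version field '%s'", version)
  readChar(con, 80 + 80 + 8 + 8, useBytes = TRUE)
  header_bytes <- as.integer(read_edf_field(con, 8))
  read_edf_field(con, 44)
  n_rec <- as.integer(read_edf_field(con, 8))
  rec_dur <- as.numeric(read_edf_field(con, 8))
  ns <- as.integer(read_edf_field(con, 4))
  if (is.na(ns) || ns != 1 || is.na(header_bytes) ||
      header_bytes != 256 * (1 + ns)) {
    stopf("malformed EDF header: expected one signal, got '%s'", ns)
  }
  label <- read_edf_field(con, 16)
  read_edf_field(con, 80)
  read_edf_field(con, 8)
  pmin <- as.numeric(read_edf_field(con, 8))
  pmax <- as.numeric(read_edf_field(con, 8))
  dmin <- as.numeric(read_edf_field(con, 8))
  dmax <- as.numeric(read_edf_field(con, 8))
  read_edf_field(con, 80)
  spr <- as.integer(read_edf_field(con, 8))
  read_edf_field(con, 32)
  dig <- readBin(con, integer(), n = n_rec * spr, size = 2, signed = TRUE,
                 endian = "little")
  fs <- spr / rec_dur
  phys <- (dig - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  eeg_recording(phys, fs = fs, channels = label)
}

#' EDF amplitude quantization step of a recording's encoding
#'
#' @param recording the recording as written
#' @return step size in physical units
#' @export
edf_quantization_step <- function(recording) {
  x <- recording$samples
  (ceiling(max(x, 1)) - floor(min(x, -1))) / 65535
}

#' Write/read EEG recordings as long-format CSV
#'
#' Columns: participant, experiment, trial, t_s, uv.
#'
#' @param recordings list of [eeg_recording()] with `trial_link` set
#' @param path CSV path
#' @return `path` invisibly (writer); named list of recordings (reader)
#' @export
write_eeg_csv <- function(recordings, path) {
  rows <- lapply(recordings, function(r) {
    if (is.null(r$trial_link)) stopf("recording lacks trial_link metadata")
    data.frame(participant = r$trial_link$participant,
               experiment = r$trial_link$experiment,
               trial = r$trial_link$trial,
               t_s = (seq_along(r$samples) - 1) / r$fs,
               uv = r$samples)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param fs sampling rate to restore (checked against time stamps)
#' @export
read_eeg_csv <- function(path, fs = 500) {
  d <- utils::read.csv(path)
  needed <- c("participant", "experiment", "trial", "t_s", "uv")
  miss <- setdiff(needed, names(d))
  if (length(miss)) stopf("EEG CSV is missing column '%s'", miss[1])
  split_keys <- interaction(d$participant, d$experiment, d$trial, drop = TRUE)
  lapply(split(d, split_keys), function(g) {
    eeg_recording(g$uv, fs = fs,
                  trial_link = list(participant = g$participant[1],
                                    experiment = g$experiment[1],
                                    trial = g$trial[1]))
  })
}

trial_record_columns <- c("participant", "experiment", "trial", "accuracy",
                          "economy", "time_s", "latent_load")

#' Write/read trial-record CSV
#'
#' @param records trial-record data frame
#' @param path CSV path
#' @return `path` invisibly (writer); validated data frame (reader)
#' @export
write_trial_records <- function(records, path) {
  miss <- setdiff(setdiff(trial_record_columns, "latent_load"),
                  names(records))
  if (length(miss)) stopf("trial records are missing column '%s'", miss[1])
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_records
#' @export
read_trial_records <- function(path) {
  d <- utils::read.csv(path)
  miss <- setdiff(setdiff(trial_record_columns, "latent_load"), names(d))
  if (length(miss)) stopf("trial records are missing column '%s'", miss[1])
  if (any(d$time_s <= 0)) stopf("time_s must be positive")
  if (anyDuplicated(d[c("participant", "experiment", "trial")])) {
    stopf("duplicate (participant, experiment, trial) rows")
  }
  d
}

#' Assemble a full run configuration
#'
#' Bundles the scenario with the wavelet, spectral, biomarker and
#' statistical settings; together with the seed it fully determines every
#' pipeline output.
#'
#' @param scenario a [load_scenario()]
#' @param filter wavelet filter name
#' @param max_depth packet-tree depth
#' @param k_features retained BAF count
#' @param bands band definitions data frame
#' @param transfer biomarker transfer function
#' @param norm_probs normalization anchor percentiles
#' @param alpha significance level of the battery
#' @param calibration_n calibration segments per class
#' @param calibration_duration_s calibration segment length
#' @param write_edf whether [run_pipeline()] writes per-trial EDF files
#' @return object of class `run_config`
#' @export
run_config <- function(scenario, filter = "db4", max_depth = 6,
                       k_features = 121, bands = default_bands(),
                       transfer = "linear", norm_probs = c(0.01, 0.99),
                       alpha = 0.05, calibration_n = 50,
                       calibration_duration_s = 10, write_edf = TRUE) {
  structure(list(scenario = scenario, filter = filter,
                 max_depth = max_depth, k_features = k_features,
                 bands = bands, transfer = transfer,
                 norm_probs = norm_probs, alpha = alpha,
                 calibration_n = calibration_n,
                 calibration_duration_s = calibration_duration_s,
                 write_edf = write_edf),
            class = "run_config")
}

#' Write/read a run configuration as JSON
#'
#' @param config a [run_config()]
#' @param path JSON path
#' @return `path` invisibly (writer); `run_config` (reader)
#' @export
write_run_config <- function(config, path) {
  out <- unclass(config)
  out$scenario <- unclass(out$scenario)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- do.call(load_scenario, raw$scenario[
    setdiff(names(raw$scenario), character(0))])
  run_config(scenario = sc, filter = raw$filter,
             max_depth = raw$max_depth, k_features = raw$k_features,
             bands = as.data.frame(raw$bands), transfer = raw$transfer,
             norm_probs = raw$norm_probs, alpha = raw$alpha,
             calibration_n = raw$calibration_n,
             calibration_duration_s = raw$calibration_duration_s,
             write_edf = raw$write_edf)
}

#' Write/read a biomarker model as JSON
#'
#' @param model a [train_load_biomarker()] model
#' @param path JSON path
#' @return `path` invisibly (writer); `load_biomarker` (reader)
#' @export
write_biomarker_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_biomarker_json
#' @export
read_biomarker_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(weights = raw$weights, bias = raw$bias,
                 transfer = raw$transfer,
                 norm = raw$norm, training_meta = raw$training_meta),
            class = "load_biomarker")
}
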