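# BIDS-flavoured on-disk sessions: BrainVision signal files plus
# channels.tsv / events.tsv / JSON sidecar, so synthetic and real recordings
# flow through one interface.

#' Continuous multichannel EEG recording with its event stream
#'
#' The in-memory container for one session/condition: a channels x samples
#' signal matrix in microvolts, the ordered channel names, the sampling rate,
#' the event table, and session metadata. Construction validates the type
#' invariants and fails with an error naming the violated one.
#'
#' @param signals numeric matrix, channels x samples, microvolts.
#' @param channel_names character vector, one name per signal row.
#' @param sampling_rate sampling rate in Hz, positive.
#' @param events data frame with columns `onset_sample` (0-based sample
#'   index), `stimulus_index` (0-based symbol id, NA for phase markers),
#'   `label` (`"target"`/`"nontarget"`, NA for phase markers), `block_id`,
#'   `phase`.
#' @param metadata list with at least `subject`, `session`, `condition`
#'   (`"SF"` or `"CF"`), `n_symbols`.
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(signals, channel_names, sampling_rate,
                                 events, metadata = list()) {
  rec <- structure(list(signals = signals, channel_names = channel_names,
                        sampling_rate = sampling_rate, events = events,
                        metadata = metadata),
                   class = "continuous_recording")
  validate_recording(rec)
  rec
}

#' Validate the invariants of a continuous recording
#'
#' Checks: channel count matches the signal matrix; positive sampling rate;
#' event onsets within `[0, n_samples)`; onsets strictly increasing within
#' each block; no two consecutive stimulation flashes share a stimulus index
#' (the no-repeat constraint).
#'
#' @param rec a `continuous_recording`.
#' @return `rec`, invisibly; errors name the violated invariant.
#' @export
validate_recording <- function(rec) {
  if (!is.matrix(rec$signals)) stop("invariant violation: signals must be a matrix")
  if (length(rec$channel_names) != nrow(rec$signals))
    stop("invariant violation: channel count mismatch between channel_names and signals")
  if (!is.numeric(rec$sampling_rate) || rec$sampling_rate <= 0)
    stop("invariant violation: sampling_rate must be positive")
  ev <- rec$events
  req <- c("onset_sample", "stimulus_index", "label", "block_id", "phase")
  if (!all(req %in% names(ev)))
    stop("invariant violation: events missing columns: ",
         paste(setdiff(req, names(ev)), collapse = ", "))
  if (nrow(ev) > 0) {
    if (any(ev$onset_sample < 0) || any(ev$onset_sample >= ncol(rec$signals)))
      stop("invariant violation: event onsets outside [0, n_samples)")
    for (b in unique(ev$block_id)) {
      on <- ev$onset_sample[ev$block_id == b]
      if (any(diff(on) <= 0))
        stop("invariant violation: onsets not increasing within block ", b)
      si <- ev$stimulus_index[ev$block_id == b & ev$phase == "stimulation"]
      if (length(si) > 1 && any(diff(si) == 0, na.rm = TRUE))
        stop("invariant violation: consecutive flashes share stimulus_index (no-repeat) in block ", b)
    }
  }
  invisible(rec)
}

bids_prefix <- function(subject, session, condition) {
  sprintf("sub-%s_ses-%s_task-oddball_acq-%s", subject, session, condition)
}

#' Write a session to a BIDS-flavoured directory
#'
#' Serialises a recording under `root/sub-XX/ses-YY/eeg/` in a fixed
#' BrainVision dialect: `*_eeg.vhdr` (text header), `*_eeg.vmrk` (marker
#' stub), `*_eeg.eeg` (IEEE float32, multiplexed), plus `*_channels.tsv`,
#' `*_events.tsv` (onsets in seconds with 6 decimals; `trial_type` is
#' `target`/`nontarget` for flashes and the phase name otherwise), and an
#' `*_eeg.json` sidecar carrying the condition and symbol count. The
#' round-trip through [read_session()] is lossless up to float32 sample
#' quantization and microsecond onset rounding.
#'
#' @param recording a validated `continuous_recording`.
#' @param root dataset root directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
write_session <- function(recording, root) {
  validate_recording(recording)
  md <- recording$metadata
  subject <- md$subject %||% "01"
  session <- md$session %||% "01"
  condition <- md$condition %||% "SF"
  dir <- file.path(root, paste0("sub-", subject), paste0("ses-", session), "eeg")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory ", dir)
  prefix <- bids_prefix(subject, session, condition)
  fs <- recording$sampling_rate
  nch <- nrow(recording$signals)

  vhdr <- file.path(dir, paste0(prefix, "_eeg.vhdr"))
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", prefix, "_eeg.eeg"),
    paste0("MarkerFile=", prefix, "_eeg.vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    sprintf("SamplingInterval=%.6f", 1e6 / fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_len(nch), recording$channel_names)
  ), vhdr)

  vmrk <- file.path(dir, paste0(prefix, "_eeg.vmrk"))
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", prefix, "_eeg.eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  ), vmrk)

  eeg <- file.path(dir, paste0(prefix, "_eeg.eeg"))
  con <- file(eeg, "wb")
  writeBin(as.numeric(recording$signals), con, size = 4L, endian = "little")
  close(con)

  chans <- file.path(dir, paste0(prefix, "_channels.tsv"))
  utils::write.table(
    data.frame(name = recording$channel_names, type = "EEG", units = "uV"),
    chans, sep = "\t", quote = FALSE, row.names = FALSE)

  ev <- recording$events
  events_path <- file.path(dir, paste0(prefix, "_events.tsv"))
  ev_out <- data.frame(
    onset = sprintf("%.6f", ev$onset_sample / fs),
    duration = sprintf("%.6f", ifelse(ev$phase == "stimulation", 0.075,
                                      PHASE_DURATIONS[ev$phase])),
    trial_type = ifelse(is.na(ev$label), ev$phase, ev$label),
    stimulus_index = ifelse(is.na(ev$stimulus_index), "n/a", ev$stimulus_index),
    block_id = ev$block_id,
    phase = ev$phase)
  utils::write.table(ev_out, events_path, sep = "\t", quote = FALSE, row.names = FALSE)

  json_path <- file.path(dir, paste0(prefix, "_eeg.json"))
  writeLines(sprintf(paste0(
    '{\n  "TaskName": "oddball",\n  "SamplingFrequency": %s,\n',
    '  "EEGChannelCount": %d,\n  "Condition": "%s",\n  "NSymbols": %d\n}'),
    format(fs), nch, condition, as.integer(md$n_symbols %||% NA)), json_path)

  invisible(c(vhdr, vmrk, eeg, chans, events_path, json_path))
}

#' Read a session written by [write_session()]
#'
#' Reconstructs a `continuous_recording` from the on-disk layout. Event rows
#' whose `trial_type` is neither `target`, `nontarget`, nor a known phase
#' name are dropped with a warning stating how many. The returned recording
#' passes all type invariants.
#'
#' @param root dataset root directory.
#' @param subject,session BIDS entity labels (e.g. `"01"`).
#' @param condition `"SF"` or `"CF"` (stored in the `acq` entity).
#' @return a `continuous_recording`.
#' @export
read_session <- function(root, subject, session, condition) {
  dir <- file.path(root, paste0("sub-", subject), paste0("ses-", session), "eeg")
  prefix <- bids_prefix(subject, session, condition)
  vhdr <- file.path(dir, paste0(prefix, "_eeg.vhdr"))
  if (!file.exists(vhdr)) stop("missing header file: ", vhdr)
  hdr <- readLines(vhdr)
  get_field <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(ln) == 0) stop("header field missing: ", key)
    sub(paste0("^", key, "="), "", ln[1])
  }
  nch <- as.integer(get_field("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_field("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  channel_names <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                          `[[`, character(1), 1L)

  chans_tsv <- utils::read.delim(file.path(dir, paste0(prefix, "_channels.tsv")))
  if (nrow(chans_tsv) != nch)
    stop("channel-count mismatch between signal header and channels.tsv")

  eeg <- file.path(dir, paste0(prefix, "_eeg.eeg"))
  if (!file.exists(eeg)) stop("missing signal file: ", eeg)
  raw <- readBin(eeg, what = "numeric", n = file.size(eeg) / 4L,
                 size = 4L, endian = "little")
  signals <- matrix(raw, nrow = nch,
                    dimnames = list(channel_names, NULL))

  ev_in <- utils::read.delim(file.path(dir, paste0(prefix, "_events.tsv")),
                             colClasses = "character")
  known <- c("target", "nontarget", names(PHASE_DURATIONS), "stimulation")
  bad <- !(ev_in$trial_type %in% known) | is.na(suppressWarnings(as.numeric(ev_in$onset)))
  if (any(bad)) {
    warning("dropped ", sum(bad), " malformed events.tsv row(s)")
    ev_in <- ev_in[!bad, , drop = FALSE]
  }
  events <- data.frame(
    onset_sample = as.integer(round(as.numeric(ev_in$onset) * fs)),
    stimulus_index = suppressWarnings(as.integer(ev_in$stimulus_index)),
    label = ifelse(ev_in$trial_type %in% c("target", "nontarget"),
                   ev_in$trial_type, NA_character_),
    block_id = as.integer(ev_in$block_id),
    phase = ev_in$phase)

  jso <- paste(readLines(file.path(dir, paste0(prefix, "_eeg.json"))), collapse = "")
  nsym <- suppressWarnings(as.integer(sub('.*"NSymbols":\\s*([0-9]+).*', "\\1", jso)))

  continuous_recording(signals, channel_names, fs, events,
                       metadata = list(subject = subject, session = session,
                                       condition = condition, n_symbols = nsym))
}
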