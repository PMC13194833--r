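#' Standard 20-channel 10-20 montage labels
#'
#' Electrode labels used throughout the package, in the fixed order in which
#' synthetic recordings are generated and connectivity matrices are indexed.
#'
#' @return Character vector of 20 channel labels.
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F3", "F4", "Fz", "F7", "F8", "C3", "C4", "Cz",
    "T7", "T8", "P3", "P4", "Pz", "P7", "P8", "O1", "O2", "Oz")
}

#' Construct a continuous multichannel EEG recording
#'
#' A recording is the unit handled by the preprocessing stage: a channels x
#' samples matrix of signal values in microvolts plus sampling and cohort
#' metadata (subject, group, resting state).
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one distinct label per channel.
#' @param subject_id subject identifier.
#' @param group group label, typically `"Control"` or `"Miners"`.
#' @param state resting state, `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL, subject_id = NA_character_,
                          group = NA_character_, state = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("recording data must be a finite numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop("need exactly one label per channel")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be distinct")
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         subject_id = subject_id, group = group, state = state),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s  group: %s  state: %s\n",
              x$subject_id, x$group, x$state))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_channels <- function(rec) nrow(rec$data)
n_samples  <- function(rec) ncol(rec$data)
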