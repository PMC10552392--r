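#' EEG recording container
#'
#' A minimal in-memory representation of a multichannel EEG recording:
#' a channels x samples matrix in microvolts plus the metadata the pipeline
#' needs (sampling rate, 10-20 channel labels, subject/group identity,
#' reference scheme).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz (> 0).
#' @param labels character vector of channel labels, one per row of `data`.
#' @param subject_id subject identifier (coerced to character).
#' @param group group label (e.g. `"a"`/`"b"`), or `NA`.
#' @param reference reference description: a channel label or `"average"`;
#'   `"none"` for synthetic reference-free data.
#'
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(data, srate, labels,
                      subject_id = NA_character_, group = NA_character_,
                      reference = "none") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (length(srate) != 1L || !is.finite(srate) || srate <= 0)
    stop("`srate` must be a single positive number")
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop(sprintf("%d channel labels for %d data rows", length(labels), nrow(data)))
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  structure(
    list(data = data, srate = as.numeric(srate), labels = labels,
         subject_id = as.character(subject_id), group = as.character(group),
         reference = reference),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  cat(sprintf("  subject: %s  group: %s  reference: %s\n",
              x$subject_id, x$group, x$reference))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(rec) ncol(rec$data)
n_channels <- function(rec) nrow(rec$data)

#' Set of fixed-length epochs cut from one recording
#'
#' @param epochs list of channels x samples matrices (all the same shape).
#' @param srate sampling rate in Hz.
#' @param labels channel labels.
#' @param starts integer start indices (1-based, in the source recording) of
#'   each epoch.
#' @param log data.frame of per-stage processing/rejection records.
#' @param subject_id,group carried over from the source recording.
#'
#' @return An object of class `eeg_epochs`.
#' @export
epoch_set <- function(epochs, srate, labels, starts = integer(0),
                      log = empty_preprocess_log(),
                      subject_id = NA_character_, group = NA_character_) {
  stopifnot(is.list(epochs))
  structure(
    list(epochs = epochs, srate = srate, labels = labels,
         starts = starts, log = log,
         subject_id = as.character(subject_id), group = as.character(group)),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  ns <- if (length(x$epochs)) ncol(x$epochs[[1]]) else 0L
  cat(sprintf("<eeg_epochs> %d epochs of %d samples, %d channels @ %g Hz\n",
              length(x$epochs), ns, length(x$labels), x$srate))
  if (nrow(x$log)) cat(sprintf("  log: %d entries\n", nrow(x$log)))
  invisible(x)
}

empty_preprocess_log <- function() {
  data.frame(stage = character(0), action = character(0),
             index = integer(0), value = numeric(0),
             stringsAsFactors = FALSE)
}

log_entry <- function(stage, action, index = NA_integer_, value = NA_real_) {
  data.frame(stage = stage, action = action,
             index = as.integer(index), value = as.numeric(value),
             stringsAsFactors = FALSE)
}
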