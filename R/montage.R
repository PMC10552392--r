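# Electrode-to-network assignments. The seven default channel sets are 10-20
# electrode lists assigned to the canonical resting-state networks via
# published electrode-parcel proximity maps; each set has five electrodes and
# sets may share electrodes (LN and VAN differ in a single position).

.default_sets <- list(
  DMN = c("T7", "Fz", "F4", "T8", "Fp2"),
  DAN = c("P3", "P4", "C3", "C4", "Pz"),
  FPN = c("Fp1", "F4", "F8", "F7", "F3"),
  LN  = c("F7", "Fp2", "F8", "T7", "T8"),
  SMN = c("C3", "T8", "T7", "C4", "Cz"),
  VAN = c("F8", "F7", "Cz", "T7", "T8"),
  VN  = c("Pz", "P8", "P7", "O1", "O2")
)

# Standard 10-20 (extended) labels accepted without a warning in user montages.
.known_1020 <- c(
  "Fp1", "Fp2", "Fpz", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FCz", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "CP5", "CP1", "CPz", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
  "PO3", "POz", "PO4", "O1", "Oz", "O2", "A1", "A2", "M1", "M2",
  "F9", "F10", "TP9", "TP10", "P9", "P10", "AFz", "AF3", "AF4", "AF7", "AF8")

#' Named electrode set (one network)
#'
#' @param network network name (e.g. `"DMN"`).
#' @param labels ordered, unique electrode labels; the number of labels is the
#'   multivariate dimension p used for this set.
#' @return An object of class `channel_set`.
#' @export
channel_set <- function(network, labels) {
  labels <- as.character(labels)
  if (!length(labels)) stop(sprintf("channel set '%s' is empty", network))
  if (anyDuplicated(labels))
    stop(sprintf("duplicate label in channel set '%s'", network))
  unknown <- setdiff(labels, .known_1020)
  if (length(unknown))
    warning(sprintf("channel set '%s': label(s) not in the extended 10-20 set: %s",
                    network, paste(unknown, collapse = ", ")))
  structure(list(network = as.character(network), labels = labels),
            class = "channel_set")
}

#' The default seven-network montage
#'
#' Returns the seven resting-state-network electrode sets exactly as used in
#' the analysis (DMN, DAN, FPN, LN, SMN, VAN, VN; five electrodes each;
#' overlap between sets allowed and present).
#'
#' @return An object of class `eeg_montage`: a named list of [channel_set()]s
#'   with attribute `source = "default"`.
#' @export
default_montage <- function() {
  sets <- lapply(names(.default_sets),
                 function(nm) channel_set(nm, .default_sets[[nm]]))
  names(sets) <- names(.default_sets)
  structure(sets, class = "eeg_montage", source = "default")
}

#' All electrodes used by the default montage
#'
#' @return character vector of the 19 unique 10-20 labels the default
#'   networks draw from, in first-appearance order.
#' @export
montage_electrodes <- function() {
  unique(unlist(.default_sets, use.names = FALSE))
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channel sets (source: %s)\n",
              length(x), attr(x, "source")))
  for (cs in x)
    cat(sprintf("  %-4s p=%d: %s\n", cs$network, length(cs$labels),
                paste(cs$labels, collapse = ", ")))
  invisible(x)
}

#' Load a montage from a YAML configuration file
#'
#' The file maps set names to electrode label lists, e.g.
#' `DMN: [T7, Fz, F4, T8, Fp2]`. Duplicate labels within a set are an error;
#' overlap across sets is allowed (the default sets overlap); labels outside
#' the extended 10-20 vocabulary produce a warning.
#'
#' @param path path to the YAML file.
#' @return An `eeg_montage`.
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop(sprintf("montage file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (!length(cfg) || is.null(names(cfg)) || any(names(cfg) == ""))
    stop("montage config must map set names to label lists")
  sets <- lapply(names(cfg), function(nm) {
    channel_set(nm, unlist(cfg[[nm]], use.names = FALSE))
  })
  names(sets) <- names(cfg)
  structure(sets, class = "eeg_montage", source = path)
}

#' Extract one network's p-variate signal from an epoch
#'
#' @param epoch channels x samples numeric matrix.
#' @param set a [channel_set()].
#' @param channel_labels labels of the epoch's rows.
#' @param bad_labels labels flagged as bad (unavailable) in the source
#'   recording.
#' @return p x samples matrix with rows ordered as in the channel set.
#' @export
extract_network_signal <- function(epoch, set, channel_labels,
                                   bad_labels = character(0)) {
  stopifnot(inherits(set, "channel_set"))
  missing <- setdiff(set$labels, channel_labels)
  if (length(missing))
    stop(sprintf("network %s: label(s) %s not present in the recording",
                 set$network, paste(missing, collapse = ", ")))
  bad <- intersect(set$labels, bad_labels)
  if (length(bad))
    stop(sprintf("network %s: label(s) %s flagged as bad",
                 set$network, paste(bad, collapse = ", ")))
  idx <- match(set$labels, channel_labels)
  out <- epoch[idx, , drop = FALSE]
  rownames(out) <- set$labels
  out
}

# TRUE when every electrode of `set` is usable.
network_available <- function(set, channel_labels, bad_labels = character(0)) {
  all(set$labels %in% setdiff(channel_labels, bad_labels))
}
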