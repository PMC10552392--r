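# Minimal readers/writers for the two EEG interchange formats the pipeline
# consumes: BrainVision (.vhdr/.vmrk/.eeg, IEEE float32 or int16 multiplexed)
# and EDF (16-bit). Only the subset of each format needed for continuous
# multichannel recordings in microvolts is supported.

#' Write a recording as BrainVision files
#'
#' Writes `<base>.vhdr`, `<base>.vmrk` and `<base>.eeg` (multiplexed IEEE
#' float32, microvolts, resolution 1).
#'
#' @param rec an [recording()].
#' @param base path without extension.
#' @return invisibly, the `.vhdr` path.
#' @export
write_brainvision <- function(rec, base) {
  stopifnot(inherits(rec, "eeg_recording"))
  stem <- basename(base)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", n_channels(rec)),
    sprintf("SamplingInterval=%.6f", 1e6 / rec$srate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(n_channels(rec)), rec$labels))
  writeLines(hdr, paste0(base, ".vhdr"), useBytes = FALSE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]",
               sprintf("DataFile=%s.eeg", stem),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,0"),
             paste0(base, ".vmrk"))
  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(paste0(base, ".vhdr"))
}

#' Read a BrainVision recording
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @param subject_id,group optional metadata to attach.
#' @return an [recording()].
#' @export
read_brainvision <- function(vhdr_path, subject_id = NA_character_,
                             group = NA_character_) {
  if (!file.exists(vhdr_path))
    stop(sprintf("BrainVision header not found: %s", vhdr_path))
  lines <- readLines(vhdr_path, warn = FALSE, encoding = "UTF-8")
  kv <- function(key) {
    hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
    if (!length(hit)) stop(sprintf("%s: missing %s entry", vhdr_path, key))
    sub(sprintf("^%s=", key), "", hit[1])
  }
  fmt <- kv("BinaryFormat")
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop(sprintf("unsupported BinaryFormat '%s'", fmt))
  if (kv("DataOrientation") != "MULTIPLEXED")
    stop("only MULTIPLEXED orientation is supported")
  p <- as.integer(kv("NumberOfChannels"))
  srate <- 1e6 / as.numeric(kv("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != p)
    stop(sprintf("%s: %d channel entries for %d channels",
                 vhdr_path, length(ch_lines), p))
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",", fixed = TRUE)
  labels <- vapply(parts, `[`, character(1), 1L)
  res <- vapply(parts, function(z) {
    v <- suppressWarnings(as.numeric(z[3]))
    if (is.na(v)) 1 else v
  }, numeric(1))
  eeg_path <- file.path(dirname(vhdr_path), kv("DataFile"))
  if (!file.exists(eeg_path))
    stop(sprintf("BrainVision data file not found: %s", eeg_path))
  sz <- file.size(eeg_path)
  bytes <- if (fmt == "IEEE_FLOAT_32") 4L else 2L
  n_vals <- sz %/% bytes
  if (n_vals %% p != 0)
    stop(sprintf("truncated BrainVision payload: %s (%d values, %d channels)",
                 eeg_path, n_vals, p))
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw <- if (fmt == "IEEE_FLOAT_32") {
    readBin(con, "numeric", n = n_vals, size = 4, endian = "little")
  } else {
    readBin(con, "integer", n = n_vals, size = 2, signed = TRUE,
            endian = "little")
  }
  x <- matrix(raw, nrow = p)
  x <- x * res
  recording(x, srate, labels, subject_id = subject_id, group = group)
}

#' Write a recording as EDF
#'
#' 16-bit EDF with one-second data records; the recording length must be a
#' whole number of seconds and the sampling rate an integer.
#'
#' @param rec an [recording()].
#' @param path output `.edf` path.
#' @return invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  p <- n_channels(rec)
  srate <- rec$srate
  if (abs(srate - round(srate)) > 1e-9) stop("EDF writer needs an integer sampling rate")
  srate <- as.integer(round(srate))
  n <- n_samples(rec)
  if (n %% srate != 0) stop("EDF writer needs a whole number of seconds")
  n_rec <- n %/% srate
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  # Physical limits must fit the 8-char header fields. Widen the data range
  # slightly, format to <= 8 chars, and use the parsed-back (rounded) values
  # for digitization so header and payload stay consistent.
  fmt8 <- function(v) {
    s <- sprintf("%.2f", v)
    long <- nchar(s) > 8
    s[long] <- sprintf("%.3g", v[long])
    s
  }
  lo <- apply(rec$data, 1L, min)
  hi <- apply(rec$data, 1L, max)
  span <- pmax(hi - lo, 1)
  pmin_s <- fmt8(lo - 0.01 * span)
  pmax_s <- fmt8(hi + 0.01 * span)
  pmin_ <- as.numeric(pmin_s)
  pmax_ <- as.numeric(pmax_s)
  hdr <- paste0(
    pad("0", 8), pad("X", 80), pad("X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + p * 256, 8), pad("", 44), pad(n_rec, 8), pad("1", 8), pad(p, 4))
  sig <- paste0(
    paste(vapply(rec$labels, pad, character(1), w = 16), collapse = ""),
    paste(rep(pad("", 80), p), collapse = ""),
    paste(rep(pad("uV", 8), p), collapse = ""),
    paste(vapply(pmin_s, pad, character(1), w = 8), collapse = ""),
    paste(vapply(pmax_s, pad, character(1), w = 8), collapse = ""),
    paste(rep(pad("-32768", 8), p), collapse = ""),
    paste(rep(pad("32767", 8), p), collapse = ""),
    paste(rep(pad("", 80), p), collapse = ""),
    paste(rep(pad(srate, 8), p), collapse = ""),
    paste(rep(pad("", 32), p), collapse = ""))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(hdr, sig)), con)
  dig <- matrix(0L, p, n)
  for (k in seq_len(p)) {
    dig[k, ] <- as.integer(round((rec$data[k, ] - pmin_[k]) /
                                   (pmax_[k] - pmin_[k]) * 65535 - 32768))
  }
  for (r0 in seq_len(n_rec)) {
    idx <- ((r0 - 1) * srate + 1):(r0 * srate)
    for (k in seq_len(p))
      writeBin(dig[k, idx], con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Supports continuous 16-bit EDF where every signal shares one sampling
#' rate.
#'
#' @param path `.edf` path.
#' @param subject_id,group optional metadata to attach.
#' @return an [recording()].
#' @export
read_edf <- function(path, subject_id = NA_character_, group = NA_character_) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  p <- as.integer(rd(4))
  if (is.na(p) || p < 1) stop(sprintf("malformed EDF header in %s", path))
  labels <- vapply(seq_len(p), function(i) rd(16), character(1))
  rd(80 * p); rd(8 * p)
  pmin_ <- as.numeric(vapply(seq_len(p), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(p), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(p), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(p), function(i) rd(8), character(1)))
  rd(80 * p)
  nsamp <- as.integer(vapply(seq_len(p), function(i) rd(8), character(1)))
  rd(32 * p)
  if (length(unique(nsamp)) != 1)
    stop("EDF reader requires a common sampling rate across signals")
  ns <- nsamp[1]
  srate <- ns / dur
  expected <- 2 * sum(nsamp) * n_rec
  payload <- file.size(path) - hdr_bytes
  if (payload < expected)
    stop(sprintf("truncated EDF payload in %s: %d bytes, expected %d",
                 path, payload, expected))
  x <- matrix(0, p, ns * n_rec)
  for (r0 in seq_len(n_rec)) {
    for (k in seq_len(p)) {
      d <- readBin(con, "integer", n = ns, size = 2, signed = TRUE,
                   endian = "little")
      x[k, ((r0 - 1) * ns + 1):(r0 * ns)] <-
        pmin_[k] + (d - dmin_[k]) / (dmax_[k] - dmin_[k]) * (pmax_[k] - pmin_[k])
    }
  }
  recording(x, srate, labels, subject_id = subject_id, group = group)
}

#' Read a recording in either supported format
#'
#' @param path path to a `.vhdr` (BrainVision) or `.edf` file.
#' @param format `"brainvision"`, `"edf"`, or `"auto"` (by extension).
#' @param ... passed to the format-specific reader.
#' @return an [recording()].
#' @export
read_recording <- function(path, format = c("auto", "brainvision", "edf"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vhdr = "brainvision", edf = "edf",
                     stop(sprintf("cannot infer format from extension '.%s'", ext)))
  }
  switch(format,
         brainvision = read_brainvision(path, ...),
         edf = read_edf(path, ...))
}

#' Write a generated cohort to disk
#'
#' One file (pair) per subject plus a `cohort.tsv` sidecar with subject id,
#' group and the per-subject seed.
#'
#' @param cohort list of [recording()]s (as from [generate_cohort()]).
#' @param dir output directory (created if missing).
#' @param format `"brainvision"` or `"edf"`.
#' @param seeds optional per-subject seeds for the sidecar.
#' @return invisibly, the sidecar path.
#' @export
write_cohort <- function(cohort, dir, format = c("brainvision", "edf"),
                         seeds = NULL) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- data.frame(subject_id = character(0), group = character(0),
                     file = character(0), seed = integer(0))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    fname <- if (format == "brainvision") {
      write_brainvision(rec, file.path(dir, rec$subject_id))
      paste0(rec$subject_id, ".vhdr")
    } else {
      write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
      paste0(rec$subject_id, ".edf")
    }
    meta <- rbind(meta, data.frame(
      subject_id = rec$subject_id, group = rec$group, file = fname,
      seed = if (is.null(seeds)) NA_integer_ else seeds[i]))
  }
  sidecar <- file.path(dir, "cohort.tsv")
  write.table(meta, sidecar, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(sidecar)
}
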