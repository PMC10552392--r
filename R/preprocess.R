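# The preprocessing cascade, in the order used for the resting-state
# analysis: downsample -> 1 Hz high-pass -> SD-based bad-channel removal ->
# 444 uV epoch rejection -> 40 Hz low-pass -> average reference -> 222 uV
# rejection -> (pluggable artifact-removal hook) -> 111 uV rejection.
# Amplitude-rejection stages share the final 10,240-sample epoch grid, which
# is fixed right after the high-pass; the filters and the reference are
# applied per epoch on that grid. Removed channels are excluded downstream
# (interpolation is cosmetic in the original procedure and is not performed).

#' Preprocessing configuration
#'
#' Defaults are the cascade parameters used throughout: 256 Hz target rate,
#' 1-40 Hz band, channel-SD z thresholds of 5 (0-5 Hz band) and 2.5
#' (5-40 Hz band), staged epoch-rejection thresholds 444/222/111 microvolts,
#' and 10,240-sample (40 s) epochs.
#'
#' @param target_rate resampling target in Hz.
#' @param highpass_hz,lowpass_hz band edges in Hz.
#' @param chan_sd_threshold_low_band z threshold on per-channel SD in the
#'   0-5 Hz band.
#' @param chan_sd_threshold_high_band z threshold in the 5-40 Hz band.
#' @param epoch_reject_uv_stage1,epoch_reject_uv_stage2,epoch_reject_uv_stage3
#'   absolute-amplitude rejection thresholds (microvolts) for the three
#'   rejection passes; must be strictly decreasing.
#' @param epoch_samples epoch length in samples at `target_rate`.
#'
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate = 256,
                              highpass_hz = 1, lowpass_hz = 40,
                              chan_sd_threshold_low_band = 5,
                              chan_sd_threshold_high_band = 2.5,
                              epoch_reject_uv_stage1 = 444,
                              epoch_reject_uv_stage2 = 222,
                              epoch_reject_uv_stage3 = 111,
                              epoch_samples = 10240) {
  th <- c(epoch_reject_uv_stage1, epoch_reject_uv_stage2, epoch_reject_uv_stage3)
  if (any(th <= 0)) stop("rejection thresholds must be positive")
  if (!(th[1] > th[2] && th[2] > th[3]))
    stop("rejection thresholds must satisfy stage1 > stage2 > stage3")
  if (target_rate <= 0) stop("`target_rate` must be positive")
  structure(as.list(environment()), class = "preprocess_config")
}

butter_apply <- function(x, filt) {
  t(apply(x, 1L, function(ch) signal::filtfilt(filt, ch)))
}

#' Resample a recording to a lower rate
#'
#' Rational polyphase resampling (anti-alias filtered); output length is
#' `round(N * target / source)`. A no-op when already at the target rate.
#'
#' @param rec an [recording()].
#' @param target_rate target sampling rate in Hz (positive, <= current rate).
#' @return resampled [recording()].
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate <= 0) stop("`target_rate` must be positive")
  if (target_rate > rec$srate) stop("upsampling not supported")
  if (target_rate == rec$srate) return(rec)
  frac <- rational_ratio(target_rate, rec$srate)
  n_out <- round(n_samples(rec) * target_rate / rec$srate)
  y <- t(apply(rec$data, 1L, function(ch) {
    out <- signal::resample(ch, frac[1], frac[2])
    length(out) <- n_out          # pad/trim to the length contract
    out[is.na(out)] <- 0
    out
  }))
  rec$data <- y
  rec$srate <- target_rate
  rec
}

# Reduced integer ratio p/q ~ a/b for (possibly non-integer) rates.
rational_ratio <- function(a, b) {
  scale <- 1000
  p <- round(a * scale); q <- round(b * scale)
  g <- gcd_int(p, q)
  c(p / g, q / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Zero-phase Butterworth band filtering
#'
#' Applies a 4th-order Butterworth high-pass and/or low-pass filter forwards
#' and backwards (zero phase) to every channel.
#'
#' @param rec an [recording()].
#' @param highpass_hz,lowpass_hz cutoff frequencies in Hz (`NULL` to skip);
#'   must be below the Nyquist frequency.
#' @return filtered [recording()].
#' @export
filter_band <- function(rec, highpass_hz = NULL, lowpass_hz = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$srate / 2
  x <- rec$data
  if (!is.null(highpass_hz)) {
    if (highpass_hz >= nyq) stop("high-pass cutoff at or above Nyquist")
    x <- x - rowMeans(x)     # demean first to suppress filter edge transients
    x <- butter_apply(x, signal::butter(4, highpass_hz / nyq, type = "high"))
  }
  if (!is.null(lowpass_hz)) {
    if (lowpass_hz >= nyq) stop("low-pass cutoff at or above Nyquist")
    x <- butter_apply(x, signal::butter(4, lowpass_hz / nyq, type = "low"))
  }
  rec$data <- x
  rec
}

#' Detect outlier channels from band-limited standard deviations
#'
#' For the 0-5 Hz and 5-40 Hz bands, each channel's band-limited SD is
#' standardized against the channel population (z-score over the per-channel
#' SDs); channels exceeding the per-band z threshold are flagged. The union
#' over the two bands is returned.
#'
#' @param rec an [recording()] (>= 4 channels).
#' @param config a [preprocess_config()].
#' @return character vector of flagged channel labels (possibly empty), with
#'   attribute `zscores` (channels x 2 matrix of per-band z-scores).
#' @export
detect_bad_channels <- function(rec, config = preprocess_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 4)
    stop("bad-channel detection needs >= 4 channels for population statistics")
  nyq <- rec$srate / 2
  low <- butter_apply(rec$data, signal::butter(4, 5 / nyq, type = "low"))
  high <- butter_apply(rec$data,
                       signal::butter(4, c(5, min(40, nyq * 0.99)) / nyq,
                                      type = "pass"))
  zs <- cbind(low = pop_z(apply(low, 1L, sd)),
              high = pop_z(apply(high, 1L, sd)))
  rownames(zs) <- rec$labels
  flagged <- rec$labels[zs[, "low"] > config$chan_sd_threshold_low_band |
                          zs[, "high"] > config$chan_sd_threshold_high_band]
  structure(flagged, zscores = zs)
}

pop_z <- function(v) {
  s <- sd(v)
  if (s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Re-reference to the average (common) reference
#'
#' Subtracts the per-sample mean across channels, leaving every column with
#' zero mean. Idempotent.
#'
#' @param rec an [recording()] (>= 2 channels).
#' @return re-referenced [recording()] with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2) stop("average reference needs >= 2 channels")
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data))
  rec$reference <- "average"
  rec
}

#' Cut a recording into disjoint fixed-length epochs
#'
#' Extracts `floor(N / epoch_samples)` consecutive disjoint epochs starting
#' at sample 1; the trailing remainder is discarded. A too-short recording
#' yields an empty epoch set with a warning entry in the log.
#'
#' @param rec an [recording()].
#' @param epoch_samples samples per epoch.
#' @return an [epoch_set()].
#' @export
extract_epochs <- function(rec, epoch_samples = 10240) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- n_samples(rec)
  k <- n %/% epoch_samples
  log <- empty_preprocess_log()
  if (k == 0) {
    warning(sprintf("recording too short for a single %d-sample epoch", epoch_samples))
    log <- rbind(log, log_entry("extract", "too_short", NA, n))
  }
  starts <- (seq_len(k) - 1L) * epoch_samples + 1L
  eps <- lapply(starts, function(s0) {
    rec$data[, s0:(s0 + epoch_samples - 1L), drop = FALSE]
  })
  epoch_set(eps, rec$srate, rec$labels, starts = starts, log = log,
            subject_id = rec$subject_id, group = rec$group)
}

#' Reject epochs by absolute amplitude
#'
#' An epoch is rejected iff its maximum absolute value over all channels and
#' samples exceeds the threshold.
#'
#' @param epochs an [epoch_set()].
#' @param threshold_uv rejection threshold in microvolts (> 0).
#' @param stage label recorded in the rejection log.
#' @return the surviving [epoch_set()]; the log gains one `reject` entry per
#'   removed epoch (index = original epoch position, value = peak amplitude).
#' @export
reject_epochs_by_amplitude <- function(epochs, threshold_uv,
                                       stage = "amplitude") {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (threshold_uv <= 0) stop("`threshold_uv` must be positive")
  if (!length(epochs$epochs)) return(epochs)
  peaks <- vapply(epochs$epochs, function(e) max(abs(e)), numeric(1))
  drop <- which(peaks > threshold_uv)
  log <- epochs$log
  for (d in drop)
    log <- rbind(log, log_entry(stage, "reject_epoch", d, peaks[d]))
  epochs$epochs <- epochs$epochs[setdiff(seq_along(peaks), drop)]
  epochs$starts <- epochs$starts[setdiff(seq_along(peaks), drop)]
  epochs$log <- log
  epochs
}

apply_to_epochs <- function(epochs, f) {
  epochs$epochs <- lapply(epochs$epochs, f)
  epochs
}

#' Full preprocessing cascade
#'
#' Runs the staged pipeline (see the file-level description for the order),
#' logging every action. `ica_hook`, when supplied, receives and returns the
#' epoch set between the 222 and 111 microvolt stages (the slot occupied by
#' component-based artifact removal in the original procedure); the default
#' is a pass-through. `rereference = FALSE` skips the average-reference
#' stage, which is appropriate for reference-free synthetic cohorts (see the
#' vignette).
#'
#' @param rec an [recording()].
#' @param config a [preprocess_config()].
#' @param ica_hook optional function `eeg_epochs -> eeg_epochs`.
#' @param rereference apply the average-reference stage (default `TRUE`).
#' @return an [epoch_set()] of clean epochs; attributes `bad_labels` (removed
#'   channels). The log records resampling, filtering, channel removals and
#'   every epoch rejection with its trigger value.
#' @export
preprocess_pipeline <- function(rec, config = preprocess_config(),
                                ica_hook = NULL, rereference = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(config, "preprocess_config"))
  log <- empty_preprocess_log()

  if (rec$srate != config$target_rate) {
    rec <- resample_recording(rec, config$target_rate)
    log <- rbind(log, log_entry("resample", "to_target_rate", NA,
                                config$target_rate))
  }
  rec <- filter_band(rec, highpass_hz = config$highpass_hz)
  log <- rbind(log, log_entry("highpass", "filtered", NA, config$highpass_hz))

  bad <- character(0)
  if (n_channels(rec) >= 4) {
    bad <- detect_bad_channels(rec, config)
    for (b in bad)
      log <- rbind(log, log_entry("bad_channels", paste0("removed_", b),
                                  match(b, rec$labels), NA))
    if (length(bad)) {
      keep <- !(rec$labels %in% bad)
      rec$data <- rec$data[keep, , drop = FALSE]
      rec$labels <- rec$labels[keep]
    }
  }

  epochs <- extract_epochs(rec, config$epoch_samples)
  epochs$log <- rbind(log, epochs$log)
  epochs <- reject_epochs_by_amplitude(epochs, config$epoch_reject_uv_stage1,
                                       stage = "stage1_444")

  lp <- signal::butter(4, config$lowpass_hz / (rec$srate / 2), type = "low")
  epochs <- apply_to_epochs(epochs, function(e) butter_apply(e, lp))
  epochs$log <- rbind(epochs$log,
                      log_entry("lowpass", "filtered", NA, config$lowpass_hz))

  if (rereference && length(epochs$labels) >= 2) {
    epochs <- apply_to_epochs(epochs, function(e) sweep(e, 2L, colMeans(e)))
    epochs$log <- rbind(epochs$log, log_entry("reference", "average", NA, NA))
  }

  epochs <- reject_epochs_by_amplitude(epochs, config$epoch_reject_uv_stage2,
                                       stage = "stage2_222")
  if (!is.null(ica_hook)) {
    epochs <- ica_hook(epochs)
    epochs$log <- rbind(epochs$log, log_entry("ica_hook", "applied", NA, NA))
  }
  epochs <- reject_epochs_by_amplitude(epochs, config$epoch_reject_uv_stage3,
                                       stage = "stage3_111")

  attr(epochs, "bad_labels") <- as.character(bad)
  epochs
}
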