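# Surrogate multichannel EEG with known spectral/entropy structure.
#
# Signals are built per channel as a weighted mixture of three noise classes
# (white: entropy decays across scales; 1/f: flat entropy profile; AR(1):
# short-memory), then spatially mixed through a common-mode matrix so channels
# share most of their signal, as volume conduction makes real scalp channels do.

#' Noise mixture specification
#'
#' Describes one group's signal-generating process: non-negative weights for
#' the white, 1/f ("pink") and AR(1) components, the AR coefficient, and the
#' cross-channel mixing strength.
#'
#' @param w_white,w_pink,w_ar non-negative component weights (amplitude scale;
#'   at least one must be positive).
#' @param ar_coefficient AR(1) coefficient in (-1, 1).
#' @param mixing_strength off-diagonal channel-mixing weight in `[0, 1)`, or
#'   `NULL` (default) to resolve at generation time to `0.99 * (p - 1) / p`
#'   for `p` channels. The default keeps the induced inter-channel correlation
#'   (~0.998) constant across montage sizes; see the package vignette for why
#'   the multivariate entropy estimator needs strongly covarying channels at
#'   segment length 1024.
#' @param subject_sd standard deviation (log scale) of the per-subject
#'   multiplicative jitter applied to the component weights; gives subjects
#'   trait-like individual differences so segment-wise reliability is
#'   non-trivial. 0 disables jitter.
#'
#' @return An object of class `noise_mixture_spec`.
#' @export
noise_mixture_spec <- function(w_white = 0, w_pink = 0, w_ar = 0,
                               ar_coefficient = 0.9,
                               mixing_strength = NULL,
                               subject_sd = 0.15) {
  w <- c(w_white, w_pink, w_ar)
  if (any(w < 0) || !any(w > 0))
    stop("mixture weights must be non-negative with at least one positive")
  if (abs(ar_coefficient) >= 1) stop("`ar_coefficient` must lie in (-1, 1)")
  if (!is.null(mixing_strength) &&
      (mixing_strength < 0 || mixing_strength >= 1))
    stop("`mixing_strength` must lie in [0, 1)")
  if (subject_sd < 0) stop("`subject_sd` must be >= 0")
  structure(list(w_white = w_white, w_pink = w_pink, w_ar = w_ar,
                 ar_coefficient = ar_coefficient,
                 mixing_strength = mixing_strength,
                 subject_sd = subject_sd),
            class = "noise_mixture_spec")
}

#' Two-group synthetic cohort specification
#'
#' Defaults emulate a scaled-down version of the study design: two groups of
#' 20 subjects, the 19 electrodes used by the default network montage, 40-s
#' epochs at 256 Hz, three epochs per subject (the three reliability "items"),
#' and group mixtures that trade fine-scale against coarse-scale entropy
#' (group a white-heavy, group b pink-heavy).
#'
#' @param n_group_a,n_group_b subjects per group.
#' @param spec_a,spec_b [noise_mixture_spec()] for each group.
#' @param n_channels number of channels.
#' @param sampling_rate Hz.
#' @param epoch_length_s epoch length in seconds; `sampling_rate *
#'   epoch_length_s` must be a whole number of samples.
#' @param n_epochs epochs per subject.
#' @param seed integer cohort seed; per-subject seeds are derived from it.
#' @param channel_labels unique channel labels (10-20 names for default use).
#' @param scale_uv per-channel signal standard deviation in microvolts.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 20, n_group_b = 20,
                        spec_a = noise_mixture_spec(w_white = 0.8, w_pink = 0.2),
                        spec_b = noise_mixture_spec(w_white = 0.2, w_pink = 0.8),
                        n_channels = length(channel_labels),
                        sampling_rate = 256,
                        epoch_length_s = 40,
                        n_epochs = 3,
                        seed = 1L,
                        channel_labels = montage_electrodes(),
                        scale_uv = 15) {
  if (n_group_a < 0 || n_group_b < 0 || n_group_a + n_group_b < 1)
    stop("cohort must contain at least one subject")
  ns <- sampling_rate * epoch_length_s
  if (abs(ns - round(ns)) > 1e-9)
    stop("sampling_rate * epoch_length_s must be an integer sample count")
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (length(channel_labels) != n_channels)
    stop(sprintf("%d labels for %d channels", length(channel_labels), n_channels))
  if (n_epochs < 1) stop("`n_epochs` must be >= 1")
  stopifnot(inherits(spec_a, "noise_mixture_spec"),
            inherits(spec_b, "noise_mixture_spec"))
  structure(list(n_group_a = n_group_a, n_group_b = n_group_b,
                 spec_a = spec_a, spec_b = spec_b,
                 n_channels = n_channels, sampling_rate = sampling_rate,
                 epoch_length_s = epoch_length_s, n_epochs = n_epochs,
                 seed = as.integer(seed), channel_labels = channel_labels,
                 scale_uv = scale_uv),
            class = "cohort_spec")
}

#' Artifact injection specification
#'
#' @param spike_amplitude spike height in microvolts (> 0).
#' @param spike_count number of spikes, spread evenly over the recording (one
#'   per stretch of `total/spike_count` samples, so up to `spike_count`
#'   distinct epochs carry a spike).
#' @param bad_channel_indices integer channel indices to corrupt.
#' @param bad_channel_gain multiplicative gain applied to bad channels.
#'
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(spike_amplitude = 500, spike_count = 0,
                          bad_channel_indices = integer(0),
                          bad_channel_gain = 10) {
  if (spike_amplitude <= 0) stop("`spike_amplitude` must be > 0")
  if (spike_count < 0) stop("`spike_count` must be >= 0")
  structure(list(spike_amplitude = spike_amplitude,
                 spike_count = as.integer(spike_count),
                 bad_channel_indices = as.integer(bad_channel_indices),
                 bad_channel_gain = bad_channel_gain),
            class = "artifact_spec")
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate multichannel white noise
#'
#' i.i.d. standard Gaussian samples per channel, reproducible for a fixed
#' seed.
#'
#' @param n_samples samples per channel (>= 1).
#' @param n_channels number of channels (>= 1).
#' @param seed integer seed.
#' @return channels x samples numeric matrix.
#' @export
generate_white_noise <- function(n_samples, n_channels, seed) {
  if (n_samples < 1 || n_channels < 1)
    stop("`n_samples` and `n_channels` must be positive")
  with_seed(seed,
            matrix(rnorm(n_samples * n_channels), nrow = n_channels))
}

#' Generate multichannel 1/f ("pink") noise
#'
#' White Gaussian noise shaped in the frequency domain so each channel's power
#' spectral density is proportional to 1/f (amplitude scaling by
#' `f^(-1/2)`, zero-frequency bin set to 0), then standardized to zero mean
#' and unit variance per channel.
#'
#' @inheritParams generate_white_noise
#' @return channels x samples numeric matrix.
#' @export
generate_pink_noise <- function(n_samples, n_channels, seed) {
  if (n_samples < 16) stop("`n_samples` must be >= 16")
  if (n_channels < 1) stop("`n_channels` must be positive")
  w <- generate_white_noise(n_samples, n_channels, seed)
  t(apply(w, 1L, shape_one_over_f))
}

# 1/f amplitude shaping of one white-noise channel.
shape_one_over_f <- function(x) {
  n <- length(x)
  f <- fft(x)
  # symmetric frequency index: bin k (0-based) has frequency min(k, n-k)/n
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / n
  amp <- c(0, 1 / sqrt(freq[-1]))
  y <- Re(fft(f * amp, inverse = TRUE)) / n
  as.numeric(scale(y))
}

# AR(1) noise, standardized, with burn-in discarded.
generate_ar_noise <- function(n_samples, n_channels, phi, seed) {
  burn <- 100L
  e <- generate_white_noise(n_samples + burn, n_channels, seed)
  x <- t(apply(e, 1L, function(ch) {
    stats::filter(ch, phi, method = "recursive")[(burn + 1):(burn + n_samples)]
  }))
  x <- x - rowMeans(x)
  x / apply(x, 1L, sd)
}

# Common-mode channel mixing matrix: (1-a) * own + a * mean(others).
mixing_matrix <- function(p, alpha) {
  if (p == 1L || alpha == 0) return(diag(p))
  (1 - alpha) * diag(p) + alpha / (p - 1) * (matrix(1, p, p) - diag(p))
}

resolve_mixing <- function(spec, p) {
  if (!is.null(spec$mixing_strength)) return(spec$mixing_strength)
  if (p == 1L) return(0)
  0.99 * (p - 1) / p
}

#' Generate one subject's recording from a cohort specification
#'
#' Builds each channel as the standardized mixture
#' `w_white * white + w_pink * pink + w_ar * AR(1)`, applies the common-mode
#' spatial mixing (`(1 - mixing) * own + mixing * mean(others)`), rescales to
#' `scale_uv` microvolts SD per channel, and labels the result.
#'
#' @param spec a [cohort_spec()].
#' @param group `"a"` or `"b"`.
#' @param subject_id subject identifier.
#' @param seed integer seed for this subject.
#' @return An [recording()] of `n_epochs * epoch_length_s` seconds.
#' @export
generate_subject_recording <- function(spec, group = c("a", "b"),
                                       subject_id, seed) {
  group <- match.arg(group)
  mspec <- if (group == "a") spec$spec_a else spec$spec_b
  p <- spec$n_channels
  if (length(spec$channel_labels) != p)
    stop("label count does not match n_channels")
  n <- round(spec$sampling_rate * spec$epoch_length_s) * spec$n_epochs

  w <- c(mspec$w_white, mspec$w_pink, mspec$w_ar)
  if (mspec$subject_sd > 0) {
    jit <- with_seed(seed + 1L,
                     exp(rnorm(3, -mspec$subject_sd^2 / 2, mspec$subject_sd)))
    w <- w * jit
  }

  x <- matrix(0, p, n)
  if (w[1] > 0) x <- x + w[1] * generate_white_noise(n, p, seed)
  if (w[2] > 0) x <- x + w[2] * generate_pink_noise(n, p, seed + 2L)
  if (w[3] > 0) x <- x + w[3] * generate_ar_noise(n, p, mspec$ar_coefficient,
                                                  seed + 3L)
  x <- x - rowMeans(x)
  x <- x / apply(x, 1L, sd)
  alpha <- resolve_mixing(mspec, p)
  x <- mixing_matrix(p, alpha) %*% x
  x <- x / apply(x, 1L, sd) * spec$scale_uv
  recording(x, spec$sampling_rate, spec$channel_labels,
            subject_id = subject_id, group = group)
}

# Deterministic per-subject seed below 2^31, derived from the cohort seed.
subject_seed <- function(cohort_seed, subject_index) {
  as.integer((as.numeric(cohort_seed) %% 100003 * 20011 +
                subject_index * 104729 + 17) %% 2147480017)
}

#' Generate a full two-group cohort
#'
#' A pure function of its specification: per-subject seeds are derived
#' deterministically from the cohort seed, so the same `cohort_spec` always
#' yields the same cohort.
#'
#' @param spec a [cohort_spec()].
#' @return list of [recording()] objects (group a first, then group b), with
#'   subject ids `"a01"..`, `"b01"..`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("a%02d", seq_len(spec$n_group_a)),
           sprintf("b%02d", seq_len(spec$n_group_b)))
  groups <- rep(c("a", "b"), c(spec$n_group_a, spec$n_group_b))
  lapply(seq_along(ids), function(i) {
    generate_subject_recording(spec, groups[i], ids[i],
                               subject_seed(spec$seed, i))
  })
}

#' Inject controlled artifacts into a recording
#'
#' Adds high-amplitude spikes (one per stretch of `total / spike_count`
#' samples, applied across all channels simultaneously, like a movement
#' artifact) and scales "bad" channels by a gain, returning the corrupted
#' recording alongside a log of every injection.
#'
#' @param rec an [recording()].
#' @param aspec an [artifact_spec()].
#' @return list with elements `recording` (corrupted copy) and `log`
#'   (data.frame: kind, channel, sample, value).
#' @export
inject_artifacts <- function(rec, aspec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(aspec, "artifact_spec"))
  n <- n_samples(rec)
  p <- n_channels(rec)
  if (length(aspec$bad_channel_indices) &&
      (min(aspec$bad_channel_indices) < 1 || max(aspec$bad_channel_indices) > p))
    stop("bad channel index out of range")
  if (aspec$spike_count > n) stop("more spikes than samples")
  log <- data.frame(kind = character(0), channel = integer(0),
                    sample = integer(0), value = numeric(0))
  x <- rec$data
  if (aspec$spike_count > 0) {
    pos <- floor((seq_len(aspec$spike_count) - 0.5) * n / aspec$spike_count) + 1L
    for (s0 in pos) {
      sgn <- sign(x[, s0])
      sgn[sgn == 0] <- 1
      x[, s0] <- x[, s0] + sgn * aspec$spike_amplitude
    }
    log <- rbind(log, data.frame(kind = "spike", channel = NA_integer_,
                                 sample = pos,
                                 value = aspec$spike_amplitude))
  }
  for (ch in aspec$bad_channel_indices) {
    x[ch, ] <- x[ch, ] * aspec$bad_channel_gain
    log <- rbind(log, data.frame(kind = "bad_channel", channel = ch,
                                 sample = NA_integer_,
                                 value = aspec$bad_channel_gain))
  }
  out <- rec
  out$data <- x
  list(recording = out, log = log)
}
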