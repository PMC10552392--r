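# Multivariate multiscale sample entropy (mMSE).
#
# The entropy of a p-variate segment at scale s is the negative log of the
# conditional probability that composite delay vectors (spanning all p
# channels) matching within Chebyshev distance r at total dimension sum(m)
# still match when extended by one further delayed sample of one variate.
# The multiscale profile applies this to coarse-grained versions of the
# segment (non-overlapping window means of length s), with the segment
# standardized once at scale 1 so the fixed r retains its conventional
# meaning as a fraction of the scale-1 standard deviation.

#' mMSE parameter set
#'
#' @param m embedding dimension per variate (scalar, applied to every
#'   channel). Default 2.
#' @param r similarity threshold in units of the scale-1 standardized
#'   amplitude. Default 0.15.
#' @param tau time delay per variate. Default 1.
#' @param max_scale largest coarse-graining scale factor (the profile covers
#'   scales `1..max_scale`). Default 12.
#' @param segment_length samples per analysis segment at scale 1. Default
#'   1024, giving coarse series of >= 85 samples at the default
#'   `max_scale = 12`.
#'
#' @return An object of class `mmse_params`.
#' @export
mmse_params <- function(m = 2, r = 0.15, tau = 1, max_scale = 12,
                        segment_length = 1024) {
  if (m < 1 || tau < 1 || max_scale < 1) stop("m, tau and max_scale must be >= 1")
  if (r <= 0) stop("`r` must be positive")
  min_coarse <- max(m * tau + 2, 20)   # below ~20 samples pair counts are vacuous
  if (floor(segment_length / max_scale) < min_coarse)
    stop(sprintf(
      "segment_length %d too short: coarse series at scale %d has %d samples, need >= %d",
      segment_length, max_scale, floor(segment_length / max_scale), min_coarse))
  structure(list(m = as.integer(m), r = r, tau = as.integer(tau),
                 max_scale = as.integer(max_scale),
                 segment_length = as.integer(segment_length)),
            class = "mmse_params")
}

#' Coarse-grain a multichannel series
#'
#' Replaces each channel by the means of consecutive non-overlapping windows
#' of length `scale`; a trailing remainder shorter than `scale` is dropped.
#'
#' @param x p x N numeric matrix (a vector is treated as one channel).
#' @param scale scale factor (>= 1).
#' @return p x floor(N/scale) matrix.
#' @export
coarse_grain <- function(x, scale) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  scale <- as.integer(scale)
  if (scale < 1) stop("`scale` must be >= 1")
  n <- ncol(x)
  if (n < scale) stop("series shorter than the scale factor")
  if (scale == 1L) return(x)
  L <- n %/% scale
  out <- matrix(0, nrow(x), L)
  for (k in seq_len(nrow(x))) {
    out[k, ] <- colMeans(matrix(x[k, seq_len(L * scale)], nrow = scale))
  }
  out
}

#' Standardize each channel of a segment
#'
#' Centers and scales every channel to mean 0, SD 1. Channels with zero
#' variance are left centered and flagged via the `degenerate_channels`
#' attribute rather than divided by zero.
#'
#' @param x p x n numeric matrix.
#' @return standardized matrix, with attribute `degenerate_channels`
#'   (integer indices, possibly empty).
#' @export
standardize_segment <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  degen <- which(s == 0 | !is.finite(s))
  s[degen] <- 1
  out <- (x - mu) / s
  attr(out, "degenerate_channels") <- degen
  out
}

#' Multivariate sample entropy of one segment
#'
#' Forms composite delay vectors across all channels, counts ordered pairs
#' with distinct time origins matching within Chebyshev distance `r` at total
#' dimension `sum(m)` (`B_m`) and, after extending each vector by one further
#' delayed sample in each variate separately (`p * (N - n*)` vectors), at
#' dimension `sum(m) + 1` (`B_{m+1}`); returns `-log(B_{m+1} / B_m)` in nats.
#'
#' @param x p x N numeric matrix (a vector is treated as one channel). The
#'   caller is responsible for any standardization.
#' @param m embedding dimension per variate (scalar or length-p vector).
#' @param r similarity threshold.
#' @param tau time delay per variate (scalar or length-p vector).
#' @return entropy in nats, or `NA` with attribute `undefined` (`"B_m"` or
#'   `"B_m1"`) when no matches exist at one of the two dimensions.
#' @export
msampen <- function(x, m = 2, r = 0.15, tau = 1) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  p <- nrow(x)
  if (r <= 0) stop("`r` must be positive")
  m <- rep_len(as.integer(m), p)
  tau <- rep_len(as.integer(tau), p)
  if (ncol(x) < max(m * tau) + 2)
    stop("segment too short for the requested embedding")
  cnt <- .msampen_counts(x, m, tau, r)
  if (cnt$bm_count == 0) {
    out <- NA_real_; attr(out, "undefined") <- "B_m"; return(out)
  }
  if (cnt$bm1_count == 0) {
    out <- NA_real_; attr(out, "undefined") <- "B_m1"; return(out)
  }
  M <- cnt$n_vectors
  bm <- cnt$bm_count / (M * (M - 1))
  bm1 <- cnt$bm1_count / (p^2 * M * (M - 1))
  -log(bm1 / bm)
}

#' Brute-force reference implementation of [msampen()]
#'
#' Constructs every composite delay vector explicitly and compares all pairs
#' exhaustively in R. O(N^2) and slow; exists as an independent oracle for
#' the optimized counting kernel, and is exact to floating-point
#' associativity.
#'
#' @inheritParams msampen
#' @return entropy in nats, or `NA` (attribute `undefined`) as for
#'   [msampen()].
#' @export
msampen_brute <- function(x, m = 2, r = 0.15, tau = 1) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  p <- nrow(x); N <- ncol(x)
  m <- rep_len(as.integer(m), p)
  tau <- rep_len(as.integer(tau), p)
  nstar <- max(m * tau)
  M <- N - nstar
  if (M < 2) stop("segment too short")
  # base vectors, one row per origin
  base <- do.call(cbind, lapply(seq_len(p), function(k) {
    sapply(0:(m[k] - 1), function(t) x[k, (1:M) + t * tau[k]])
  }))
  base <- matrix(base, nrow = M)
  # full pairwise Chebyshev distance matrix over the base vectors
  pair_cheb <- function(V) {
    D <- matrix(0, nrow(V), nrow(V))
    for (d in seq_len(ncol(V)))
      D <- pmax(D, abs(outer(V[, d], V[, d], "-")))
    D
  }
  Db <- pair_cheb(base)
  bm <- sum(Db <= r) - M                       # remove self pairs
  if (bm == 0) { out <- NA_real_; attr(out, "undefined") <- "B_m"; return(out) }
  # extended vectors: (origin i, incremented variate k), stacked k-major
  ext <- do.call(rbind, lapply(seq_len(p), function(k) {
    cbind(base, x[k, (1:M) + m[k] * tau[k]])
  }))
  origin <- rep(seq_len(M), times = p)
  De <- pair_cheb(ext)
  same_origin <- outer(origin, origin, "==")
  bm1 <- sum(De <= r & !same_origin)
  if (bm1 == 0) { out <- NA_real_; attr(out, "undefined") <- "B_m1"; return(out) }
  Bm <- bm / (M * (M - 1))
  Bm1 <- bm1 / (p^2 * M * (M - 1))
  -log(Bm1 / Bm)
}

#' mMSE profile of one p-variate epoch
#'
#' Splits the epoch into `floor(N / segment_length)` disjoint segments,
#' standardizes each segment once (scale 1), then for each scale
#' `s = 1..max_scale` coarse-grains the standardized segment and applies
#' [msampen()] with the fixed `r`. The profile value at each scale is the
#' mean over segments with a defined entropy; per-scale validity counts are
#' recorded. Segments containing a zero-variance channel are excluded.
#'
#' @param x p x N numeric matrix (network signal of one epoch).
#' @param params an [mmse_params()].
#' @param network optional network name carried in the result.
#' @return An object of class `mmse_vector`: list with `values` (length
#'   `max_scale`, NA where undefined everywhere), `n_segments_valid`
#'   (per scale), `segment_values` (segments x scales matrix), `params`,
#'   `network`.
#' @export
mmse_vector <- function(x, params = mmse_params(), network = NA_character_) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  stopifnot(inherits(params, "mmse_params"))
  n <- params$segment_length
  if (ncol(x) < n)
    stop(sprintf("signal length %d shorter than segment_length %d", ncol(x), n))
  nseg <- ncol(x) %/% n
  seg_vals <- matrix(NA_real_, nseg, params$max_scale)
  for (g in seq_len(nseg)) {
    seg <- x[, ((g - 1) * n + 1):(g * n), drop = FALSE]
    seg <- standardize_segment(seg)
    if (length(attr(seg, "degenerate_channels"))) next
    for (s in seq_len(params$max_scale)) {
      cg <- coarse_grain(seg, s)
      seg_vals[g, s] <- msampen(cg, m = params$m, r = params$r,
                                tau = params$tau)
    }
  }
  nv <- colSums(!is.na(seg_vals))
  vals <- ifelse(nv > 0, colMeans(seg_vals, na.rm = TRUE), NA_real_)
  structure(list(values = as.numeric(vals),
                 n_segments_valid = as.integer(nv),
                 segment_values = seg_vals,
                 params = params, network = network),
            class = "mmse_vector")
}

#' @export
print.mmse_vector <- function(x, ...) {
  cat(sprintf("<mmse_vector> network %s, scales 1..%d\n",
              x$network, x$params$max_scale))
  print(round(x$values, 3))
  invisible(x)
}

#' Per-network mMSE vectors for one subject
#'
#' For every channel set of the montage, computes an [mmse_vector()] per
#' epoch and averages the profiles element-wise across epochs (NA-aware);
#' per-epoch vectors are retained for segment-wise reliability analysis.
#' Networks whose electrodes are missing or flagged bad yield a missing
#' entry, recorded in `unavailable`.
#'
#' @param epochs an [epoch_set()].
#' @param montage an `eeg_montage` (default [default_montage()]).
#' @param params an [mmse_params()].
#' @param bad_labels channel labels unavailable in this recording.
#' @return An object of class `subject_mmse`: list with `networks` (named
#'   list of per-network results: `values`, `per_epoch` (epochs x scales),
#'   `n_segments_valid`), `unavailable`, `subject_id`, `group`, `params`.
#' @export
subject_network_mmse <- function(epochs, montage = default_montage(),
                                 params = mmse_params(),
                                 bad_labels = character(0)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!length(epochs$epochs)) stop("no epochs to analyse")
  nets <- list()
  unavailable <- character(0)
  for (cs in montage) {
    if (!network_available(cs, epochs$labels, bad_labels)) {
      unavailable <- c(unavailable, cs$network)
      next
    }
    per_epoch <- t(vapply(epochs$epochs, function(ep) {
      sig <- extract_network_signal(ep, cs, epochs$labels, bad_labels)
      mmse_vector(sig, params, network = cs$network)$values
    }, numeric(params$max_scale)))
    per_epoch <- matrix(per_epoch, ncol = params$max_scale)
    nv <- colSums(!is.na(per_epoch))
    vals <- ifelse(nv > 0, colMeans(per_epoch, na.rm = TRUE), NA_real_)
    nets[[cs$network]] <- list(values = as.numeric(vals),
                               per_epoch = per_epoch,
                               n_epochs_valid = as.integer(nv))
  }
  structure(list(networks = nets, unavailable = unavailable,
                 subject_id = epochs$subject_id, group = epochs$group,
                 params = params),
            class = "subject_mmse")
}
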