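# Shared helpers: small synthetic objects and independent mini-oracles used
# across test files.

# Least-squares log-log periodogram slope over a relative frequency band.
periodogram_slope <- function(x, f_lo = 0.01, f_hi = 0.3) {
  n <- length(x)
  spec <- Mod(fft(x))^2 / n
  f <- (seq_len(n) - 1) / n          # cycles/sample; Nyquist = 0.5
  keep <- f >= f_lo * 0.5 & f <= f_hi * 0.5
  fit <- stats::lm(log(spec[keep]) ~ log(f[keep]))
  unname(stats::coef(fit)[2])
}

# Dominant frequency (cycles/sample) from the periodogram.
periodogram_peak <- function(x) {
  n <- length(x)
  spec <- Mod(fft(x))^2
  half <- 2:(floor(n / 2))
  (half[which.max(spec[half])] - 1) / n
}

# Independent univariate sample entropy (Richman & Moorman convention,
# Chebyshev distance, self-matches excluded), written without reference to
# the package implementation.
sampen_uni <- function(x, m = 2, r = 0.15) {
  N <- length(x)
  count_dim <- function(d) {
    n_vec <- N - m                   # common template count for both dims
    V <- sapply(seq_len(d), function(t) x[(1:n_vec) + t - 1])
    D <- matrix(0, n_vec, n_vec)
    for (cc in seq_len(d)) D <- pmax(D, abs(outer(V[, cc], V[, cc], "-")))
    sum(D <= r) - n_vec
  }
  b <- count_dim(m)
  a <- count_dim(m + 1)
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

# A tiny clean recording: correlated smooth noise, amplitude ~uv_sd.
tiny_recording <- function(n_channels = 4, n_samples = 2560, srate = 256,
                           seed = 1, uv_sd = 15,
                           labels = c("C3", "C4", "T7", "T8", "Cz",
                                      "Fz", "Pz", "O1")[seq_len(n_channels)]) {
  x <- generate_white_noise(n_samples, n_channels, seed)
  recording(x * uv_sd, srate, labels, subject_id = "t1", group = "a")
}

expect_same_recording <- function(a, b, tol = 1e-6) {
  expect_equal(a$labels, b$labels)
  expect_equal(a$srate, b$srate)
  expect_equal(a$data, b$data, tolerance = tol, ignore_attr = TRUE)
}
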