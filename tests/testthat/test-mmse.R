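test_that("coarse-graining averages non-overlapping windows", {
  expect_equal(as.numeric(coarse_grain(c(1, 2, 3, 4, 5, 6), 2)),
               c(1.5, 3.5, 5.5))
  x <- matrix(rnorm(40), 2, 20)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(as.numeric(coarse_grain(c(1, 2, 3, 4, 5), 2)), c(1.5, 3.5))
  expect_error(coarse_grain(1:3, 4), "shorter")
})

test_that("segment standardization is exact and flags degenerate channels", {
  z <- standardize_segment(c(2, 4, 6))
  expect_equal(mean(z), 0)
  expect_equal(sd(as.numeric(z)), 1)
  x <- matrix(rnorm(60), 3, 20)
  z1 <- standardize_segment(x)
  expect_equal(standardize_segment(z1), z1, tolerance = 1e-12,
               ignore_attr = TRUE)
  xc <- rbind(x[1:2, ], 5)
  zc <- standardize_segment(xc)
  expect_equal(attr(zc, "degenerate_channels"), 3L)
  expect_true(all(is.finite(zc)))
})

test_that("constant series has zero entropy and ramps are undefined", {
  const <- matrix(1.3, 2, 40)
  expect_equal(msampen(const, r = 0.2), 0)
  ramp <- matrix(seq(0, 49), 1)
  out <- msampen(ramp, r = 0.15)
  expect_true(is.na(out))
  expect_equal(attr(out, "undefined"), "B_m")
})

test_that("fast kernel equals the brute-force oracle across random instances", {
  set.seed(101)
  for (i in 1:60) {
    p <- sample(1:3, 1)
    N <- sample(40:200, 1)
    m <- sample(1:3, 1)
    tau <- sample(1:2, 1)
    r <- runif(1, 0.2, 0.8)
    x <- matrix(rnorm(p * N), p)
    # strengthen channel correlation on some draws so both regimes occur
    if (p > 1 && i %% 2 == 0) x <- x + matrix(rnorm(N), p, N, byrow = TRUE)
    f <- msampen(x, m = m, r = r, tau = tau)
    b <- msampen_brute(x, m = m, r = r, tau = tau)
    if (is.na(f) || is.na(b)) {
      expect_identical(is.na(f), is.na(b))
    } else {
      expect_equal(f, b, tolerance = 1e-12)
    }
  }
})

test_that("univariate path reproduces classic sample entropy", {
  set.seed(55)
  for (i in 1:10) {
    x <- as.numeric(scale(rnorm(200)))
    expect_equal(msampen(x, m = 2, r = 0.15),
                 sampen_uni(x, m = 2, r = 0.15), tolerance = 1e-12)
  }
})

test_that("msampen is equivariant under channel permutation", {
  set.seed(77)
  x <- matrix(rnorm(3 * 80), 3) + matrix(rnorm(80), 3, 80, byrow = TRUE)
  v <- msampen(x, r = 0.6)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(msampen(x[perm, ], r = 0.6), v, tolerance = 1e-14)
  }
})

test_that("mmse_vector segments, averages and reduces correctly", {
  set.seed(8)
  p <- mmse_params(r = 0.4, max_scale = 1, segment_length = 256)
  x <- matrix(rnorm(2 * 512), 2) + 2 * matrix(rnorm(512), 2, 512, byrow = TRUE)
  v <- mmse_vector(x, p)
  expect_length(v$values, 1)
  # reduction: mean of per-segment scale-1 entropies
  s1 <- standardize_segment(x[, 1:256])
  s2 <- standardize_segment(x[, 257:512])
  expect_equal(v$values, mean(c(msampen(s1, r = 0.4), msampen(s2, r = 0.4))),
               tolerance = 1e-12)
  expect_equal(v$n_segments_valid, 2L)
  expect_error(mmse_vector(x[, 1:100], p), "shorter")
})

test_that("noise-class mMSE signatures hold on mixed 4-channel segments", {
  # white: entropy decays across scales; pink: comparatively flat profile
  prof <- function(w_white, w_pink, seed) {
    spec <- cohort_spec(n_group_a = 1, n_group_b = 0, n_channels = 4,
                        channel_labels = c("C3", "C4", "T7", "T8"),
                        n_epochs = 1,
                        spec_a = noise_mixture_spec(w_white = w_white,
                                                    w_pink = w_pink,
                                                    subject_sd = 0))
    rec <- generate_subject_recording(spec, "a", "s", seed)
    mmse_vector(rec$data)$values
  }
  w <- rowMeans(cbind(prof(1, 0, 301), prof(1, 0, 302)))
  p <- rowMeans(cbind(prof(0, 1, 303), prof(0, 1, 304)))
  expect_true(all(is.finite(w)) && all(is.finite(p)))
  expect_gt(w[1], w[12])
  expect_gt(w[1] - w[12], 0.8)
  expect_lt(abs(p[1] - p[12]), 0.3 * (w[1] - w[12]))
})

test_that("subject-level aggregation over epochs is consistent", {
  set.seed(21)
  x <- matrix(rnorm(4 * 1024), 4) + matrix(rnorm(1024), 4, 1024, byrow = TRUE)
  params <- mmse_params(max_scale = 4, segment_length = 256)
  ep1 <- epoch_set(list(x), 256, c("C3", "C4", "T7", "T8"),
                   subject_id = "s", group = "a")
  ep3 <- epoch_set(list(x, x, x), 256, c("C3", "C4", "T7", "T8"),
                   subject_id = "s", group = "a")
  mont <- structure(list(SMNish = channel_set("SMNish", c("C3", "T8"))),
                    class = "eeg_montage", source = "test")
  s1 <- suppressWarnings(subject_network_mmse(ep1, mont, params))
  s3 <- suppressWarnings(subject_network_mmse(ep3, mont, params))
  expect_equal(s1$networks$SMNish$values, s3$networks$SMNish$values,
               tolerance = 1e-12)
  expect_equal(nrow(s3$networks$SMNish$per_epoch), 3)
})

test_that("unavailable networks are reported, not zero-filled", {
  set.seed(22)
  x <- matrix(rnorm(3 * 512), 3)
  ep <- epoch_set(list(x), 256, c("C3", "C4", "T7"))
  params <- mmse_params(max_scale = 2, segment_length = 256)
  su <- subject_network_mmse(ep, default_montage(), params)
  expect_true("DMN" %in% su$unavailable)
  expect_false("DMN" %in% names(su$networks))
})

test_that("EEG-like band-limited mixtures produce the inverted-U profile", {
  spec <- cohort_spec(n_group_a = 2, n_group_b = 0, n_epochs = 1)
  profs <- sapply(1:2, function(i) {
    rec <- generate_subject_recording(spec, "a", paste0("s", i), 400 + i)
    rec <- filter_band(rec, highpass_hz = 1, lowpass_hz = 40)
    sig <- extract_network_signal(rec$data, default_montage()$SMN, rec$labels)
    mmse_vector(sig)$values
  })
  v <- rowMeans(profs)
  peak <- which.max(v)
  expect_gt(peak, 1)
  expect_lt(peak, 7)
  expect_gt(v[peak], v[1] + 0.3)
  expect_gt(v[peak], v[12])
})
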