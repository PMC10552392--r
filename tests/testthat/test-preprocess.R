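test_that("resampling honors the length contract and spectral content", {
  x <- generate_white_noise(5000, 2, 1) * 10
  rec <- recording(x, 500, c("C3", "C4"))
  out <- resample_recording(rec, 256)
  expect_equal(ncol(out$data), 2560)
  expect_equal(out$srate, 256)

  t <- seq(0, by = 1 / 500, length.out = 5000)
  sine <- recording(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)) * 50,
                    500, c("C3", "C4"))
  res <- resample_recording(sine, 256)
  peak_hz <- periodogram_peak(res$data[1, 400:2100]) * 256
  expect_lt(abs(peak_hz - 10), 0.3)

  expect_identical(resample_recording(rec, 500), rec)
  expect_error(resample_recording(rec, 0), "positive")
  expect_error(resample_recording(rec, 600), "upsampling")
})

test_that("band filters remove DC, stop 60 Hz, pass 10 Hz", {
  n <- 2560
  t <- seq(0, by = 1 / 256, length.out = n)
  const <- recording(matrix(7, 2, n), 256, c("C3", "C4"))
  hp <- filter_band(const, highpass_hz = 1)
  expect_lt(abs(mean(hp$data)), 7 * 1e-6)

  s60 <- recording(rbind(sin(2 * pi * 60 * t), sin(2 * pi * 60 * t)) * 20,
                   256, c("C3", "C4"))
  lp <- filter_band(s60, lowpass_hz = 40)
  mid <- 300:(n - 300)
  atten_db <- 20 * log10(sqrt(mean(lp$data[1, mid]^2)) /
                           sqrt(mean(s60$data[1, mid]^2)))
  expect_lt(atten_db, -20)

  s10 <- recording(rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t)) * 20,
                   256, c("C3", "C4"))
  both <- filter_band(s10, highpass_hz = 1, lowpass_hz = 40)
  ratio <- sqrt(mean(both$data[1, mid]^2)) / sqrt(mean(s10$data[1, mid]^2))
  expect_lt(abs(ratio - 1), 0.05)

  expect_error(filter_band(s10, lowpass_hz = 128), "Nyquist")
})

test_that("bad-channel detection flags by band-limited SD z-scores", {
  # The population z-score of a single outlier is bounded by (n-1)/sqrt(n),
  # so sufficiently many channels are needed for the thresholds to be
  # attainable: >= 8 for z > 2.5 (high band), >= 28 for z > 5 (low band).
  labels40 <- c(montage_electrodes(),
                "Fpz", "FCz", "CPz", "Oz", "AF3", "AF4", "AF7", "AF8",
                "FC1", "FC2", "FC5", "FC6", "CP1", "CP2", "CP5", "CP6",
                "PO3", "PO4", "POz", "TP9", "TP10")
  rec <- tiny_recording(n_channels = 19, n_samples = 5120,
                        labels = montage_electrodes())
  expect_length(detect_bad_channels(rec), 0)

  broad <- rec; broad$data[3, ] <- broad$data[3, ] * 10
  flagged <- detect_bad_channels(broad)
  expect_equal(as.character(flagged), montage_electrodes()[3])

  # slow drift only: flagged by the 0-5 Hz rule, not the 5-40 Hz rule
  drift <- tiny_recording(n_channels = 40, n_samples = 5120,
                          labels = labels40)
  t <- seq(0, by = 1 / 256, length.out = 5120)
  drift$data[5, ] <- drift$data[5, ] + 400 * sin(2 * pi * 0.3 * t)
  f2 <- detect_bad_channels(drift)
  z <- attr(f2, "zscores")
  expect_true(labels40[5] %in% as.character(f2))
  expect_gt(z[labels40[5], "low"], 5)
  expect_lt(z[labels40[5], "high"], 2.5)

  expect_error(
    detect_bad_channels(tiny_recording(n_channels = 3,
                                       labels = c("C3", "C4", "Cz"))),
    ">= 4")
})

test_that("amplitude rejection follows the max-abs rule exactly", {
  x <- matrix(rnorm(2 * 300) * 10, 2)
  eps <- epoch_set(list(x, x * 0 + 500, x * 0 + 400), 256, c("C3", "C4"),
                   starts = c(1L, 301L, 601L))
  kept <- reject_epochs_by_amplitude(eps, 444)
  expect_length(kept$epochs, 2)
  expect_equal(kept$log$index[kept$log$action == "reject_epoch"], 2L)
  expect_equal(kept$starts, c(1L, 601L))
  expect_error(reject_epochs_by_amplitude(eps, -1), "positive")
})

test_that("average reference zeroes columns and is idempotent", {
  rec <- tiny_recording(n_channels = 4)
  rr <- rereference_average(rec)
  expect_lt(max(abs(colMeans(rr$data))), 1e-10)
  expect_equal(rereference_average(rr)$data, rr$data, tolerance = 1e-12)
  anti <- recording(rbind(rnorm(100), 0) , 256, c("C3", "C4"))
  anti$data[2, ] <- -anti$data[1, ]
  expect_equal(rereference_average(anti)$data, anti$data, tolerance = 1e-12)
})

test_that("epoch extraction is disjoint from sample 1, remainder dropped", {
  rec <- tiny_recording(n_channels = 2, n_samples = 25600,
                        labels = c("C3", "C4"))
  es <- extract_epochs(rec, 10240)
  expect_length(es$epochs, 2)
  expect_equal(es$starts, c(1L, 10241L))

  short <- tiny_recording(n_channels = 2, n_samples = 10239,
                          labels = c("C3", "C4"))
  expect_warning(es0 <- extract_epochs(short, 10240), "too short")
  expect_length(es0$epochs, 0)

  three <- tiny_recording(n_channels = 2, n_samples = 30720,
                          labels = c("C3", "C4"))
  es3 <- extract_epochs(three, 10240)
  expect_length(es3$epochs, 3)
  expect_equal(diff(es3$starts), c(10240L, 10240L))
})

clean_subject <- function(seed = 77, n_epochs = 3) {
  spec <- cohort_spec(n_group_a = 1, n_group_b = 0, n_epochs = n_epochs,
                      seed = seed)
  generate_subject_recording(spec, "a", "s1", seed)
}

test_that("full cascade keeps clean data and drops spiked epochs", {
  rec <- clean_subject()
  out <- preprocess_pipeline(rec, rereference = FALSE)
  expect_length(out$epochs, 3)
  expect_equal(sum(out$log$action == "reject_epoch"), 0)

  rec6 <- clean_subject(seed = 78, n_epochs = 6)
  inj <- inject_artifacts(rec6, artifact_spec(spike_amplitude = 500,
                                              spike_count = 3))
  spike_epochs <- unique((inj$log$sample[inj$log$kind == "spike"] - 1) %/%
                           10240 + 1)
  out2 <- preprocess_pipeline(inj$recording, rereference = FALSE)
  rej <- out2$log[out2$log$action == "reject_epoch", ]
  expect_setequal(rej$index[rej$stage == "stage1_444"], spike_epochs)
  expect_length(out2$epochs, 6 - length(spike_epochs))
  # survivors satisfy the final-stage bound
  expect_true(all(vapply(out2$epochs, function(e) max(abs(e)), 1) <= 111))
})

test_that("with infinite thresholds the cascade reduces to filter+segment", {
  rec <- clean_subject(seed = 79)
  loose <- preprocess_config(epoch_reject_uv_stage1 = 1e9,
                             epoch_reject_uv_stage2 = 1e8,
                             epoch_reject_uv_stage3 = 1e7)
  a <- preprocess_pipeline(rec, loose, rereference = TRUE)
  # plain path: high-pass, epochs, low-pass, average reference
  b <- filter_band(rec, highpass_hz = 1)
  b <- extract_epochs(b, 10240)
  lp <- signal::butter(4, 40 / 128, type = "low")
  b$epochs <- lapply(b$epochs, function(e) {
    e <- t(apply(e, 1, function(ch) signal::filtfilt(lp, ch)))
    sweep(e, 2, colMeans(e))
  })
  expect_equal(a$epochs, b$epochs, tolerance = 1e-9)
})

test_that("permuting the rejection stages leaves clean-data output identical", {
  rec <- clean_subject(seed = 80)
  cfg <- preprocess_config()
  ref <- preprocess_pipeline(rec, cfg, rereference = FALSE)
  # permuted thresholds still pass validation reversed via three manual passes
  manual <- filter_band(rec, highpass_hz = 1)
  manual <- extract_epochs(manual, 10240)
  manual <- reject_epochs_by_amplitude(manual, 111, stage = "first")
  lp <- signal::butter(4, 40 / 128, type = "low")
  manual$epochs <- lapply(manual$epochs, function(e)
    t(apply(e, 1, function(ch) signal::filtfilt(lp, ch))))
  manual <- reject_epochs_by_amplitude(manual, 222, stage = "second")
  manual <- reject_epochs_by_amplitude(manual, 444, stage = "third")
  expect_length(manual$epochs, length(ref$epochs))
  expect_equal(manual$epochs, ref$epochs, tolerance = 1e-9)
})

test_that("threshold ordering is validated", {
  expect_error(preprocess_config(epoch_reject_uv_stage1 = 100,
                                 epoch_reject_uv_stage2 = 222),
               "stage1 > stage2 > stage3")
})
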