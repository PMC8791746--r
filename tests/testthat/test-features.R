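test_that("channel selection keeps requested rows in order and rejects references", {
  rec <- make_small_record(n_trials = 2, seed = 3)
  seg <- preprocess_record(rec)[[1]]
  full <- select_channels(seg, eeg_1020_scalp())
  expect_equal(rownames(full$data), eeg_1020_scalp())
  one <- select_channels(seg, "Cz")
  expect_equal(dim(one$data), c(1L, 400L))
  expect_error(select_channels(seg, c("Cz", "XX")), "unknown channel")
  expect_error(feature_config(channels = c(eeg_1020_scalp(), "A1")),
               "reference")
  expect_silent(feature_config(channels = c("Cz", "A1"),
                               allow_reference_channels = TRUE))
})

test_that("time-window selection picks the configured interval", {
  x <- matrix(seq_len(400 * 2), nrow = 2, byrow = TRUE)
  win <- select_time_window(x, 1, 2.5, 100)
  expect_equal(dim(win), c(2L, 250L))
  expect_equal(win[1, 1], 101)       # starts at sample round(t_w * fs)
  expect_equal(select_time_window(x, 0, 4, 100), x)
  expect_error(select_time_window(x, 4, 0.5, 100), "exceeds")
  expect_error(select_time_window(x, 0, 0.001, 100), "too short")
})

test_that("magnitude spectra match a brute-force DFT and locate pure tones", {
  fs <- 100
  t <- (0:249) / fs
  x <- sin(2 * pi * 10 * t)
  sp <- magnitude_spectrum(x, fs)
  expect_equal(sp$magnitude, dft_magnitude(x), tolerance = 1e-8)
  expect_equal(sp$freq_hz[which.max(sp$magnitude)], 10)
  expect_equal(sp$freq_hz[2] - sp$freq_hz[1], 0.4)   # 1/Ts for Ts = 2.5 s
  z <- magnitude_spectrum(rep(0, 250), fs)
  expect_equal(z$magnitude, rep(0, 126))
  two <- 2 * sin(2 * pi * 8 * t) + 1 * sin(2 * pi * 20 * t)
  spt <- magnitude_spectrum(two, fs)
  i8 <- which.min(abs(spt$freq_hz - 8)); i20 <- which.min(abs(spt$freq_hz - 20))
  expect_equal(spt$magnitude[i8] / spt$magnitude[i20], 2, tolerance = 0.05)
  expect_error(magnitude_spectrum(1, fs), "at least 2")
})

test_that("1 Hz resampling reduces any native grid to integer frequencies", {
  # native bins already at integers: identity on 0..32
  sp1 <- magnitude_spectrum(sin(2 * pi * 10 * (0:99) / 100), 100)
  r1 <- resample_to_1hz(sp1$freq_hz, sp1$magnitude)
  expect_length(r1, 33)
  expect_equal(r1, sp1$magnitude[1:33])
  # flat spectrum stays flat
  expect_equal(resample_to_1hz(seq(0, 50, by = 0.4), rep(1, 126)), rep(1, 33))
  # 0.4 Hz grid: mean of native bins centred in [f - 0.5, f + 0.5)
  freq <- seq(0, 50, by = 0.4)
  mag <- runif(length(freq))
  got <- resample_to_1hz(freq, mag)
  want <- sapply(0:32, function(f)
    mean(mag[freq >= f - 0.5 & freq < f + 0.5]))
  expect_equal(got, want)
  # a 10 Hz tone at Ts = 2.5 resamples to a peak at index 10
  x <- sin(2 * pi * 10 * (0:249) / 100)
  sp <- magnitude_spectrum(x, 100)
  rs <- resample_to_1hz(sp$freq_hz, sp$magnitude)
  expect_equal(which.max(rs) - 1, 10)
  expect_error(resample_to_1hz(seq(0, 50, by = 2), rep(1, 26)), "coarser")
})

test_that("per-channel normalization divides by the maximum and selects the band", {
  cfg <- feature_config()
  vals <- c(2, 4, 8, 6, rep(0, 29))
  norm <- normalize_and_band_select(c(2, 4, 8, 6, rep(0, 29)),
                                    feature_config(freq_lo_hz = 0,
                                                   freq_hi_hz = 32,
                                                   exclude_dc = FALSE))
  expect_equal(norm[1:4], c(0.25, 0.5, 1, 0.75))
  expect_equal(normalize_and_band_select(rep(0, 33), cfg), rep(0, 31))
  out <- normalize_and_band_select(seq(0, 32), cfg)
  expect_length(out, 31)                      # 1..31 Hz after dropping DC
  expect_true(all(out >= 0 & out <= 1))
  expect_error(feature_config(freq_lo_hz = 0), "conflicts")
})

test_that("feature vectors have length Nch x Nf and stay in [0, 1]", {
  rec <- make_small_record(n_trials = 2, seed = 5)
  segs <- preprocess_record(rec)
  fv <- build_feature_vector(segs[[1]])
  expect_length(fv$values, 19 * 31)           # 589
  expect_true(all(fv$values >= 0 & fv$values <= 1))
  one <- build_feature_vector(segs[[1]], feature_config(channels = "Pz"))
  expect_length(one$values, 31)
  expect_equal(one$values, fv$values[(which(eeg_1020_scalp() == "Pz") - 1) * 31 + 1:31])
})

test_that("features are invariant to overall signal amplitude", {
  rec <- make_small_record(n_trials = 2, seed = 6)
  seg <- preprocess_record(rec)[[2]]
  base <- build_feature_vector(seg)$values
  for (c in c(0.01, 3.7, 1000)) {
    scaled <- seg
    scaled$data <- seg$data * c
    expect_equal(build_feature_vector(scaled)$values, base, tolerance = 1e-10)
  }
})

test_that("feature length does not depend on sampling rate or window duration", {
  rec <- make_small_record(n_trials = 2, seed = 7)
  seg100 <- preprocess_record(rec)[[1]]
  seg250 <- preprocess_record(rec, preprocess_config(downsample_factor = 2L))[[1]]
  f_a <- build_feature_vector(seg100)
  f_b <- build_feature_vector(seg250)
  f_c <- build_feature_vector(seg100, feature_config(t_w_s = 0.5, t_s_s = 3))
  expect_length(f_b$values, length(f_a$values))
  expect_length(f_c$values, length(f_a$values))
})

test_that("identical channels produce identical feature blocks", {
  seg <- preprocess_record(make_small_record(n_trials = 1, seed = 8))[[1]]
  seg$data["Fp2", ] <- seg$data["Fp1", ]
  fv <- build_feature_vector(seg)
  expect_equal(fv$values[1:31], fv$values[32:62])
})

test_that("feature databases carry labelled columns and metadata", {
  rec <- make_small_record(words = c(3, 6), n_trials = 2, seed = 9,
                           record_id = 2)
  db <- featurize_segments(preprocess_record(rec))
  expect_equal(dim(db$features), c(6L, 589L))
  expect_equal(colnames(db$features)[1], "Fp1_1Hz")
  expect_equal(colnames(db$features)[32], "Fp2_1Hz")
  expect_setequal(unique(db$meta$class_code), c(32, 62, 72))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(db, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 6)
  expect_equal(df$Cz_10Hz, unname(db$features[, "Cz_10Hz"]))
})
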