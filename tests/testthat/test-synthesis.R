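test_that("synthesized records have the acquisition geometry", {
  rec <- make_small_record(n_trials = 2)
  expect_equal(nrow(rec$data), 21)  # 19 scalp + 2 sync rows
  expect_equal(rownames(rec$data)[1:19], eeg_1020_scalp())
  expect_equal(rec$fs_hz, 500)
  expect_equal(nrow(rec$sync_events), 6)
  expect_gte(ncol(rec$data), 6 * 4 * 500)
  # every onset leaves room for a full instance
  expect_true(all(rec$sync_events$onset_sample + 2000 - 1 <= ncol(rec$data)))
})

test_that("sync rows encode the schedule losslessly", {
  rec <- make_small_record(n_trials = 3, seed = 7)
  dec <- decode_sync_events(rec)
  expect_equal(dec$class_code, as.integer(rec$sync_events$class_code))
  expect_equal(dec$onset_sample, as.integer(rec$sync_events$onset_sample))
})

test_that("a noise-free single-peak signature puts its FFT peak at the stated frequency", {
  sigs <- list("1" = class_signature(1, 10, 1, noise_amplitude = 0),
               "7" = class_signature(7, numeric(0), numeric(0), noise_amplitude = 0))
  sch <- generate_schedule(c(1, 7), 2, seed = 3)
  rec <- synthesize_record(sch, sigs, acquisition_config(), seed = 4)
  k <- which(rec$sync_events$class_code == 1)[1]
  on <- rec$sync_events$onset_sample[k]
  win <- rec$data["Cz", on:(on + 511)]
  mag <- dft_magnitude(win)
  freq <- (seq_along(mag) - 1) * 500 / 512
  expect_equal(freq[which.max(mag)], 10, tolerance = 0.5)
  # silence instances carry no deterministic signal at zero noise
  on_s <- rec$sync_events$onset_sample[rec$sync_events$class_code == 7][1]
  expect_equal(max(abs(rec$data["Cz", on_s:(on_s + 1999)])), 0)
})

test_that("per-channel spectra agree with the DFT oracle on short windows", {
  rec <- make_small_record(n_trials = 1, seed = 12)
  win <- rec$data["F3", 1:256]
  sp <- magnitude_spectrum(win, 500)
  expect_equal(sp$magnitude, dft_magnitude(win), tolerance = 1e-8)
})

test_that("records are bit-identical under a fixed seed", {
  a <- make_small_record(n_trials = 2, seed = 5)
  b <- make_small_record(n_trials = 2, seed = 5)
  expect_identical(a$data, b$data)
})

test_that("spectral drift grows with record distance", {
  sigs <- list("1" = class_signature(1, 10, 1, noise_amplitude = 0,
                                     drift_per_record = 0.5),
               "7" = class_signature(7, numeric(0), numeric(0),
                                     noise_amplitude = 0))
  sch <- generate_schedule(c(1, 7), 1, seed = 3)
  spec_of <- function(rid) {
    rec <- synthesize_record(sch, sigs, acquisition_config(),
                             record_id = rid, seed = 4)
    on <- rec$sync_events$onset_sample[rec$sync_events$class_code == 1][1]
    sp <- magnitude_spectrum(rec$data["Cz", on:(on + 1999)], 500)
    resample_to_1hz(sp$freq_hz, sp$magnitude)
  }
  s0 <- spec_of(0)
  d3 <- sqrt(sum((spec_of(3) - s0)^2))
  d6 <- sqrt(sum((spec_of(6) - s0)^2))
  expect_gt(d3, 0)
  expect_gt(d6, d3)
})

test_that("artifact injection scales exactly one instance's energy by gain squared", {
  rec <- make_small_record(n_trials = 3, seed = 21)
  inst_energy <- function(r, k) {
    on <- r$sync_events$onset_sample[k]
    mean(r$data[1:19, on:(on + 1999)]^2)
  }
  before <- vapply(1:9, inst_energy, numeric(1), r = rec)
  hit <- inject_artifact(rec, 3, 10)
  after <- vapply(1:9, inst_energy, numeric(1), r = hit)
  expect_equal(after[3], 100 * before[3])
  expect_equal(after[-3], before[-3])
  expect_identical(inject_artifact(rec, 2, 1)$data, rec$data)
  low <- inject_artifact(rec, 5, 0.05)
  expect_equal(inst_energy(low, 5), 0.0025 * before[5])
  expect_error(inject_artifact(rec, 99, 2), "out of range")
  expect_error(inject_artifact(rec, 1, 0), "energy_gain")
})

test_that("a reduced subject dataset follows the session/part/test design", {
  cfg <- acquisition_config(n_trials = 2L)
  recs <- generate_subject_dataset(cfg, seed = 9)
  expect_length(recs, 30)  # 5 sessions x 2 parts x 3 tests
  ids <- vapply(recs, `[[`, integer(1), "record_id")
  expect_setequal(unique(ids), 0:9)
  all_events <- do.call(rbind, lapply(recs, function(r)
    cbind(r$sync_events, record_id = r$record_id)))
  counts <- table(all_events$class_code)
  # each word: n_sessions * n_parts * n_trials instances; silence 3x that
  expect_true(all(counts[as.character(1:6)] == 5 * 2 * 2))
  expect_equal(unname(counts["7"]), 3 * 5 * 2 * 2)
  # each word present in exactly 10 records, silence in all 30
  per_word_records <- tapply(all_events$record_id, all_events$class_code,
                             function(r) length(unique(r)))
  expect_true(all(per_word_records[as.character(1:6)] == 10))
  by_rec <- split(all_events$class_code, all_events$record_id)
  expect_true(all(vapply(by_rec, function(x) 7 %in% x, logical(1))))
})

test_that("subject dataset rejects malformed word pairings", {
  cfg <- acquisition_config(n_trials = 1L)
  expect_error(generate_subject_dataset(cfg, word_pairs = list(c(1, 2), c(3, 4))),
               "one word pair per test")
  expect_error(generate_subject_dataset(
    cfg, word_pairs = list(c(1, 2), c(3, 4), c(4, 5))), "distinct")
  expect_error(generate_subject_dataset(
    cfg, word_pairs = list(c(1, 2), c(3, 7), c(5, 6))), "silence")
})

test_that("missing signatures are refused", {
  sch <- generate_schedule(c(1, 2, 7), 1, seed = 1)
  sigs <- default_signatures()
  sigs[["2"]] <- NULL
  expect_error(synthesize_record(sch, sigs, acquisition_config()),
               "missing signature")
})
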