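#' Spectral signature of a synthetic EEG class
#'
#' A synthetic class is rendered, within each instance window, as 1/f^alpha
#' Gaussian background noise plus a set of band-limited sinusoidal peaks.
#' Record-to-record nonstationarity ("drift") is modelled as a systematic
#' shift of the peak frequencies by `drift_per_record` Hz per unit of record
#' id, optionally accompanied by a relative amplitude change of
#' `drift_amp_per_record` per record, so instances of the same class
#' recorded in different parts have systematically different spectra.
#'
#' @param class_code Integer class code the signature belongs to.
#' @param peak_freqs_hz Peak frequencies in Hz, each within 1-31 Hz; empty
#'   for a background-only class such as Silence. Keep
#'   `max(peak_freqs_hz) + 9 * drift_per_record` below 32 Hz so drifted
#'   peaks survive the low-pass filter.
#' @param peak_amplitudes Peak amplitudes (same units as the noise), one per
#'   frequency, all non-negative.
#' @param background_exponent Exponent alpha of the 1/f^alpha background.
#' @param noise_amplitude RMS amplitude of the background noise; 0 gives a
#'   noise-free deterministic signal.
#' @param drift_per_record Frequency drift in Hz per unit record id; 0 for
#'   stationary classes.
#' @param drift_amp_per_record Relative peak-amplitude change per unit
#'   record id (record r scales peaks by `1 + drift_amp_per_record * r`).
#'
#' @return An object of class `class_signature`.
#' @export
class_signature <- function(class_code, peak_freqs_hz, peak_amplitudes,
                            background_exponent = 1, noise_amplitude = 1,
                            drift_per_record = 0, drift_amp_per_record = 0) {
  stopifnot(length(peak_freqs_hz) == length(peak_amplitudes),
            noise_amplitude >= 0, background_exponent >= 0)
  if (length(peak_freqs_hz) &&
      (any(peak_freqs_hz < 1) || any(peak_freqs_hz > 31)))
    stop("peak frequencies must lie within 1-31 Hz")
  if (length(peak_amplitudes) && any(peak_amplitudes < 0))
    stop("peak amplitudes must be non-negative")
  structure(
    list(class_code = as.integer(class_code),
         peak_freqs_hz = peak_freqs_hz,
         peak_amplitudes = peak_amplitudes,
         background_exponent = background_exponent,
         noise_amplitude = noise_amplitude,
         drift_per_record = drift_per_record,
         drift_amp_per_record = drift_amp_per_record),
    class = "class_signature")
}

#' Default signatures for the six-word + Silence class set
#'
#' Assigns each word two disjoint spectral peaks (one low, one high band)
#' and makes Silence background-only, emulating the rest state. Peak
#' amplitudes are kept small relative to the background (under 10% of total
#' power) so word and Silence instances have comparable energy, as in real
#' EEG where class-specific rhythms are a small fraction of total power;
#' this also keeps energy-based artifact rejection class-neutral.
#'
#' @param word_codes Codes of the word classes.
#' @param silence_code Code of the Silence class.
#' @param noise_amplitude,drift_per_record,drift_amp_per_record,background_exponent
#'   Passed to [class_signature()] for every class.
#' @return Named list of `class_signature` objects keyed by class code.
#' @export
default_signatures <- function(word_codes = 1:6, silence_code = 7,
                               noise_amplitude = 1, drift_per_record = 0,
                               drift_amp_per_record = 0,
                               background_exponent = 1) {
  sigs <- list()
  for (i in seq_along(word_codes)) {
    sigs[[as.character(word_codes[i])]] <- class_signature(
      class_code = word_codes[i],
      peak_freqs_hz = c(4 + 2 * i, 16 + 2 * i),
      peak_amplitudes = c(0.3, 0.25),
      background_exponent = background_exponent,
      noise_amplitude = noise_amplitude,
      drift_per_record = drift_per_record,
      drift_amp_per_record = drift_amp_per_record)
  }
  sigs[[as.character(silence_code)]] <- class_signature(
    class_code = silence_code,
    peak_freqs_hz = numeric(0), peak_amplitudes = numeric(0),
    background_exponent = background_exponent,
    noise_amplitude = noise_amplitude,
    drift_per_record = drift_per_record)
  sigs
}

# 1/f^alpha Gaussian noise of length n, unit RMS, zero-mean.
# Spectral shaping of white noise in the frequency domain; DC is zeroed.
noise_1f <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  if (alpha == 0) return(w)
  W <- stats::fft(w)
  i <- seq_len(n) - 1
  fidx <- pmin(i, n - i)               # symmetric frequency index
  scale <- ifelse(fidx == 0, 0, fidx^(-alpha / 2))
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Synthesize one multichannel EEG record
#'
#' Renders a test schedule into a continuous multichannel recording: for
#' every scheduled instance, each of the 19 scalp rows receives that class's
#' background noise plus its (drifted) sinusoidal peaks with independent
#' random phases. Two synchronization rows encode the schedule losslessly:
#' `SYNC_TYPE` holds the class code as a constant level for the duration of
#' the instance, and `SYNC_ONSET` carries a short unit pulse at each onset.
#'
#' @param schedule A `test_schedule` from [generate_schedule()].
#' @param signatures Named list of `class_signature`s keyed by class code;
#'   every class in the schedule must be present.
#' @param cfg An [acquisition_config()].
#' @param record_id Part number 0-9; scales the per-record drift.
#' @param subject_id,session,part,test_index Metadata carried on the record.
#' @param record_drift Record-level nonstationarity common to all classes:
#'   the background spectral exponent of every instance in this record is
#'   increased by `record_drift * record_id`. This models the
#'   session-to-session changes (electrode placement, impedance, vigilance)
#'   that give each recording part a spectral fingerprint shared by its
#'   classes, on top of the class-specific `drift_per_record` in the
#'   signatures.
#' @param seed Optional integer seed.
#'
#' @return An `eeg_record`: list with `data` (21 x n_samples matrix in uV:
#'   19 scalp rows + 2 sync rows), `fs_hz`, `sync_events` (data.frame of
#'   `class_code`, `onset_sample`), `channel_names` and the metadata fields.
#' @export
synthesize_record <- function(schedule, signatures, cfg = acquisition_config(),
                              record_id = 0L, subject_id = 1L, session = NA_integer_,
                              part = NA_integer_, test_index = 1L,
                              record_drift = 0, seed = NULL) {
  stopifnot(inherits(schedule, "test_schedule"))
  if (record_id < 0 || record_id > 9) stop("record_id must be in 0..9")
  entries <- schedule$entries
  need <- unique(entries$class_code)
  have <- names(signatures)
  if (!all(as.character(need) %in% have))
    stop("missing signature for class(es): ",
         paste(setdiff(as.character(need), have), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  fs <- cfg$fs_hz
  wlen <- round(cfg$instance_time_s * fs)
  n_samples <- max(entries$onset_sample) + wlen - 1L
  n_scalp <- length(eeg_1020_scalp())
  data <- matrix(0, nrow = n_scalp + 2L, ncol = n_samples)
  rownames(data) <- c(eeg_1020_scalp(), sync_row_names())
  tt <- (seq_len(wlen) - 1) / fs
  pulse_len <- min(wlen, max(1L, round(0.05 * fs)))

  for (k in seq_len(nrow(entries))) {
    code <- entries$class_code[k]
    on <- entries$onset_sample[k]
    idx <- on:(on + wlen - 1L)
    sig <- signatures[[as.character(code)]]
    amp_scale <- 1 + sig$drift_amp_per_record * record_id
    f_shift <- sig$drift_per_record * record_id
    alpha <- sig$background_exponent + record_drift * record_id
    for (ch in seq_len(n_scalp)) {
      x <- if (sig$noise_amplitude > 0)
        sig$noise_amplitude * noise_1f(wlen, alpha)
      else rep(0, wlen)
      for (p in seq_along(sig$peak_freqs_hz)) {
        x <- x + sig$peak_amplitudes[p] * amp_scale *
          sin(2 * pi * (sig$peak_freqs_hz[p] + f_shift) * tt +
                stats::runif(1, 0, 2 * pi))
      }
      data[ch, idx] <- x
    }
    data[n_scalp + 1L, idx] <- code
    data[n_scalp + 2L, on:(on + pulse_len - 1L)] <- 1
  }

  structure(
    list(subject_id = subject_id, session = session, part = part,
         test_index = test_index, record_id = as.integer(record_id),
         data = data, fs_hz = fs,
         sync_events = entries[, c("class_code", "onset_sample")],
         channel_names = rownames(data)),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf(
    "EEG record: subject %s, record %d (session %s, part %s, test %s)\n",
    x$subject_id, x$record_id, x$session, x$part, x$test_index))
  cat(sprintf("  %d channels x %d samples @ %g Hz; %d sync events\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$sync_events)))
  invisible(x)
}

#' Recover sync events from the sync rows
#'
#' Decodes the schedule back out of the `SYNC_TYPE`/`SYNC_ONSET` rows,
#' independent of the `sync_events` metadata. Useful to verify that the sync
#' encoding is lossless, and as the segmentation source for records whose
#' metadata was stripped.
#'
#' @param record An `eeg_record`.
#' @return data.frame with `class_code` and `onset_sample`.
#' @export
decode_sync_events <- function(record) {
  stopifnot(inherits(record, "eeg_record"))
  onset_row <- record$data["SYNC_ONSET", ]
  type_row <- record$data["SYNC_TYPE", ]
  rising <- which(diff(c(0, onset_row)) > 0.5)
  data.frame(class_code = as.integer(round(type_row[rising])),
             onset_sample = as.integer(rising))
}

#' Generate a complete synthetic dataset for one subject
#'
#' Emulates the full acquisition design: `n_sessions` sessions of
#' `n_parts_per_session` parts, each part recording one test per word pair
#' (every test = the pair plus Silence, `n_trials` trials). Record ids run
#' chronologically from 0 (first part of first session) upward, and the
#' per-record drift in `signatures` makes later records drift away from
#' earlier ones. Under the default design this yields 30 records in which
#' each word appears in 10 records (200 instances) and Silence in all 30
#' (600 instances).
#'
#' @param cfg An [acquisition_config()].
#' @param word_pairs List of 3 disjoint pairs of word codes, one pair per
#'   test; their union must be exactly 6 distinct codes.
#' @param silence_code Code of the Silence class, present in every test.
#' @param signatures Named list of `class_signature`s for all 7 classes;
#'   defaults to [default_signatures()] over the given codes.
#' @param seed Optional integer master seed; per-record seeds are derived
#'   from it so the whole dataset is reproducible.
#' @param subject_id Subject identifier carried on every record.
#' @param record_drift Record-level spectral-exponent drift passed to
#'   [synthesize_record()].
#'
#' @return List of `eeg_record`s, one per (session, part, test).
#' @export
generate_subject_dataset <- function(cfg = acquisition_config(),
                                     word_pairs = list(c(1, 5), c(3, 6), c(2, 4)),
                                     silence_code = 7L,
                                     signatures = NULL,
                                     seed = NULL,
                                     subject_id = 1L,
                                     record_drift = 0) {
  words <- unlist(word_pairs)
  if (length(word_pairs) != cfg$n_tests_per_part)
    stop("need one word pair per test (", cfg$n_tests_per_part, ")")
  if (length(words) != 6 || anyDuplicated(words))
    stop("word_pairs must cover exactly 6 distinct word codes")
  if (silence_code %in% words)
    stop("silence_code must not appear among the word codes")
  if (is.null(signatures))
    signatures <- default_signatures(word_codes = words,
                                     silence_code = silence_code)
  n_rec <- cfg$n_sessions * cfg$n_parts_per_session * cfg$n_tests_per_part
  seeds <- derive_seeds(seed, 2L * n_rec)
  records <- vector("list", n_rec)
  r <- 0L
  for (session in seq_len(cfg$n_sessions)) {
    for (part in seq_len(cfg$n_parts_per_session)) {
      record_id <- (session - 1L) * cfg$n_parts_per_session + part - 1L
      for (test_index in seq_len(cfg$n_tests_per_part)) {
        r <- r + 1L
        word_set <- c(word_pairs[[test_index]], silence_code)
        sch <- generate_schedule(word_set, cfg$n_trials,
                                 ti_s = cfg$instance_time_s,
                                 fs_hz = cfg$fs_hz,
                                 seed = seeds[2L * r - 1L])
        records[[r]] <- synthesize_record(
          sch, signatures, cfg, record_id = record_id,
          subject_id = subject_id, session = session, part = part,
          test_index = test_index, record_drift = record_drift,
          seed = seeds[2L * r])
      }
    }
  }
  records
}

#' Inject an energy artifact into one instance
#'
#' Scales the scalp-channel samples of the given instance by `energy_gain`,
#' changing its mean energy by `energy_gain^2` and leaving every other
#' instance untouched. Models occasional high-energy (movement) or
#' low-energy (electrode dropout) artifacts for exercising energy-based
#' rejection.
#'
#' @param record An `eeg_record`.
#' @param instance_index 1-based index into the record's sync events.
#' @param energy_gain Positive amplitude scale factor.
#' @return The modified `eeg_record`.
#' @export
inject_artifact <- function(record, instance_index, energy_gain) {
  stopifnot(inherits(record, "eeg_record"))
  if (energy_gain <= 0) stop("energy_gain must be > 0")
  n_ev <- nrow(record$sync_events)
  if (instance_index < 1 || instance_index > n_ev)
    stop("instance_index out of range 1..", n_ev)
  on <- record$sync_events$onset_sample[instance_index]
  wlen <- if (n_ev > 1)
    diff(record$sync_events$onset_sample[1:2])
  else ncol(record$data) - on + 1L
  idx <- on:min(on + wlen - 1L, ncol(record$data))
  scalp <- seq_along(eeg_1020_scalp())
  record$data[scalp, idx] <- record$data[scalp, idx] * energy_gain
  record
}

#' Label-independent feature vectors
#'
#' Draws feature vectors uniformly on \[0,1\] independently of the class
#' labels, mimicking the range and length of the pipeline's normalized
#' spectral features (default length 19 channels x 31 frequencies). Used to
#' measure the chance level of a classifier: on such data the expected
#' accuracy is (1 - u)/n for n balanced classes, where u is the classifier's
#' rate of undecidable (Unknown) votes. u shrinks with feature dimension:
#' vote cycles between three or more classes become rarer as the pairwise
#' hyperplanes decorrelate.
#'
#' @param n_per_class Instances per class.
#' @param classes Class codes.
#' @param n_features Feature vector length.
#' @param seed Optional integer seed.
#' @return List with `features` (matrix) and `labels` (integer vector).
#' @export
simulate_null_features <- function(n_per_class, classes, n_features = 589,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_per_class * length(classes)
  list(features = matrix(stats::runif(n * n_features), nrow = n),
       labels = rep(as.integer(classes), each = n_per_class))
}
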