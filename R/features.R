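#' Feature extraction configuration
#'
#' Controls the spectral feature chain: channel selection, the processed
#' time window inside each instance, the magnitude FFT, 1 Hz resampling and
#' frequency-band selection. Defaults reproduce the reference parameters:
#' all 19 scalp channels, a 2.5 s window starting 1 s into the instance
#' (skipping stimulus playback and rest), DC excluded, 1-31 Hz retained.
#'
#' @param channels Channel names used, in feature order. The earlobe
#'   references A1/A2 are not scalp EEG and are refused unless
#'   `allow_reference_channels = TRUE`.
#' @param t_w_s Wait time Tw in seconds before the processed window; must
#'   cover stimulus excitation plus rest.
#' @param t_s_s Processed window duration Ts in seconds.
#' @param freq_lo_hz,freq_hi_hz Retained frequency band (integer Hz) after
#'   1 Hz resampling.
#' @param exclude_dc Drop the 0 Hz value before band selection.
#' @param resample_method `"bin_mean"` averages native FFT bins whose
#'   centers fall in each 1 Hz-wide band (robust to leakage);
#'   `"interp"` linearly interpolates the native spectrum at integer
#'   frequencies.
#' @param allow_reference_channels Permit A1/A2 in `channels`.
#'
#' @return Object of class `feature_config`.
#' @export
feature_config <- function(channels = eeg_1020_scalp(),
                           t_w_s = 1,
                           t_s_s = 2.5,
                           freq_lo_hz = 1L,
                           freq_hi_hz = 31L,
                           exclude_dc = TRUE,
                           resample_method = c("bin_mean", "interp"),
                           allow_reference_channels = FALSE) {
  resample_method <- match.arg(resample_method)
  stopifnot(t_w_s >= 0, t_s_s > 0,
            freq_lo_hz >= 0, freq_hi_hz >= freq_lo_hz, freq_hi_hz <= 32)
  if (!allow_reference_channels && any(channels %in% c("A1", "A2")))
    stop("A1/A2 are reference electrodes, not scalp EEG; ",
         "set allow_reference_channels = TRUE to override")
  if (exclude_dc && freq_lo_hz == 0)
    stop("freq_lo_hz = 0 conflicts with exclude_dc = TRUE")
  structure(
    list(channels = channels, t_w_s = t_w_s, t_s_s = t_s_s,
         freq_lo_hz = as.integer(freq_lo_hz),
         freq_hi_hz = as.integer(freq_hi_hz),
         exclude_dc = exclude_dc,
         resample_method = resample_method),
    class = "feature_config")
}

#' Number of frequency values per channel under a configuration
#' @param cfg A [feature_config()].
#' @return Integer Nf.
#' @export
n_freqs <- function(cfg) cfg$freq_hi_hz - cfg$freq_lo_hz + 1L

#' Select and order channels of a segment
#'
#' @param segment An `instance_segment`.
#' @param channels Channel names to keep, in the desired row order.
#' @return The segment with `data` restricted and reordered.
#' @export
select_channels <- function(segment, channels) {
  unknown <- setdiff(channels, rownames(segment$data))
  if (length(unknown))
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  segment$data <- segment$data[channels, , drop = FALSE]
  segment
}

#' Extract the processed time window
#'
#' Keeps `round(t_s_s * fs)` samples per channel starting `round(t_w_s * fs)`
#' samples into the segment, discarding the initial stimulus/rest interval.
#'
#' @param x Channels-by-samples matrix.
#' @param t_w_s Wait time in seconds.
#' @param t_s_s Window duration in seconds.
#' @param fs_hz Sampling rate in Hz.
#' @return Matrix of the windowed samples.
#' @export
select_time_window <- function(x, t_w_s, t_s_s, fs_hz) {
  start <- round(t_w_s * fs_hz)
  len <- round(t_s_s * fs_hz)
  if (len < 1) stop("window duration too short")
  if (start + len > ncol(x))
    stop(sprintf("window [%d, %d) exceeds segment length %d",
                 start, start + len, ncol(x)))
  x[, (start + 1L):(start + len), drop = FALSE]
}

#' One-sided magnitude spectrum
#'
#' Absolute value of the FFT of a single-channel sample series, one-sided,
#' at the native resolution `fs / N` Hz (equivalently `1/Ts`). No taper is
#' applied (rectangular window).
#'
#' @param x Numeric vector of samples.
#' @param fs_hz Sampling rate in Hz.
#' @return List with `freq_hz` and `magnitude`, both of length
#'   `floor(N/2) + 1`.
#' @export
magnitude_spectrum <- function(x, fs_hz) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples")
  n_keep <- n %/% 2 + 1L
  list(freq_hz = (seq_len(n_keep) - 1) * fs_hz / n,
       magnitude = Mod(stats::fft(x))[seq_len(n_keep)])
}

#' Resample a magnitude spectrum to 1 Hz resolution
#'
#' Normalizes the feature length against sampling rate and window duration
#' by reducing the native `1/Ts` Hz grid to integer frequencies 0..`f_max`.
#' The default method averages the native magnitudes whose bin centers fall
#' in `[f - 0.5, f + 0.5)`; `"interp"` linearly interpolates instead.
#'
#' @param freq_hz Native frequency axis (ascending, uniform).
#' @param magnitude Native magnitudes.
#' @param f_max Highest integer frequency retained (values above carry no
#'   energy after a 32 Hz low-pass).
#' @param method `"bin_mean"` or `"interp"`.
#' @return Numeric vector of `f_max + 1` values at 0..`f_max` Hz.
#' @export
resample_to_1hz <- function(freq_hz, magnitude, f_max = 32L,
                            method = c("bin_mean", "interp")) {
  method <- match.arg(method)
  res <- freq_hz[2] - freq_hz[1]
  if (res > 1 + 1e-9)
    stop("native resolution ", signif(res, 4),
         " Hz is coarser than 1 Hz; cannot resample")
  f_int <- 0:f_max
  if (method == "interp")
    return(stats::approx(freq_hz, magnitude, xout = f_int, rule = 2)$y)
  out <- numeric(f_max + 1L)
  band <- findInterval(freq_hz, f_int - 0.5)   # 1-based band index
  band[freq_hz >= f_max + 0.5] <- 0L           # beyond the last band
  for (i in seq_along(f_int)) {
    in_band <- band == i
    out[i] <- if (any(in_band)) mean(magnitude[in_band])
    else stats::approx(freq_hz, magnitude, xout = f_int[i], rule = 2)$y
  }
  out
}

#' Normalize a per-channel spectrum and select the frequency band
#'
#' Divides the 1 Hz-resampled values by their maximum (an all-zero channel
#' passes through unchanged), then drops DC if configured and keeps
#' `[freq_lo_hz, freq_hi_hz]`. Output values always lie in \[0, 1\], and the
#' normalization makes features invariant to overall signal amplitude.
#'
#' @param values Vector of magnitudes on the 0..32 Hz integer grid.
#' @param cfg A [feature_config()].
#' @return Numeric vector of `n_freqs(cfg)` values.
#' @export
normalize_and_band_select <- function(values, cfg = feature_config()) {
  m <- max(values)
  if (m > 0) values <- values / m
  keep <- cfg$freq_lo_hz:cfg$freq_hi_hz
  values[keep + 1L]           # grid is 0-based, R indexing 1-based
}

#' Build the feature vector of one instance
#'
#' Full per-instance chain: channel selection, time-window selection,
#' magnitude FFT per channel, 1 Hz resampling, per-channel max
#' normalization, band selection, and concatenation of the channel blocks
#' in configuration order. The result has length `Nch * Nf` regardless of
#' sampling rate or window duration.
#'
#' @param segment An `instance_segment`.
#' @param cfg A [feature_config()].
#' @return A `feature_vector`: list with `values`, `class_code`,
#'   `word_code`, `record_id`, `subject_id`, `n_channels`, `n_freqs`.
#' @export
build_feature_vector <- function(segment, cfg = feature_config()) {
  seg <- select_channels(segment, cfg$channels)
  win <- select_time_window(seg$data, cfg$t_w_s, cfg$t_s_s, seg$fs_hz)
  blocks <- lapply(seq_len(nrow(win)), function(ch) {
    sp <- magnitude_spectrum(win[ch, ], seg$fs_hz)
    rs <- resample_to_1hz(sp$freq_hz, sp$magnitude, f_max = 32L,
                          method = cfg$resample_method)
    normalize_and_band_select(rs, cfg)
  })
  structure(
    list(values = unlist(blocks),
         class_code = segment$class_code,
         word_code = segment$word_code,
         record_id = segment$record_id,
         subject_id = segment$subject_id,
         n_channels = nrow(win),
         n_freqs = n_freqs(cfg)),
    class = "feature_vector")
}

#' Build a feature database from a list of segments
#'
#' @param segments List of `instance_segment`s.
#' @param cfg A [feature_config()].
#' @return A `feature_db`: list with `features` (instances x `Nch*Nf`
#'   matrix, columns labelled `Cz_10Hz`-style), `meta` (data.frame with
#'   `class_code`, `word_code`, `record_id`, `subject_id`) and `config`.
#' @export
featurize_segments <- function(segments, cfg = feature_config()) {
  stopifnot(length(segments) >= 1)
  fvs <- lapply(segments, build_feature_vector, cfg = cfg)
  features <- do.call(rbind, lapply(fvs, `[[`, "values"))
  colnames(features) <- as.vector(vapply(
    cfg$channels,
    function(ch) sprintf("%s_%dHz", ch, cfg$freq_lo_hz:cfg$freq_hi_hz),
    character(n_freqs(cfg))))
  meta <- data.frame(
    class_code = vapply(fvs, `[[`, integer(1), "class_code"),
    word_code = vapply(fvs, `[[`, integer(1), "word_code"),
    record_id = vapply(fvs, `[[`, integer(1), "record_id"),
    subject_id = vapply(fvs, function(f) as.integer(f$subject_id), integer(1)))
  structure(list(features = features, meta = meta, config = cfg),
            class = "feature_db")
}

#' Export a feature database as CSV
#'
#' One row per instance: metadata columns followed by the labelled feature
#' columns.
#'
#' @param db A `feature_db`.
#' @param path Output file path.
#' @export
write_features_csv <- function(db, path) {
  stopifnot(inherits(db, "feature_db"))
  utils::write.csv(cbind(db$meta, as.data.frame(db$features)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.feature_db <- function(x, ...) {
  cat(sprintf("Feature database: %d instances x %d features (%d channels x %d freqs)\n",
              nrow(x$features), ncol(x$features),
              length(x$config$channels), n_freqs(x$config)))
  cat("  classes:", paste(sort(unique(x$meta$class_code)), collapse = " "), "\n")
  invisible(x)
}
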