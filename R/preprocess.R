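#' Preprocessing configuration
#'
#' Parameters of the preprocessing chain: zero-phase low-pass filtering,
#' block-average downsampling, sync-driven segmentation and energy-based
#' artifact rejection. Defaults follow the reference pipeline: 32 Hz cutoff,
#' 500 -> 100 Hz downsampling (factor 5), rejection factor k = 3.
#'
#' @param lpf_cutoff_hz Low-pass cutoff in Hz.
#' @param filter_order Butterworth order of the single-direction prototype;
#'   applied forward and backward, so the effective magnitude response is
#'   squared.
#' @param downsample_factor Consecutive samples replaced by their average.
#' @param energy_reject_factor Factor k: instances with mean energy outside
#'   \[mean/k, mean*k\] are rejected. Must exceed 1.
#' @param target_instance_samples Samples every segment is cropped or padded
#'   to; `NULL` (default) uses `instance_time * fs` after downsampling.
#'
#' @return Object of class `preproc_config`.
#' @export
preprocess_config <- function(lpf_cutoff_hz = 32,
                              filter_order = 8,
                              downsample_factor = 5L,
                              energy_reject_factor = 3,
                              target_instance_samples = NULL) {
  stopifnot(lpf_cutoff_hz > 0, filter_order >= 1,
            downsample_factor >= 1, energy_reject_factor > 1)
  structure(
    list(lpf_cutoff_hz = lpf_cutoff_hz,
         filter_order = as.integer(filter_order),
         downsample_factor = as.integer(downsample_factor),
         energy_reject_factor = energy_reject_factor,
         target_instance_samples = target_instance_samples),
    class = "preproc_config")
}

#' Zero-phase low-pass filter
#'
#' Butterworth low-pass applied forward and backward (`signal::filtfilt`),
#' so the output has exactly zero phase: transients and sync onsets stay at
#' their original sample index. The forward-backward pass squares the
#' magnitude response, which is why an order-8 prototype is used: it keeps
#' the passband flat (gain within 5% up to 0.8x cutoff) while attenuating
#' 50 Hz mains noise by more than 40 dB at the default 32 Hz cutoff.
#'
#' @param x Numeric vector, or matrix with one channel per row.
#' @param fs_hz Sampling rate in Hz.
#' @param cutoff_hz Cutoff frequency; must be below Nyquist.
#' @param order Butterworth prototype order.
#' @return Filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs_hz, cutoff_hz = 32, order = 8) {
  if (cutoff_hz >= fs_hz / 2)
    stop("cutoff_hz must be below the Nyquist frequency ", fs_hz / 2)
  bf <- signal::butter(order, cutoff_hz / (fs_hz / 2), type = "low")
  if (is.matrix(x)) {
    out <- t(apply(x, 1, function(row) signal::filtfilt(bf, row)))
    dimnames(out) <- dimnames(x)
    out
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Block-average downsampling
#'
#' Replaces each run of `factor` consecutive samples by their average;
#' trailing samples that do not fill a complete block are dropped, so the
#' output length is `floor(n / factor)`. With `factor = 1` this is the
#' identity.
#'
#' @param x Numeric vector, or matrix with one channel per row.
#' @param factor Positive integer decimation factor.
#' @return Downsampled signal, same orientation as `x`.
#' @export
block_downsample <- function(x, factor = 5L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (is.matrix(x)) {
    n_out <- ncol(x) %/% factor
    if (n_out == 0) return(x[, 0, drop = FALSE])
    kept <- x[, seq_len(n_out * factor), drop = FALSE]
    out <- matrix(0, nrow(x), n_out, dimnames = list(rownames(x), NULL))
    for (i in seq_len(nrow(x)))
      out[i, ] <- colMeans(matrix(kept[i, ], nrow = factor))
    out
  } else {
    n_out <- length(x) %/% factor
    if (n_out == 0) return(numeric(0))
    colMeans(matrix(x[seq_len(n_out * factor)], nrow = factor))
  }
}

#' Segment a preprocessed record into per-instance windows
#'
#' Cuts one `InstanceSegment` per sync event out of an already filtered and
#' downsampled record. Each segment is cropped (from the end) or padded with
#' zeros (at the end) to exactly `target_instance_samples`, so every
#' instance in the database has the same length. Segment class codes follow
#' the two-digit coding convention: word digit followed by the record's part
#' number, e.g. word 4 in part 1 gives class code 41.
#'
#' @param record An `eeg_record` whose `data` has already been filtered and
#'   downsampled (scalp rows only; sync information is taken from
#'   `sync_events`, with onsets already rescaled to the current rate).
#' @param cfg A [preprocess_config()].
#' @return List of `instance_segment` objects: each a list with `class_code`
#'   (two-digit), `word_code`, `record_id`, `subject_id`, `data`
#'   (scalp channels x samples) and `fs_hz`.
#' @export
segment_record <- function(record, cfg = preprocess_config()) {
  stopifnot(inherits(record, "eeg_record"))
  data <- record$data
  scalp <- intersect(rownames(data), eeg_1020_scalp())
  data <- data[scalp, , drop = FALSE]
  target <- cfg$target_instance_samples
  if (is.null(target)) {
    spacing <- if (nrow(record$sync_events) > 1)
      diff(record$sync_events$onset_sample[1:2]) else ncol(data)
    target <- as.integer(spacing)
  }
  n <- ncol(data)
  segments <- list()
  for (k in seq_len(nrow(record$sync_events))) {
    on <- record$sync_events$onset_sample[k]
    code <- record$sync_events$class_code[k]
    if (on > n) {
      warning(sprintf("sync event %d at sample %d beyond data end (%d); skipped",
                      k, on, n))
      next
    }
    end <- min(on + target - 1L, n)
    seg <- data[, on:end, drop = FALSE]
    if (ncol(seg) < target)   # pad zeros at the end
      seg <- cbind(seg, matrix(0, nrow(seg), target - ncol(seg)))
    segments[[length(segments) + 1L]] <- structure(
      list(class_code = as.integer(code) * 10L + as.integer(record$record_id),
           word_code = as.integer(code),
           record_id = record$record_id,
           subject_id = record$subject_id,
           data = seg,
           fs_hz = record$fs_hz),
      class = "instance_segment")
  }
  segments
}

#' Energy-based artifact rejection
#'
#' Computes each segment's mean per-sample energy (squared amplitude pooled
#' over channels and samples) and rejects segments whose energy falls
#' outside \[E/k, E*k\], where E is the mean energy over all input
#' segments. Rejected segments are returned, not discarded silently.
#'
#' @param segments List of `instance_segment`s.
#' @param k Rejection factor, > 1.
#' @return List with `kept`, `rejected` (both lists of segments), `energies`
#'   and logical `rejected_flag` aligned with the input.
#' @export
reject_artifacts <- function(segments, k = 3) {
  stopifnot(k > 1, length(segments) >= 1)
  energies <- vapply(segments, function(s) mean_energy(s$data), numeric(1))
  e_bar <- mean(energies)
  bad <- energies < e_bar / k | energies > e_bar * k
  list(kept = segments[!bad],
       rejected = segments[bad],
       energies = energies,
       rejected_flag = bad)
}

#' Run the full preprocessing chain on one record
#'
#' Applies the pipeline in its fixed order: low-pass filter, block-average
#' downsample (rescaling sync onsets by the same factor), then segmentation
#' into fixed-length instances. Artifact rejection is applied afterwards,
#' per batch of segments, via [reject_artifacts()].
#'
#' @param record An `eeg_record` at the acquisition rate.
#' @param cfg A [preprocess_config()].
#' @param instance_time_s Instance duration used to fix the segment length
#'   at the downsampled rate.
#' @return List of `instance_segment`s at the downsampled rate.
#' @export
preprocess_record <- function(record, cfg = preprocess_config(),
                              instance_time_s = 4) {
  stopifnot(inherits(record, "eeg_record"))
  scalp <- intersect(rownames(record$data), eeg_1020_scalp())
  filtered <- lowpass_filter(record$data[scalp, , drop = FALSE],
                             fs_hz = record$fs_hz,
                             cutoff_hz = cfg$lpf_cutoff_hz,
                             order = cfg$filter_order)
  ds <- block_downsample(filtered, cfg$downsample_factor)
  fs_out <- record$fs_hz / cfg$downsample_factor
  rec2 <- record
  rec2$data <- ds
  rec2$fs_hz <- fs_out
  rec2$sync_events$onset_sample <-
    (record$sync_events$onset_sample - 1L) %/% cfg$downsample_factor + 1L
  if (is.null(cfg$target_instance_samples))
    cfg$target_instance_samples <- as.integer(round(instance_time_s * fs_out))
  segment_record(rec2, cfg)
}

#' Preprocess a list of records into a segment database
#'
#' Runs [preprocess_record()] on every record and applies energy-based
#' rejection within each record's batch of segments (the rejection baseline
#' is that record's own average energy).
#'
#' @param records List of `eeg_record`s.
#' @param cfg A [preprocess_config()].
#' @param instance_time_s Instance duration in seconds.
#' @return List with `kept` and `rejected` segment lists pooled over records.
#' @export
preprocess_dataset <- function(records, cfg = preprocess_config(),
                               instance_time_s = 4) {
  kept <- list()
  rejected <- list()
  for (rec in records) {
    segs <- preprocess_record(rec, cfg, instance_time_s)
    rej <- reject_artifacts(segs, cfg$energy_reject_factor)
    kept <- c(kept, rej$kept)
    rejected <- c(rejected, rej$rejected)
  }
  list(kept = kept, rejected = rejected)
}
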