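#' Scalp channel names of the 10-20 montage
#'
#' The 19 scalp electrode names of the international 10-20 system, in the
#' conventional anterior-to-posterior order. The earlobe reference positions
#' A1 and A2 are excluded; see [eeg_1020_channels()] for the full montage.
#'
#' @return Character vector of 19 channel names.
#' @export
eeg_1020_scalp <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Full 10-20 montage including reference electrodes
#'
#' @return Character vector of 21 channel names: 19 scalp channels plus the
#'   earlobe references A1 and A2.
#' @export
eeg_1020_channels <- function() {
  c(eeg_1020_scalp(), "A1", "A2")
}

# row names used for the two synchronization rows of a synthesized record
sync_row_names <- function() c("SYNC_TYPE", "SYNC_ONSET")

#' Acquisition design configuration
#'
#' Describes the recording protocol a dataset was (or is simulated to be)
#' acquired under: sampling rate, per-instance timing, the trial/test
#' schedule, and the session structure. The defaults reproduce the reference
#' design: 500 Hz sampling, 4 s instances, 3 classes x 20 trials per test,
#' 3 tests per part, 2 parts per session, 5 sessions.
#'
#' @param fs_hz Sampling rate in Hz.
#' @param instance_time_s Instance duration Ti in seconds: the interval
#'   between two consecutive word presentations.
#' @param display_time_s Display duration Td in seconds. Only meaningful for
#'   visual stimulation; retained as metadata.
#' @param excitation_time_s Excitation time Te in seconds: the initial part
#'   of each instance during which the stimulus word is played.
#' @param rest_time_s Rest time Tr in seconds between stimulus end and the
#'   start of silent repetition.
#' @param n_classes_per_test Number of classes Nc presented in one test.
#' @param n_trials Number of trials Nt per test; each trial presents every
#'   class of the test exactly once.
#' @param n_sessions Number of recording sessions per subject.
#' @param n_parts_per_session Recording parts per session.
#' @param n_tests_per_part Tests recorded in each part.
#' @param channel_names Names of the electrode montage; must contain the 19
#'   scalp channels of the 10-20 system plus A1 and A2.
#'
#' @return An object of class `acq_config`.
#' @export
acquisition_config <- function(fs_hz = 500,
                               instance_time_s = 4,
                               display_time_s = 2,
                               excitation_time_s = 0.5,
                               rest_time_s = 0.25,
                               n_classes_per_test = 3L,
                               n_trials = 20L,
                               n_sessions = 5L,
                               n_parts_per_session = 2L,
                               n_tests_per_part = 3L,
                               channel_names = eeg_1020_channels()) {
  stopifnot(fs_hz > 0, instance_time_s > 0,
            n_classes_per_test >= 2, n_trials >= 1,
            n_sessions >= 1, n_parts_per_session >= 1, n_tests_per_part >= 1)
  if (instance_time_s <= excitation_time_s + rest_time_s)
    stop("instance_time_s must exceed excitation_time_s + rest_time_s")
  missing <- setdiff(eeg_1020_channels(), channel_names)
  if (length(missing))
    stop("channel_names must contain the 10-20 montage; missing: ",
         paste(missing, collapse = ", "))
  structure(
    list(fs_hz = fs_hz,
         instance_time_s = instance_time_s,
         display_time_s = display_time_s,
         excitation_time_s = excitation_time_s,
         rest_time_s = rest_time_s,
         n_classes_per_test = as.integer(n_classes_per_test),
         n_trials = as.integer(n_trials),
         n_sessions = as.integer(n_sessions),
         n_parts_per_session = as.integer(n_parts_per_session),
         n_tests_per_part = as.integer(n_tests_per_part),
         channel_names = channel_names),
    class = "acq_config")
}

#' @export
print.acq_config <- function(x, ...) {
  cat("EEG acquisition design\n")
  cat(sprintf("  fs = %g Hz, Ti = %g s (Te = %g, Tr = %g)\n",
              x$fs_hz, x$instance_time_s, x$excitation_time_s, x$rest_time_s))
  cat(sprintf("  %d classes x %d trials per test; %d tests/part, %d parts/session, %d sessions\n",
              x$n_classes_per_test, x$n_trials, x$n_tests_per_part,
              x$n_parts_per_session, x$n_sessions))
  invisible(x)
}
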