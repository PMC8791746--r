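#' Generate a pseudorandom test schedule
#'
#' Builds the presentation order for one test: `n_trials` trials, each an
#' independent uniform permutation of `word_set`, concatenated back-to-back
#' at `ti_s` spacing. This mirrors the trial generator used during
#' acquisition, where every block of `length(word_set)` consecutive
#' instances contains each class exactly once.
#'
#' @param word_set Distinct class codes presented in this test.
#' @param n_trials Number of trials; total instances = `n_trials * length(word_set)`.
#' @param ti_s Instance time in seconds.
#' @param fs_hz Sampling rate in Hz; onsets are expressed in samples at this rate.
#' @param seed Optional integer seed; fixed seeds give bit-identical schedules.
#' @param max_test_time_s Soft cap on total test duration; exceeding it warns
#'   (long tests fatigue subjects) but still returns the schedule.
#'
#' @return A `test_schedule`: list with `entries` (data.frame of `class_code`
#'   and 1-based `onset_sample`), `word_set`, `ti_s` and `fs_hz`.
#' @export
#' @examples
#' sch <- generate_schedule(c(3, 6, 7), n_trials = 20, seed = 1)
#' table(sch$entries$class_code)  # 20 of each class
generate_schedule <- function(word_set, n_trials, ti_s = 4, fs_hz = 500,
                              seed = NULL, max_test_time_s = 300) {
  if (anyDuplicated(word_set))
    stop("word_set must contain distinct class codes")
  if (length(word_set) < 2) stop("need at least 2 classes per test")
  if (n_trials < 1) stop("n_trials must be >= 1")
  total_s <- length(word_set) * n_trials * ti_s
  if (total_s > max_test_time_s)
    warning(sprintf("test duration %.0f s exceeds max_test_time_s = %.0f s",
                    total_s, max_test_time_s))
  if (!is.null(seed)) set.seed(seed)
  order <- unlist(lapply(seq_len(n_trials),
                         function(i) sample(word_set, length(word_set))))
  spacing <- round(ti_s * fs_hz)
  entries <- data.frame(
    class_code = order,
    onset_sample = (seq_along(order) - 1L) * spacing + 1L)
  structure(list(entries = entries, word_set = word_set,
                 ti_s = ti_s, fs_hz = fs_hz),
            class = "test_schedule")
}

#' Export a schedule as CSV
#'
#' Writes one row per instance with the class code, its onset in samples and
#' in seconds.
#'
#' @param schedule A `test_schedule`.
#' @param path Output file path.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "test_schedule"))
  df <- schedule$entries
  df$onset_seconds <- (df$onset_sample - 1) / schedule$fs_hz
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.test_schedule <- function(x, ...) {
  cat(sprintf("Test schedule: %d instances (%d classes x %d trials), Ti = %g s @ %g Hz\n",
              nrow(x$entries), length(x$word_set),
              nrow(x$entries) / length(x$word_set), x$ti_s, x$fs_hz))
  invisible(x)
}
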