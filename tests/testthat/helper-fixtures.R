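# Brute-force DFT magnitude oracle, O(n^2), independent of stats::fft.
# One-sided, same bin convention as magnitude_spectrum().
dft_magnitude <- function(x) {
  n <- length(x)
  vapply(0:(n %/% 2), function(k)
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))), numeric(1))
}

# Independent re-statement of the one-vs-one winner selection rule, used as
# the enumeration oracle for majority_vote().
brute_force_vote <- function(votes, pairs, classes, unknown_code = 0L) {
  counts <- sapply(classes, function(cl) sum(votes == cl))
  top <- classes[counts == max(counts)]
  if (length(top) == 1) return(as.integer(top))
  if (length(top) > 2) return(as.integer(unknown_code))
  for (m in seq_len(nrow(pairs)))
    if (setequal(pairs[m, ], top)) return(as.integer(votes[m]))
  stop("specialist machine not found")
}

# Two Gaussian point clouds, linearly separable for well-separated centers.
make_clouds <- function(n, center, n_features = 5, sd = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(n * n_features, mean = center, sd = sd), nrow = n)
}

# One synthetic record through the default pipeline; small by default.
make_small_record <- function(words = c(3, 6), n_trials = 4, seed = 42,
                              signatures = default_signatures(),
                              record_id = 0, ...) {
  sch <- generate_schedule(c(words, 7), n_trials, seed = seed)
  synthesize_record(sch, signatures, acquisition_config(),
                    record_id = record_id, seed = seed + 1, ...)
}

# Minimal hand-built feature database for mode-assembly tests: every word in
# every record, one instance each, features = the class code (1 column).
make_toy_db <- function(words = 1:6, silence = 7, records = 0:9) {
  grid <- expand.grid(word_code = c(words, silence), record_id = records)
  features <- matrix(as.numeric(grid$word_code), ncol = 1)
  colnames(features) <- "Cz_1Hz"
  structure(list(
    features = features,
    meta = data.frame(
      class_code = grid$word_code * 10L + grid$record_id,
      word_code = grid$word_code,
      record_id = grid$record_id,
      subject_id = 1L),
    config = feature_config(channels = "Cz", freq_lo_hz = 1, freq_hi_hz = 1)),
    class = "feature_db")
}

# Hand-built 3-class bank of stub machines acting on 2-D features:
# machine (1,2) votes by sign of x1; machines (1,7) and (2,7) vote Silence
# (class 7) whenever x2 < 0 -- "perfect" word-vs-silence specialists for
# samples with x2 < 0.
make_stub_wws_bank <- function() {
  mk <- function(pos, neg, w, b) structure(
    list(class_pair = sort(c(pos, neg)), positive_class = pos,
         negative_class = neg, weights = w, bias = b, cost = 1),
    class = "binary_svm")
  structure(list(
    classes = c(1L, 2L, 7L),
    machines = list("1:2" = mk(1L, 2L, c(1, 0), 0),
                    "1:7" = mk(1L, 7L, c(0, 1), 0),
                    "2:7" = mk(2L, 7L, c(0, 1), 0)),
    unknown_code = 0L, n_features = 2L),
    class = "svm_bank")
}
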