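#' Assemble a labelled dataset under a classification mode
#'
#' The three modes differ in the recording-time separation between and
#' within classes, reflecting EEG nonstationarity:
#' \describe{
#'   \item{long_time}{all instances of each requested word across every
#'     record, labelled by the single-digit word code;}
#'   \item{short_time}{instances of all requested words from one single
#'     record, labelled by the two-digit word+record code;}
#'   \item{mixed_time}{each word taken from its own, pairwise-distinct
#'     record, labelled by the two-digit code.}
#' }
#' All Silence instances of a part count as that part's Silence record.
#'
#' @param db A `feature_db`.
#' @param mode `"long_time"`, `"short_time"` or `"mixed_time"`.
#' @param words Single-digit word codes to include.
#' @param records For `short_time`, one record id shared by all classes;
#'   for `mixed_time`, one record id per word, pairwise distinct; ignored
#'   for `long_time`.
#' @return List with `features` (matrix) and `labels` (integer vector).
#' @export
assemble_mode_dataset <- function(db, mode = c("long_time", "short_time",
                                               "mixed_time"),
                                  words, records = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "feature_db"), length(words) >= 1)
  meta <- db$meta
  if (mode == "long_time") {
    sel <- meta$word_code %in% words
    labels <- meta$word_code[sel]
  } else if (mode == "short_time") {
    if (length(records) != 1)
      stop("short_time mode needs exactly one record id")
    sel <- meta$word_code %in% words & meta$record_id == records
    labels <- meta$class_code[sel]
  } else {
    if (length(records) != length(words))
      stop("mixed_time mode needs one record id per word")
    if (anyDuplicated(records))
      stop("mixed_time record ids must be pairwise distinct")
    sel <- rep(FALSE, nrow(meta))
    for (k in seq_along(words))
      sel <- sel | (meta$word_code == words[k] & meta$record_id == records[k])
    labels <- meta$class_code[sel]
  }
  if (!sum(sel)) stop("no instances match the requested classes")
  present <- sort(unique(labels))
  expected <- if (mode == "long_time") sort(words)
  else if (mode == "short_time") sort(words * 10L + records)
  else sort(words * 10L + records)
  if (!all(expected %in% present))
    stop("empty class(es): ", paste(setdiff(expected, present), collapse = ", "))
  list(features = db$features[sel, , drop = FALSE],
       labels = as.integer(labels))
}

#' Number of mixed-time record assignments
#'
#' Counts the injective assignments of `n_classes` classes to `n_records`
#' records (falling factorial): with 10 records and 7 classes there are
#' 10!/3! = 604800 ways to give every class its own record.
#'
#' @param n_records Available records.
#' @param n_classes Classes needing distinct records.
#' @return The count as a double (exact for the design sizes involved).
#' @export
count_mixed_assignments <- function(n_records, n_classes) {
  if (n_classes > n_records)
    stop("cannot assign ", n_classes, " classes to ", n_records,
         " distinct records")
  if (n_classes < 1) stop("n_classes must be >= 1")
  prod(seq(n_records, by = -1, length.out = n_classes))
}

#' Confusion matrix with an Unknown column
#'
#' Rows are true classes; columns are the predicted classes plus a final
#' `"Unknown"` column for samples the majority rule could not decide.
#'
#' @param true,pred Integer vectors of true and predicted codes.
#' @param classes The class codes (row/column order).
#' @param unknown_code Code counted in the Unknown column.
#' @return Integer matrix `n x (n+1)`.
#' @export
confusion_matrix <- function(true, pred, classes, unknown_code = 0L) {
  n <- length(classes)
  C <- matrix(0L, n, n + 1L,
              dimnames = list(classes, c(classes, "Unknown")))
  for (k in seq_along(true)) {
    i <- match(true[k], classes)
    j <- if (pred[k] == unknown_code) n + 1L else match(pred[k], classes)
    if (is.na(i) || is.na(j)) stop("label outside the class set")
    C[i, j] <- C[i, j] + 1L
  }
  C
}

#' Accuracy of a confusion matrix
#'
#' Trace of the square part divided by the total count including the
#' Unknown column, so undecided samples count as errors.
#'
#' @param C Confusion matrix as built by [confusion_matrix()].
#' @return Fraction in \[0, 1\].
#' @export
accuracy_from_confusion <- function(C) {
  if (!length(C) || sum(C) == 0) stop("empty confusion matrix")
  n <- nrow(C)
  sum(diag(C[, seq_len(n), drop = FALSE])) / sum(C)
}

#' Monte-Carlo cross-validation of the one-vs-one bank
#'
#' Repeats `n_iter` times: draw a stratified random split (per class,
#' `floor(train_fraction * n)` training samples), train a full classifier
#' bank on the training split, classify the test split, and record the
#' iteration's confusion matrix and accuracy. Accumulates the summed
#' confusion matrix C, the per-iteration accuracy vector Mc, their mean A
#' and (population) standard deviation sigma.
#'
#' A master seed derives one seed per iteration, so any iteration can be
#' reproduced in isolation.
#'
#' @param features Instances-by-features matrix.
#' @param labels Integer class codes, one per row.
#' @param n_iter Number of Monte-Carlo iterations Nr.
#' @param train_fraction Fraction of each class used for training.
#' @param cost Soft-margin constant for every binary machine.
#' @param seed Optional master seed.
#' @param unknown_code Sentinel for undecided predictions.
#' @return An `mc_result`: list with `C`, `Mc`, `A`, `sigma`, `n_iter`,
#'   `classes`, `unknown_code`.
#' @export
monte_carlo_cv <- function(features, labels, n_iter = 30,
                           train_fraction = 0.7, cost = 1, seed = NULL,
                           unknown_code = 0L) {
  stopifnot(nrow(features) == length(labels), n_iter >= 1,
            train_fraction > 0, train_fraction < 1)
  classes <- sort(unique(as.integer(labels)))
  counts <- table(labels)
  if (any(counts < 2))
    stop("every class needs at least 2 samples to split; offending: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  iter_seeds <- derive_seeds(seed, n_iter)
  n <- length(classes)
  C <- matrix(0L, n, n + 1L, dimnames = list(classes, c(classes, "Unknown")))
  Mc <- numeric(n_iter)
  for (r in seq_len(n_iter)) {
    set.seed(iter_seeds[r])
    train_idx <- unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      sample(idx, floor(train_fraction * length(idx)))
    }))
    test_idx <- setdiff(seq_along(labels), train_idx)
    class_data <- lapply(classes, function(cl)
      features[intersect(train_idx, which(labels == cl)), , drop = FALSE])
    names(class_data) <- classes
    bank <- train_bank(class_data, cost = cost, unknown_code = unknown_code)
    pred <- predict(bank, features[test_idx, , drop = FALSE])
    Cr <- confusion_matrix(labels[test_idx], pred, classes, unknown_code)
    C <- C + Cr
    Mc[r] <- accuracy_from_confusion(Cr)
  }
  A <- mean(Mc)
  structure(
    list(C = C, Mc = Mc, A = A,
         sigma = sqrt(mean((A - Mc)^2)),
         n_iter = n_iter, classes = classes,
         unknown_code = as.integer(unknown_code)),
    class = "mc_result")
}

#' Summarize an evaluation result
#'
#' Produces the row-normalized percentage confusion matrix, the raw counts,
#' the overall accuracy with its Monte-Carlo standard deviation, and the
#' Unknown rate. Each normalized row sums to 100 (up to rounding).
#'
#' @param result An `mc_result`.
#' @param digits Decimal places for the percentage matrix.
#' @return Invisibly, a list with `percent` (row-normalized matrix),
#'   `counts`, `accuracy_percent`, `sigma_percent`, `unknown_rate`.
#' @export
report <- function(result, digits = 1) {
  stopifnot(inherits(result, "mc_result"))
  C <- result$C
  pct <- 100 * sweep(C, 1, pmax(rowSums(C), 1), "/")
  out <- list(percent = round(pct, digits),
              counts = C,
              accuracy_percent = 100 * result$A,
              sigma_percent = 100 * result$sigma,
              unknown_rate = sum(C[, ncol(C)]) / sum(C))
  cat(sprintf("Accuracy: %.1f +/- %.1f %% over %d Monte-Carlo iterations\n",
              out$accuracy_percent, out$sigma_percent, result$n_iter))
  cat(sprintf("Unknown rate: %.2f %%\n", 100 * out$unknown_rate))
  cat("Row-normalized confusion matrix (%):\n")
  print(out$percent)
  invisible(out)
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo CV result: %d classes, Nr = %d\n",
              length(x$classes), x$n_iter))
  cat(sprintf("  A = %.3f, sigma = %.3f\n", x$A, x$sigma))
  invisible(x)
}

#' Sample distinct record assignments for mixed-time evaluation
#'
#' Draws `n` random injective assignments of records to the given words;
#' full enumeration of all assignments (e.g. 604800 for 7 classes over 10
#' records) is impractical, so evaluation averages over a random sample.
#'
#' @param n_records Number of available records (ids `0:(n_records-1)`).
#' @param words Word codes needing records.
#' @param n Number of assignments to draw.
#' @param seed Optional seed.
#' @return List of integer vectors, each one record id per word.
#' @export
sample_mixed_assignments <- function(n_records, words, n = 100, seed = NULL) {
  if (length(words) > n_records)
    stop("more words than records; no injective assignment exists")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i)
    sample(0:(n_records - 1L), length(words)))
}

#' Evaluate one classification mode end to end
#'
#' Convenience wrapper: assembles the mode's dataset and runs Monte-Carlo
#' cross-validation. For mixed-time mode with `assignments` a list of
#' record assignments, evaluates each and returns the average accuracy
#' across assignments together with the individual results.
#'
#' @param db A `feature_db`.
#' @param mode Classification mode.
#' @param words Word codes.
#' @param records Record id(s) as required by the mode.
#' @param assignments For mixed-time: list of record assignments (overrides
#'   `records`).
#' @param n_iter,train_fraction,cost,seed Passed to [monte_carlo_cv()].
#' @return For a single dataset, an `mc_result`; with `assignments`, a list
#'   with `A` (mean over assignments) and `results`.
#' @export
evaluate_mode <- function(db, mode, words, records = NULL,
                          assignments = NULL, n_iter = 30,
                          train_fraction = 0.7, cost = 1, seed = NULL) {
  if (!is.null(assignments)) {
    seeds <- derive_seeds(seed, length(assignments))
    results <- vector("list", length(assignments))
    for (k in seq_along(assignments)) {
      ds <- assemble_mode_dataset(db, mode, words, assignments[[k]])
      results[[k]] <- monte_carlo_cv(ds$features, ds$labels, n_iter,
                                     train_fraction, cost, seeds[k])
    }
    return(list(A = mean(vapply(results, `[[`, numeric(1), "A")),
                results = results))
  }
  ds <- assemble_mode_dataset(db, mode, words, records)
  monte_carlo_cv(ds$features, ds$labels, n_iter, train_fraction, cost, seed)
}
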