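#' Train one pairwise binary classifier
#'
#' Fits a soft-margin linear support-vector machine discriminating two
#' classes, and stores it as an explicit linear decision rule: predicted
#' class is `class_i` when `w . x + b > 0`, else `class_j`. Swapping the
#' class order yields the same decision partition.
#'
#' @param x_i,x_j Feature matrices (instances x features) of the two classes.
#' @param class_i,class_j Their class codes.
#' @param cost Soft-margin regularization constant C.
#' @param seed Optional seed (the fit itself is deterministic; the seed is
#'   accepted for interface uniformity).
#' @return A `binary_svm`: list with `class_pair` (sorted), `positive_class`,
#'   `negative_class`, `weights`, `bias`.
#' @export
train_binary <- function(x_i, x_j, class_i, class_j, cost = 1, seed = NULL) {
  if (!nrow(x_i) || !nrow(x_j)) stop("both classes must be non-empty")
  if (ncol(x_i) != ncol(x_j)) stop("feature lengths differ between classes")
  if (class_i == class_j) stop("classes must differ")
  x <- rbind(x_i, x_j)
  if (all(vapply(seq_len(nrow(x)),
                 function(r) identical(x[r, ], x[1, ]), logical(1))))
    stop("degenerate data: all feature vectors identical across both classes")
  if (!is.null(seed)) set.seed(seed)
  y <- factor(c(rep(class_i, nrow(x_i)), rep(class_j, nrow(x_j))),
              levels = c(class_i, class_j))
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  # linear kernel: w = coefs' SV, b = -rho; decision > 0 <=> first level
  w <- drop(crossprod(fit$coefs, fit$SV))
  structure(
    list(class_pair = sort(c(class_i, class_j)),
         positive_class = class_i,
         negative_class = class_j,
         weights = unname(w),
         bias = -fit$rho,
         cost = cost),
    class = "binary_svm")
}

# vote of one binary machine for each row of x
predict_binary <- function(machine, x) {
  dv <- drop(x %*% machine$weights) + machine$bias
  ifelse(dv > 0, machine$positive_class, machine$negative_class)
}

# canonical key of an unordered class pair
pair_key <- function(i, j) paste(sort(c(i, j)), collapse = ":")

#' Train a one-vs-one classifier bank
#'
#' Trains one binary machine for every unordered pair of classes:
#' `n(n-1)/2` machines for n classes.
#'
#' @param class_data Named list mapping class code to that class's feature
#'   matrix (instances x features).
#' @param cost Soft-margin constant passed to every machine.
#' @param seed Optional seed.
#' @param unknown_code Sentinel code returned when the vote is undecidable.
#' @return An `svm_bank`: list with `classes`, `machines` (named by
#'   `"i:j"` pair keys), `unknown_code`, `n_features`.
#' @export
train_bank <- function(class_data, cost = 1, seed = NULL, unknown_code = 0L) {
  if (length(class_data) < 2) stop("need at least 2 classes")
  classes <- as.integer(names(class_data))
  if (anyNA(classes)) stop("class_data must be named by integer class codes")
  if (unknown_code %in% classes)
    stop("unknown_code collides with a class code")
  if (!is.null(seed)) set.seed(seed)
  pairs <- utils::combn(sort(classes), 2)
  machines <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    machines[[pair_key(i, j)]] <- train_binary(
      class_data[[as.character(i)]], class_data[[as.character(j)]], i, j,
      cost = cost)
  }
  structure(
    list(classes = sort(classes), machines = machines,
         unknown_code = as.integer(unknown_code),
         n_features = ncol(class_data[[1]])),
    class = "svm_bank")
}

#' Majority rule over pairwise votes
#'
#' Implements the winner-selection rule of a one-vs-one bank: the class
#' with the unique largest vote count wins; when exactly two classes tie
#' for the maximum, the "specialist" machine trained on that very pair
#' casts the deciding vote; when three or more classes tie, the sample is
#' assigned the Unknown code.
#'
#' @param votes Integer vector: the class voted by each machine.
#' @param pairs 2-column matrix: row m holds the class pair of machine m.
#' @param classes All class codes of the bank.
#' @param unknown_code Code returned for undecidable ties.
#' @return The winning class code (or `unknown_code`).
#' @export
majority_vote <- function(votes, pairs, classes, unknown_code = 0L) {
  counts <- vapply(classes, function(cl) sum(votes == cl), integer(1))
  m <- max(counts)
  tied <- classes[counts == m]
  if (length(tied) == 1L) return(as.integer(tied))
  if (length(tied) == 2L) {
    spec <- which(pairs[, 1] == min(tied) & pairs[, 2] == max(tied))
    return(as.integer(votes[spec]))
  }
  as.integer(unknown_code)
}

#' Classify feature vectors with a one-vs-one bank
#'
#' Presents each feature vector to every binary machine, tallies the votes
#' and applies [majority_vote()].
#'
#' @param object An `svm_bank`.
#' @param newdata Numeric matrix (instances x features) or a single vector.
#' @param ... Unused.
#' @return Integer vector of predicted class codes; undecidable samples get
#'   the bank's `unknown_code`.
#' @export
predict.svm_bank <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != object$n_features)
    stop(sprintf("feature length %d does not match bank (%d)",
                 ncol(newdata), object$n_features))
  votes <- vapply(object$machines, predict_binary, numeric(nrow(newdata)),
                  x = newdata)
  if (nrow(newdata) == 1L) votes <- matrix(votes, nrow = 1)
  pairs <- do.call(rbind, lapply(object$machines, `[[`, "class_pair"))
  as.integer(apply(votes, 1, majority_vote, pairs = pairs,
                   classes = object$classes,
                   unknown_code = object$unknown_code))
}

#' @export
print.svm_bank <- function(x, ...) {
  cat(sprintf("One-vs-one SVM bank: %d classes, %d machines, %d features\n",
              length(x$classes), length(x$machines), x$n_features))
  cat("  classes:", paste(x$classes, collapse = " "),
      " (unknown =", x$unknown_code, ")\n")
  invisible(x)
}

#' Serialize a classifier bank to JSON
#'
#' Writes the class list, per-pair weights and biases, and an optional
#' feature-configuration fingerprint guarding against train/test
#' configuration drift.
#'
#' @param bank An `svm_bank`.
#' @param path Output file path.
#' @param feature_config Optional [feature_config()] whose fingerprint is
#'   embedded.
#' @export
write_bank <- function(bank, path, feature_config = NULL) {
  stopifnot(inherits(bank, "svm_bank"))
  fp <- if (!is.null(feature_config))
    paste(deparse(unclass(feature_config)), collapse = "") else NA_character_
  obj <- list(
    classes = bank$classes,
    unknown_code = bank$unknown_code,
    n_features = bank$n_features,
    feature_fingerprint = fp,
    machines = lapply(bank$machines, function(m)
      list(class_pair = m$class_pair,
           positive_class = m$positive_class,
           negative_class = m$negative_class,
           weights = m$weights, bias = m$bias, cost = m$cost)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier bank from JSON
#'
#' @param path File written by [write_bank()].
#' @param feature_config Optional [feature_config()]; if the stored
#'   fingerprint exists and differs, loading fails.
#' @return An `svm_bank`.
#' @export
read_bank <- function(path, feature_config = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(feature_config) && !is.na(obj$feature_fingerprint)) {
    fp <- paste(deparse(unclass(feature_config)), collapse = "")
    if (!identical(fp, obj$feature_fingerprint))
      stop("feature configuration fingerprint mismatch: ",
           "bank was trained under a different feature configuration")
  }
  machines <- lapply(obj$machines, function(m) {
    structure(list(class_pair = as.integer(m$class_pair),
                   positive_class = as.integer(m$positive_class),
                   negative_class = as.integer(m$negative_class),
                   weights = as.numeric(m$weights),
                   bias = as.numeric(m$bias),
                   cost = as.numeric(m$cost)),
              class = "binary_svm")
  })
  structure(list(classes = as.integer(obj$classes),
                 machines = machines,
                 unknown_code = as.integer(obj$unknown_code),
                 n_features = as.integer(obj$n_features)),
            class = "svm_bank")
}
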