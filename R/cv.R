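#' Confusion matrix from true and predicted labels
#'
#' @param truth,pred numeric class-id vectors of equal length.
#' @param class_ids class ids defining row/column order; default the sorted
#'   union of `truth` and `pred`.
#' @return an object of class `confusion_matrix` (integer matrix, rows =
#'   true class, columns = predicted class).
#' @export
confusion_matrix <- function(truth, pred, class_ids = NULL) {
  assert_that(length(truth) == length(pred),
              "truth and pred must have equal length")
  if (is.null(class_ids)) class_ids <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, levels = class_ids),
              factor(pred, levels = class_ids))
  out <- matrix(as.integer(cm), nrow = length(class_ids),
                dimnames = list(true = as.character(class_ids),
                                predicted = as.character(class_ids)))
  structure(out, class = c("confusion_matrix", "matrix"))
}

#' Balanced classification score of a confusion matrix
#'
#' Macro-averaged per-class recall, in percent: the mean over classes of the
#' fraction of that class's trials classified correctly. Equals plain
#' accuracy when the classes are exactly balanced, and corrects for any
#' imbalance otherwise.
#'
#' @param cm a `confusion_matrix` (or plain square count matrix).
#' @return score in percent, 0–100.
#' @export
balanced_accuracy <- function(cm) {
  cm <- unclass(cm)
  assert_that(is.matrix(cm) && nrow(cm) == ncol(cm),
              "cm must be a square confusion matrix")
  rs <- rowSums(cm)
  assert_that(all(rs > 0), "every class needs at least one true trial")
  100 * mean(diag(cm) / rs)
}

#' Seeded stratified fold assignment
#'
#' Within each class, trials are shuffled by the seed and dealt round-robin
#' to the `k` folds, so per-class fold counts differ by at most one. The
#' assignment is deterministic given the seed and is intended to be SHARED
#' between the two cuffs of a paired session, so per-fold score differences
#' compare the same held-out trials.
#'
#' @param labels per-trial class ids.
#' @param k number of folds, default 5. Every class must have >= k trials.
#' @param seed integer seed.
#' @return an object of class `fold_assignment`: list with `fold_of_trial`
#'   (integers in 0..k-1), `k`, `seed`.
#' @export
stratified_folds <- function(labels, k = 5L, seed) {
  k <- as.integer(k)
  counts <- table(labels)
  if (any(counts < k)) {
    stop("class ", names(counts)[which.min(counts)], " has fewer than k = ",
         k, " trials", call. = FALSE)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- (seq_along(idx) - 1L) %% k
    }
  })
  structure(list(fold_of_trial = fold, k = k, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Cross-validate an LDA classifier over precomputed folds
#'
#' For each fold: fit on the out-of-fold trials, predict the held-out
#' trials, score with [balanced_accuracy()]. The headline score is the
#' median of the per-fold scores; held-out predictions are pooled into one
#' cross-validated confusion matrix.
#'
#' @param table a `feature_table`.
#' @param folds a [stratified_folds()] assignment consistent with `table`.
#' @param shrinkage LDA shrinkage passed to [fit_lda()].
#' @return an object of class `cv_result`: `fold_scores` (percent, one per
#'   fold), `median_score`, `confusion` (pooled `confusion_matrix`), `folds`.
#' @export
cross_validate <- function(table, folds, shrinkage = 0.05) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  assert_that(inherits(folds, "fold_assignment"), "folds must be a fold_assignment")
  assert_that(length(folds$fold_of_trial) == nrow(table$values),
              "fold assignment does not match the table")
  class_ids <- sort(unique(table$labels))
  truth_all <- numeric(0)
  pred_all <- numeric(0)
  scores <- numeric(folds$k)
  for (j in seq_len(folds$k) - 1L) {
    hold <- folds$fold_of_trial == j
    train <- feature_table(table$values[!hold, , drop = FALSE],
                           table$labels[!hold])
    model <- fit_lda(train, shrinkage = shrinkage)
    pred <- predict_lda(model, table$values[hold, , drop = FALSE])
    scores[j + 1L] <- balanced_accuracy(
      confusion_matrix(table$labels[hold], pred, class_ids))
    truth_all <- c(truth_all, table$labels[hold])
    pred_all <- c(pred_all, pred)
  }
  structure(list(fold_scores = scores,
                 median_score = median(scores),
                 confusion = confusion_matrix(truth_all, pred_all, class_ids),
                 folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> median %.1f%% over %d folds (%s)\n",
              x$median_score, length(x$fold_scores),
              paste(sprintf("%.1f", x$fold_scores), collapse = ", ")))
  invisible(x)
}

#' Per-fold score difference between two paired cross-validations
#'
#' Both results must have been computed with the SAME fold assignment over
#' the same trials — the two cuffs record the same trials simultaneously, so
#' fold j holds out the identical trials for both.
#'
#' @param result_a,result_b `cv_result` objects sharing a fold assignment.
#' @return list with `differences` (`a - b` per fold, percentage points) and
#'   `median`.
#' @export
fold_difference <- function(result_a, result_b) {
  assert_that(inherits(result_a, "cv_result") && inherits(result_b, "cv_result"),
              "both arguments must be cv_result objects")
  assert_that(identical(result_a$folds, result_b$folds),
              "fold assignments differ; fold differences require paired folds")
  d <- result_a$fold_scores - result_b$fold_scores
  list(differences = d, median = median(d))
}

#' Exhaustive electrode-pair search
#'
#' Cross-validates every unordered channel pair (`choose(c, 2)` candidates)
#' with the same fold assignment and ranks pairs by mean fold accuracy
#' (mean, not median, to reduce ties among candidates). Ties are broken by
#' lexicographic channel indices.
#'
#' @param table a `feature_table` with >= 2 channels.
#' @param folds a shared [stratified_folds()] assignment.
#' @param shrinkage LDA shrinkage.
#' @return data frame ranked best-first: `ch_a`, `ch_b` (0-based channel
#'   ids), `mean_accuracy`, `median_accuracy`.
#' @export
pair_search <- function(table, folds, shrinkage = 0.05) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  nch <- ncol(table$values)
  assert_that(nch >= 2L, "need at least 2 channels")
  pairs <- combn(nch, 2L)
  res <- apply(pairs, 2, function(pr) {
    sub <- feature_table(table$values[, pr, drop = FALSE], table$labels,
                         table$trial_ids)
    cv <- cross_validate(sub, folds, shrinkage = shrinkage)
    c(mean(cv$fold_scores), cv$median_score)
  })
  out <- data.frame(ch_a = table$channel_ids[pairs[1, ]],
                    ch_b = table$channel_ids[pairs[2, ]],
                    mean_accuracy = res[1, ],
                    median_accuracy = res[2, ])
  out[order(-out$mean_accuracy, out$ch_a, out$ch_b), , drop = FALSE]
}

#' Difference between two confusion matrices
#'
#' Entrywise `a - b`, either on raw counts or (default) after row-normalising
#' each matrix to per-class proportions, in which case every row of the
#' difference sums to zero. Used to compare the cross-validated confusions of
#' the distal and proximal cuffs.
#'
#' @param cm_a,cm_b confusion matrices with identical class sets.
#' @param normalise row-normalise before subtracting (default TRUE).
#' @return numeric signed matrix.
#' @export
confusion_difference <- function(cm_a, cm_b, normalise = TRUE) {
  a <- unclass(cm_a)
  b <- unclass(cm_b)
  assert_that(identical(dim(a), dim(b)), "confusion matrices differ in shape")
  assert_that(identical(dimnames(a), dimnames(b)),
              "confusion matrices have different class sets")
  if (normalise) {
    a <- a / rowSums(a)
    b <- b / rowSums(b)
  }
  a - b
}

#' Label-permutation chance level of the CV pipeline
#'
#' Repeatedly permutes the class labels of a feature table, re-runs the full
#' stratified five-fold cross-validation, and returns the permutation median
#' scores. With K balanced classes the scores converge to the analytic
#' chance level 100/K percent.
#'
#' @param table a `feature_table`.
#' @param n_perm number of label permutations (default 200).
#' @param k folds (default 5).
#' @param seed integer seed (drives both permutations and fold shuffles).
#' @param shrinkage LDA shrinkage.
#' @return list with `median` (median over permutations of the per-run
#'   median scores, percent) and `scores` (all permutation medians).
#' @export
permutation_chance <- function(table, n_perm = 200L, k = 5L, seed,
                               shrinkage = 0.05) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  scores <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample(table$labels)
      tab <- feature_table(table$values, lab, table$trial_ids)
      folds <- stratified_folds(lab, k = k,
                                seed = sample.int(.Machine$integer.max, 1))
      cross_validate(tab, folds, shrinkage = shrinkage)$median_score
    }, numeric(1))
  })
  list(median = median(scores), scores = scores)
}
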