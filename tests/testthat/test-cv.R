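test_that("balanced accuracy is macro-averaged recall", {
  expect_equal(balanced_accuracy(diag(c(5, 9, 3))), 100)
  expect_equal(balanced_accuracy(rbind(c(8, 2), c(5, 5))), 65)
  expect_error(balanced_accuracy(rbind(c(0, 0), c(1, 1))), "at least one")
  # equals plain accuracy on an exactly balanced confusion
  cm <- rbind(c(7, 3), c(4, 6))
  expect_equal(balanced_accuracy(cm), 100 * sum(diag(cm)) / sum(cm))
})

test_that("stratified folds are balanced, deterministic and guarded", {
  labels <- rep(1:6, each = 50)
  f <- stratified_folds(labels, k = 5, seed = 11)
  expect_identical(f, stratified_folds(labels, k = 5, seed = 11))
  per_fold <- table(f$fold_of_trial)
  expect_true(all(per_fold == 60))
  per_cell <- table(f$fold_of_trial, labels)
  expect_true(all(per_cell == 10))
  # uneven class: counts differ by at most one across folds
  f2 <- stratified_folds(rep(1:2, c(23, 50)), k = 5, seed = 1)
  cnt <- table(f2$fold_of_trial[1:23])
  expect_lte(diff(range(cnt)), 1)
  expect_error(stratified_folds(rep(1:2, c(4, 50)), k = 5, seed = 1),
               "fewer than k")
})

test_that("perfectly separated classes score 100 in every fold", {
  tab <- gaussian_table(10, 4, 3, sep = 40, seed = 8, sd = 0.1)
  cv <- cross_validate(tab, stratified_folds(tab$labels, 5, seed = 8))
  expect_equal(cv$fold_scores, rep(100, 5))
  expect_equal(cv$median_score, 100)
  expect_equal(unclass(cv$confusion), diag(10L, 4),
               ignore_attr = "dimnames")
  expect_equal(rowSums(cv$confusion), rep(10, 4), ignore_attr = TRUE)
})

test_that("CV is invariant to consistent trial permutation", {
  tab <- gaussian_table(10, 3, 4, sep = 2, seed = 14)
  folds <- stratified_folds(tab$labels, 5, seed = 14)
  cv <- cross_validate(tab, folds)
  set.seed(1)
  perm <- sample(nrow(tab$values))
  tab2 <- feature_table(tab$values[perm, ], tab$labels[perm])
  folds2 <- folds
  folds2$fold_of_trial <- folds$fold_of_trial[perm]
  cv2 <- cross_validate(tab2, folds2)
  expect_equal(cv$fold_scores, cv2$fold_scores)
  expect_equal(unclass(cv$confusion), unclass(cv2$confusion))
})

test_that("fold differences require and use paired fold assignments", {
  tab <- gaussian_table(10, 3, 4, sep = 2, seed = 20)
  folds <- stratified_folds(tab$labels, 5, seed = 20)
  cv <- cross_validate(tab, folds)
  self <- fold_difference(cv, cv)
  expect_equal(self$differences, rep(0, 5))
  expect_equal(self$median, 0)
  shifted <- cv
  shifted$fold_scores <- cv$fold_scores + 5
  expect_equal(fold_difference(shifted, cv)$differences, rep(5, 5))
  other <- cross_validate(tab, stratified_folds(tab$labels, 5, seed = 99))
  expect_error(fold_difference(cv, other), "paired")
})

test_that("pair search enumerates all pairs and ranks a planted pair first", {
  tab <- gaussian_table(10, 3, 5, sep = 2, seed = 3)
  folds <- stratified_folds(tab$labels, 5, seed = 3)
  ranking <- pair_search(tab, folds)
  expect_equal(nrow(ranking), choose(5, 2))
  got <- ranking[order(ranking$ch_a, ranking$ch_b), c("ch_a", "ch_b")]
  expect_equal(as.matrix(got), t(combn(5, 2)) - 1L, ignore_attr = TRUE)
  # plant the only informative pair among noise channels
  set.seed(4)
  n <- 60
  lab <- rep(1:3, each = 20)
  X <- matrix(abs(rnorm(n * 6)), n, 6)
  X[, 3] <- abs(rnorm(n, mean = lab, sd = 0.45))
  X[, 5] <- abs(rnorm(n, mean = 4 - lab, sd = 0.45))
  planted <- feature_table(X, lab)
  rk <- pair_search(planted, stratified_folds(lab, 5, seed = 4))
  expect_equal(c(rk$ch_a[1], rk$ch_b[1]), c(2L, 4L))    # 0-based ids
})

test_that("confusion differences follow the stated conventions", {
  a <- confusion_matrix(rep(1:2, each = 10), rep(1:2, each = 10))
  expect_equal(confusion_difference(a, a), matrix(0, 2, 2),
               ignore_attr = TRUE)
  b <- confusion_matrix(rep(1:2, each = 10), rep(rep(1:2, each = 5), 2))
  d <- confusion_difference(a, b)
  expect_equal(unclass(d), rbind(c(0.5, -0.5), c(-0.5, 0.5)),
               ignore_attr = TRUE)
  expect_equal(rowSums(d), c(0, 0), ignore_attr = TRUE, tolerance = 1e-12)
  dc <- confusion_difference(a, b, normalise = FALSE)
  expect_equal(unclass(dc), rbind(c(5, -5), c(-5, 5)), ignore_attr = TRUE)
  expect_error(confusion_difference(a, matrix(0, 3, 3)), "shape")
})
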