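#' Fit a linear discriminant analysis model
#'
#' Gaussian LDA with a pooled within-class covariance (denominator `n - K`)
#' and optional shrinkage toward a scaled identity:
#' `Sigma(lambda) = (1 - lambda) S + lambda mean(diag(S)) I`.
#' Priors are uniform by default — the stimulation design is balanced, and
#' scores are reported balanced anyway.
#'
#' @param table a `feature_table` (raw, not normalised).
#' @param shrinkage lambda in \[0, 1\]; default 0.05 keeps the pooled
#'   covariance well-conditioned when trials are scarce relative to channels.
#' @param priors optional per-class prior probabilities (named or in class-id
#'   order); default uniform.
#' @return an object of class `lda_model`: `class_means` (classes x
#'   channels), `pooled_cov`, `priors`, `shrinkage`, `class_ids` (sorted).
#' @export
fit_lda <- function(table, shrinkage = 0.05, priors = NULL) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  assert_that(is_scalar_num(shrinkage) && shrinkage >= 0 && shrinkage <= 1,
              "shrinkage must lie in [0, 1]")
  X <- table$values
  y <- table$labels
  class_ids <- sort(unique(y))
  K <- length(class_ids)
  assert_that(K >= 2L, "need at least 2 classes")
  n <- nrow(X)
  p <- ncol(X)
  counts <- vapply(class_ids, function(c) sum(y == c), numeric(1))
  assert_that(all(counts >= 2), "every class needs at least 2 trials")
  if (n < p) {
    warning("fewer trials than channels; covariance estimate is weak",
            call. = FALSE)
  }
  mu <- matrix(0, nrow = K, ncol = p)
  for (k in seq_len(K)) {
    mu[k, ] <- colMeans(X[y == class_ids[k], , drop = FALSE])
  }
  Xc <- X - mu[match(y, class_ids), , drop = FALSE]
  S <- crossprod(Xc) / (n - K)
  Sig <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(p)
  ev <- tryCatch(min(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) -Inf)
  if (!(ev > .Machine$double.eps * max(1, mean(diag(Sig))))) {
    stop("shrunk pooled covariance is singular; raise `shrinkage`",
         call. = FALSE)
  }
  if (is.null(priors)) priors <- rep(1 / K, K)
  assert_that(length(priors) == K && abs(sum(priors) - 1) < 1e-9,
              "priors must be one probability per class, summing to 1")
  structure(list(class_means = mu, pooled_cov = Sig, priors = priors,
                 shrinkage = shrinkage, class_ids = class_ids),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> %d classes x %d channels, shrinkage %.3g\n",
              length(x$class_ids), ncol(x$class_means), x$shrinkage))
  invisible(x)
}

#' Predict class labels with a fitted LDA model
#'
#' Assigns `argmax_c delta_c(x)` with the linear discriminant
#' `delta_c(x) = x' Sigma^-1 mu_c - mu_c' Sigma^-1 mu_c / 2 + log pi_c`.
#' Exact ties are broken toward the lowest class id (deterministic).
#'
#' @param model an `lda_model`.
#' @param features matrix of trials x channels (or a `feature_table`).
#' @return numeric vector of predicted class ids.
#' @export
predict_lda <- function(model, features) {
  assert_that(inherits(model, "lda_model"), "model must be an lda_model")
  X <- if (inherits(features, "feature_table")) features$values else
    as.matrix(features)
  assert_that(ncol(X) == ncol(model$class_means),
              "feature dimensionality does not match the model")
  A <- solve(model$pooled_cov, t(model$class_means))   # p x K
  const <- -0.5 * colSums(t(model$class_means) * A) + log(model$priors)
  scores <- X %*% A + rep(const, each = nrow(X))
  # which.max takes the first maximum; class_ids are sorted, so ties go to
  # the lowest class id
  model$class_ids[apply(scores, 1, which.max)]
}
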