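#' Mean absolute value (MAV) of a trial window
#'
#' `MAV_i = mean(|x_i|)` over the window samples of channel *i* — the
#' standard time-domain ENG feature: cheap, robust, and sufficient for
#' linear separation of afferent activity levels.
#'
#' @param window a `trial_window` (or any channels x samples matrix).
#' @return numeric vector, one nonnegative MAV per channel.
#' @export
compute_mav <- function(window) {
  x <- if (inherits(window, "trial_window")) window$samples else as.matrix(window)
  assert_that(length(x) > 0 && ncol(x) > 0, "window must be non-empty")
  rowMeans(abs(x))
}

#' Assemble a labelled MAV feature table
#'
#' @param windows a `trial_windows` list with a common channel count.
#' @return an object of class `feature_table`: list with `values` (trials x
#'   channels MAV matrix), `labels` (class ids), `trial_ids`, `channel_ids`
#'   (0-based) and `normalised = FALSE`.
#' @export
build_feature_table <- function(windows) {
  assert_that(length(windows) >= 1L, "no trial windows supplied")
  nch <- vapply(windows, function(w) nrow(w$samples), integer(1))
  assert_that(length(unique(nch)) == 1L,
              "all windows must share the same channel count")
  values <- t(vapply(windows, compute_mav, numeric(nch[1])))
  values <- matrix(values, nrow = length(windows))
  feature_table(values,
                labels = vapply(windows, `[[`, numeric(1), "class_id"),
                trial_ids = vapply(windows, `[[`, integer(1), "trial_id"))
}

#' Construct a feature table directly from a matrix
#'
#' @param values trials x channels matrix of nonnegative feature values.
#' @param labels per-trial class ids.
#' @param trial_ids optional trial identifiers (default 0-based sequence).
#' @param normalised whether the values are already min-max normalised.
#' @return a `feature_table`.
#' @export
feature_table <- function(values, labels, trial_ids = NULL,
                          normalised = FALSE) {
  values <- as.matrix(values)
  assert_that(nrow(values) == length(labels),
              "labels must align with feature rows")
  assert_that(!anyNA(values), "feature values must not contain NA")
  assert_that(all(values >= 0), "MAV features must be nonnegative")
  if (is.null(trial_ids)) trial_ids <- seq_len(nrow(values)) - 1L
  structure(list(values = values, labels = as.numeric(labels),
                 trial_ids = trial_ids,
                 channel_ids = seq_len(ncol(values)) - 1L,
                 normalised = isTRUE(normalised)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d trials x %d channels, %d classes%s\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels)),
              if (x$normalised) ", normalised" else ""))
  invisible(x)
}

#' Min-max normalise a feature table per channel
#'
#' Scales every channel to \[0, 1\] across trials (constant channels map to
#' 0). Used only for visualisation — scatter plots of the best electrode
#' pair — never as classifier input: LDA is invariant to per-table affine
#' rescaling but not to per-channel rescaling estimated from the full data.
#'
#' @param table a non-normalised `feature_table`.
#' @return a `feature_table` with `normalised = TRUE`.
#' @export
normalize_features <- function(table) {
  assert_that(inherits(table, "feature_table"), "table must be a feature_table")
  assert_that(!table$normalised, "table is already normalised")
  v <- table$values
  rng <- apply(v, 2, range)
  span <- rng[2, ] - rng[1, ]
  out <- sweep(v, 2, rng[1, ], "-")
  out <- sweep(out, 2, ifelse(span > 0, span, 1), "/")
  out[, span == 0] <- 0
  feature_table(out, table$labels, table$trial_ids, normalised = TRUE)
}
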