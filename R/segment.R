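#' Stimulus onsets from recorded event markers
#'
#' Proprioception and touch recordings carry automatically recorded comments
#' (event markers); this returns them verbatim, time-sorted.
#'
#' @param rec a `raw_recording`.
#' @return data frame with columns `time` (s) and `class_id`, sorted by time.
#'   An empty marker list yields a zero-row result with a warning.
#' @export
detect_onsets_from_markers <- function(rec) {
  assert_that(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  mk <- rec$markers
  if (nrow(mk) == 0L) {
    warning("recording has no event markers", call. = FALSE)
    return(mk)
  }
  mk <- mk[order(mk$time), , drop = FALSE]
  rownames(mk) <- NULL
  mk
}

#' Stimulus ON/OFF epochs from a force-sensor trace
#'
#' Used for nociceptive pinches, whose timing is marked by the instrumented
#' forceps rather than by comments. The detection threshold is
#' `median + threshold_k * MAD` of the first second of the trace (assumed
#' baseline); an onset is the first upward crossing sustained for at least
#' 20 ms and the matching offset the next sustained downward crossing.
#' Sub-20 ms dips inside an epoch do not split it.
#'
#' @param fsr numeric force trace.
#' @param fs sampling rate, Hz. The trace must contain at least 1 s of
#'   baseline at the start.
#' @param threshold_k threshold in baseline MADs above the baseline median;
#'   default 5.
#' @return data frame with columns `onset` and `offset` (s), time-ordered;
#'   zero rows when the threshold is never crossed.
#' @export
detect_onsets_from_fsr <- function(fsr, fs, threshold_k = 5) {
  assert_that(is.numeric(fsr) && length(fsr) >= fs,
              "fsr trace must contain at least 1 s of baseline")
  base <- fsr[seq_len(round(fs))]
  thr <- median(base) + threshold_k * mad(base)
  above <- fsr > thr
  min_run <- max(1L, round(0.02 * fs))
  r <- rle(above)
  # merge sub-20 ms dips into the surrounding epoch
  short_gap <- !r$values & r$lengths < min_run
  short_gap[1] <- FALSE
  short_gap[length(short_gap)] <- FALSE
  r$values[short_gap] <- TRUE
  above <- inverse.rle(r)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(onset = (starts[keep] - 1L) / fs, offset = ends[keep] / fs)
}

#' Extract per-trial analysis windows from a filtered recording
#'
#' Window *k* covers the half-open sample interval
#' `[round((onset_k + offset_s) * fs), round((onset_k + offset_s + len_s) * fs))`
#' (0-based indices; round-half-even). A window that would overrun its ON
#' epoch (when the onset table carries `on_s`) or the recording is rejected
#' with a logged reason rather than silently truncated.
#'
#' @param rec a (typically filtered) `raw_recording`.
#' @param onsets data frame with columns `time` (s) and `class_id`, and
#'   optionally `on_s` (epoch ON duration, used to validate the window fits).
#' @param offset_s delay from stimulus onset to window start, s (default
#'   0.25).
#' @param len_s window length, s (0.5 for the ten-class designs, 2.5 for the
#'   six-angle design).
#' @return a list of class `trial_windows`; each element has `samples`
#'   (channels x window samples), `class_id`, `t_start`, `t_len` and a
#'   sequential 0-based `trial_id`. Rejected trials are recorded in
#'   `attr(, "rejected")` (data frame `index`, `reason`).
#' @export
extract_trial_windows <- function(rec, onsets, offset_s = 0.25, len_s) {
  assert_that(inherits(rec, "raw_recording"), "rec must be a raw_recording")
  assert_that(is.data.frame(onsets) &&
                all(c("time", "class_id") %in% names(onsets)),
              "onsets must have columns time and class_id")
  assert_that(is_scalar_num(offset_s) && offset_s >= 0, "offset_s must be >= 0")
  assert_that(is_scalar_num(len_s) && len_s > 0, "len_s must be > 0")
  fs <- rec$fs
  n <- ncol(rec$samples)
  n_win <- round(len_s * fs)
  out <- list()
  rejected <- data.frame(index = integer(), reason = character())
  for (k in seq_len(nrow(onsets))) {
    if (!is.null(onsets$on_s) && offset_s + len_s > onsets$on_s[k] + 1e-9) {
      rejected <- rbind(rejected, data.frame(
        index = k, reason = sprintf("window (%.3g + %.3g s) exceeds ON epoch (%.3g s)",
                                    offset_s, len_s, onsets$on_s[k])))
      next
    }
    s0 <- round((onsets$time[k] + offset_s) * fs)      # 0-based start
    if (s0 < 0 || s0 + n_win > n) {
      rejected <- rbind(rejected, data.frame(
        index = k, reason = "window outside the recording"))
      next
    }
    out[[length(out) + 1L]] <- structure(
      list(samples = rec$samples[, (s0 + 1L):(s0 + n_win), drop = FALSE],
           class_id = onsets$class_id[k],
           t_start = onsets$time[k] + offset_s,
           t_len = len_s,
           trial_id = length(out)),
      class = "trial_window")
  }
  structure(out, class = "trial_windows", rejected = rejected, fs = fs)
}

#' Reject noise-contaminated trials
#'
#' A trial is rejected when, on any channel, its peak absolute amplitude
#' exceeds `median + k_mad * MAD` of that channel's distribution of per-trial
#' peaks. The criterion and `k_mad` are deliberately exposed: the removals it
#' performs are always auditable via the returned ids.
#'
#' @param windows a `trial_windows` list (>= 10 windows).
#' @param k_mad rejection threshold in MADs; default 8. `Inf` disables
#'   rejection.
#' @return list with `kept` (a `trial_windows` list preserving order) and
#'   `rejected_ids` (the `trial_id`s removed).
#' @export
reject_noisy_trials <- function(windows, k_mad = 8) {
  assert_that(length(windows) >= 10L, "need at least 10 windows")
  peaks <- vapply(windows, function(w) apply(abs(w$samples), 1, max),
                  numeric(nrow(windows[[1]]$samples)))
  peaks <- matrix(peaks, ncol = length(windows))   # channels x trials
  med <- apply(peaks, 1, median)
  madv <- apply(peaks, 1, mad)
  bad <- apply(peaks > med + k_mad * madv, 2, any)
  bad[is.na(bad)] <- FALSE
  if (all(bad)) {
    stop("all trials rejected; rejection threshold k_mad = ", k_mad,
         " is misconfigured for these data", call. = FALSE)
  }
  kept <- windows[!bad]
  attributes(kept) <- attributes(windows)[c("class", "fs")]
  list(kept = kept,
       rejected_ids = vapply(windows[bad], `[[`, integer(1), "trial_id"))
}
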