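#' Define a single stimulus class
#'
#' @param label class label, e.g. `"+30deg"`, `"heel_pinch"`.
#' @param modality one of `"proprioception"`, `"nociception"`, `"touch"`.
#' @param on_s stimulus ON duration, seconds.
#' @param off_s rest (stimulus OFF) duration following each application,
#'   seconds.
#' @param angle joint angle in degrees for proprioceptive classes, `NA`
#'   otherwise.
#' @return one-row data frame; combine with [stimulus_classes()].
#' @export
stimulus_class <- function(label, modality, on_s, off_s, angle = NA_real_) {
  assert_that(modality %in% c("proprioception", "nociception", "touch"),
              "unknown modality")
  assert_that(is_scalar_num(on_s) && on_s > 0, "on_s must be > 0")
  assert_that(is_scalar_num(off_s) && off_s > 0, "off_s must be > 0")
  data.frame(label = label, modality = modality, on_s = on_s, off_s = off_s,
             angle = angle)
}

#' Assemble a stimulus class set
#'
#' @param ... one-row data frames from [stimulus_class()].
#' @return a `stimulus_classes` data frame with sequential `class_id`
#'   (1-based) as the first column.
#' @export
stimulus_classes <- function(...) {
  rows <- list(...)
  assert_that(length(rows) >= 1L, "class set must not be empty")
  df <- do.call(rbind, rows)
  assert_that(!anyDuplicated(df$label), "class labels must be unique")
  df <- cbind(class_id = seq_len(nrow(df)), df)
  class(df) <- c("stimulus_classes", "data.frame")
  df
}

validate_stimulus_classes <- function(x) {
  assert_that(is.data.frame(x) && nrow(x) >= 1L,
              "classes must be a non-empty stimulus_classes data frame")
  assert_that(all(c("class_id", "label", "modality", "on_s", "off_s") %in%
                    names(x)), "malformed stimulus class set")
  x
}

#' Canonical proprioceptive class set (six hindpaw angles)
#'
#' The six joint angles -30, -20, -10, +10, +20, +30 degrees; 3 s ON / 3 s OFF
#' by default.
#'
#' @param on_s,off_s ON/OFF durations in seconds.
#' @return a `stimulus_classes` data frame with 6 rows.
#' @export
proprioception_classes <- function(on_s = 3, off_s = 3) {
  angles <- c(-30, -20, -10, 10, 20, 30)
  do.call(stimulus_classes, lapply(angles, function(a) {
    stimulus_class(sprintf("%+ddeg", a), "proprioception", on_s, off_s,
                   angle = a)
  }))
}

#' Canonical ten-class set (proprioception + nociception + touch)
#'
#' Six proprioceptive angles, two nociception sites (heel and toe pinch) and
#' two Von Frey touch classes. In the Experiment-1A arrangement nociception
#' uses 1 s ON / 1 s OFF; elsewhere 3 s / 3 s.
#'
#' @param on_s,off_s default ON/OFF durations (s) for proprioception/touch.
#' @param nociception_on_s,nociception_off_s ON/OFF durations (s) for the two
#'   pinch classes.
#' @return a `stimulus_classes` data frame with 10 rows.
#' @export
full_stimulus_classes <- function(on_s = 3, off_s = 3,
                                  nociception_on_s = 3,
                                  nociception_off_s = 3) {
  pro <- lapply(c(-30, -20, -10, 10, 20, 30), function(a) {
    stimulus_class(sprintf("%+ddeg", a), "proprioception", on_s, off_s,
                   angle = a)
  })
  rest <- list(
    stimulus_class("heel_pinch", "nociception", nociception_on_s,
                   nociception_off_s),
    stimulus_class("toe_pinch", "nociception", nociception_on_s,
                   nociception_off_s),
    stimulus_class("touch_heavy", "touch", on_s, off_s),
    stimulus_class("touch_light", "touch", on_s, off_s)
  )
  do.call(stimulus_classes, c(pro, rest))
}

#' Generate a pseudo-randomised stimulation protocol
#'
#' Within each block every class appears exactly `reps_per_block` times in a
#' seeded pseudo-random order; events are laid end-to-end, each occupying its
#' class's ON duration followed by its OFF duration. One proprioceptive block
#' with the canonical six angles and ten repetitions therefore contains 60
#' movements.
#'
#' @param classes a `stimulus_classes` data frame.
#' @param reps_per_block repetitions of each class within a block (>= 1).
#' @param n_blocks number of blocks (>= 1).
#' @param seed integer seed controlling the order; identical seeds reproduce
#'   the protocol exactly.
#' @return an object of class `stim_protocol`: list with `events` (data frame
#'   `class_id`, `onset`, `on_s`, `off_s`; onsets in seconds from recording
#'   start, before any lead-in), `classes` and `seed`.
#' @export
generate_protocol <- function(classes, reps_per_block, n_blocks = 1L, seed) {
  classes <- validate_stimulus_classes(classes)
  assert_that(is_scalar_num(reps_per_block) && reps_per_block >= 1,
              "reps_per_block must be >= 1")
  assert_that(is_scalar_num(n_blocks) && n_blocks >= 1, "n_blocks must be >= 1")
  order_ids <- with_seed(seed, {
    unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(classes$class_id, reps_per_block))
    }))
  })
  idx <- match(order_ids, classes$class_id)
  on_s <- classes$on_s[idx]
  off_s <- classes$off_s[idx]
  onset <- cumsum(c(0, head(on_s + off_s, -1)))
  events <- data.frame(class_id = order_ids, onset = onset,
                       on_s = on_s, off_s = off_s)
  structure(list(events = events, classes = classes, seed = as.integer(seed)),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %d events, %d classes, duration %.1f s, seed %d\n",
              nrow(x$events), nrow(x$classes),
              protocol_duration(x), x$seed))
  invisible(x)
}

#' Total protocol duration in seconds (without lead-in)
#' @param protocol a `stim_protocol`.
#' @return numeric seconds.
#' @export
protocol_duration <- function(protocol) {
  ev <- protocol$events
  if (nrow(ev) == 0L) return(0)
  max(ev$onset + ev$on_s + ev$off_s)
}
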