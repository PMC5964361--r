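test_that("marker onsets are returned verbatim and time-sorted", {
  mk <- data.frame(time = c(3.2, 1.1, 2.5), class_id = c(3, 1, 2))
  rec <- wrap_recording(matrix(0, 3, 30000 * 4), markers = mk)
  out <- detect_onsets_from_markers(rec)
  expect_equal(out$time, sort(mk$time))
  expect_equal(out$class_id, c(1, 2, 3))
  empty <- wrap_recording(matrix(0, 3, 100))
  expect_warning(out0 <- detect_onsets_from_markers(empty), "no event markers")
  expect_equal(nrow(out0), 0L)
})

test_that("a block of 60 markers segments into 60 trials", {
  cls <- proprioception_classes(on_s = 0.3, off_s = 0.1)
  p <- generate_protocol(cls, 10, 1, seed = 6)
  rec <- synthesize_recording(p, build_cuff_layout("cuff3"),
                              default_nerve_site("distal", cls),
                              fs = 6000, seed = 6)
  on <- detect_onsets_from_markers(rec)
  expect_equal(nrow(on), 60L)
  wins <- extract_trial_windows(rec, on, offset_s = 0.05, len_s = 0.2)
  expect_length(wins, 60L)
})

test_that("FSR segmentation matches threshold-crossing construction", {
  expect_equal(nrow(detect_onsets_from_fsr(rep(0, 5000), 1000)), 0L)
  # hand-built trace: two 1 s plateaus with 50 ms ramps at t = 2 s and 5 s
  fs <- 1000
  tr <- rep(0, 8 * fs)
  ramp <- function(t0) {
    on <- round(t0 * fs); n <- fs
    tr[(on + 1):(on + n)] <<- pmin(1, pmin(seq_len(n), rev(seq_len(n))) / 50)
  }
  ramp(2); ramp(5)
  det <- detect_onsets_from_fsr(tr, fs)
  expect_equal(nrow(det), 2L)
  expect_lt(max(abs(det$onset - c(2, 5))), 0.06)
  expect_true(det$offset[1] < det$onset[2])
})

test_that("marker- and FSR-based segmentation agree on simulated nociception", {
  cls <- stimulus_classes(stimulus_class("pinch", "nociception", 1, 1))
  p <- generate_protocol(cls, 5, 1, seed = 12)
  rec <- synthesize_recording(p, build_cuff_layout("cuff3"),
                              single_fascicle_site(1), fs = 6000, seed = 12)
  mk <- detect_onsets_from_markers(rec)
  fsr <- detect_onsets_from_fsr(rec$fsr, rec$fs)
  expect_equal(nrow(fsr), nrow(mk))
  expect_lt(max(abs(fsr$onset - mk$time)), 0.06)
})

test_that("window extraction follows the sample-index convention exactly", {
  fs <- 30000
  n <- round(6 * fs)
  x <- matrix(seq_len(3 * n), nrow = 3)      # distinguishable samples
  rec <- wrap_recording(x, fs)
  on <- data.frame(time = 5.0, class_id = 4)
  wins <- extract_trial_windows(rec, on, offset_s = 0.25, len_s = 0.5)
  expect_length(wins, 1L)
  w <- wins[[1]]
  expect_equal(ncol(w$samples), 15000L)
  # 0-based half-open [157500, 172500) -> R columns 157501:172500
  expect_identical(w$samples, x[, 157501:172500])
  expect_equal(w$class_id, 4)
  expect_equal(w$trial_id, 0L)
})

test_that("windows overrunning their ON epoch or the recording are rejected", {
  fs <- 1000
  rec <- wrap_recording(matrix(0, 3, 10 * fs), fs)
  on <- data.frame(time = c(1, 8.9), class_id = c(1, 2), on_s = c(1, 3))
  # trial 2's window would overrun the recording; a 2.5 s window can never
  # fit a 1 s epoch
  wins <- extract_trial_windows(rec, on, offset_s = 0.25, len_s = 0.5)
  expect_length(wins, 2L)
  bad <- extract_trial_windows(rec, on, offset_s = 0.25, len_s = 2.5)
  expect_length(bad, 0L)
  expect_equal(attr(bad, "rejected")$index, c(1L, 2L))
  expect_match(attr(bad, "rejected")$reason[1], "exceeds ON epoch")
  # boundary case: offset 0, window exactly the epoch length is accepted
  ok <- extract_trial_windows(rec, on[1, ], offset_s = 0, len_s = 1)
  expect_length(ok, 1L)
})

test_that("rejection flags exactly the contaminated trials", {
  make_wins <- function(seed, spike_in = NULL) {
    set.seed(seed)
    rec <- wrap_recording(matrix(rnorm(3 * 12 * 200), nrow = 3), fs = 1000)
    if (!is.null(spike_in)) {
      rec$samples[2, (spike_in - 1) * 200 + 57] <- 100
    }
    on <- data.frame(time = (0:11) * 0.2, class_id = rep(1:2, 6))
    extract_trial_windows(rec, on, offset_s = 0, len_s = 0.2)
  }
  # homogeneous Gaussian trials: the false-rejection rate at k_mad = 8 stays
  # below 0.5% over 20 seeds (peak amplitudes are Gumbel-tailed, so a strict
  # zero is not a theorem; see the methods vignette)
  n_rej <- vapply(1:20, function(s) {
    length(reject_noisy_trials(make_wins(s), k_mad = 8)$rejected_ids)
  }, numeric(1))
  expect_lte(sum(n_rej), 0.005 * 20 * 12)
  # a single 100x spike is caught, and only it
  out <- reject_noisy_trials(make_wins(1, spike_in = 5))
  expect_equal(out$rejected_ids, 4L)            # 0-based trial id
  expect_length(out$kept, 11L)
  # infinite threshold disables rejection
  expect_length(reject_noisy_trials(make_wins(1, 5), k_mad = Inf)$rejected_ids,
                0L)
  expect_error(reject_noisy_trials(make_wins(1)[1:4]), "at least 10")
})

test_that("window extraction reads nothing outside the declared interval", {
  fs <- 1000
  x <- matrix(1e6, 3, 5 * fs)                   # sentinel everywhere
  x[, 2001:2500] <- 0                           # clean only [2.0, 2.5) s
  rec <- wrap_recording(x, fs)
  w <- extract_trial_windows(rec, data.frame(time = 1.75, class_id = 1),
                             offset_s = 0.25, len_s = 0.5)[[1]]
  expect_true(all(w$samples == 0))
})
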