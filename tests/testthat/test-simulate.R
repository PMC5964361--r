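test_that("degenerate source-free recording is pure white noise", {
  cls <- tiny_classes()
  p <- generate_protocol(cls, 3, 1, seed = 1)
  site <- single_fascicle_site(c(0, 0), baseline_gain = 0)
  rec <- synthesize_recording(p, build_cuff_layout("cuff3"), site,
                              noise_sd = 1, fs = 6000, seed = 5)
  n <- ncol(rec$samples)
  se <- 1 / sqrt(2 * n)          # SE of a Gaussian sd estimate
  for (i in 1:3) expect_lt(abs(sd(rec$samples[i, ]) - 1), 3 * se)
  expect_equal(nrow(rec$markers), nrow(p$events))
})

test_that("stronger gains raise the expected ON-window MAV on every channel", {
  cls <- tiny_classes()
  p <- generate_protocol(cls, 50, 1, seed = 2)   # 50 trials per class
  site <- single_fascicle_site(c(1, 3))
  rec <- synthesize_recording(p, build_cuff_layout("cuff3"), site,
                              noise_sd = 0.2, fs = 6000, seed = 3,
                              gain_jitter_sd = 0, channel_jitter_sd = 0)
  on <- detect_onsets_from_markers(rec)
  tab <- build_feature_table(extract_trial_windows(rec, on, 0, 0.3))
  m1 <- colMeans(tab$values[tab$labels == 1, ])
  m2 <- colMeans(tab$values[tab$labels == 2, ])
  expect_true(all(m2 > m1))
})

test_that("expected MAV is monotone in each gain entry (common random numbers)", {
  cls <- tiny_classes()
  p <- generate_protocol(cls, 20, 1, seed = 4)
  mav_means <- function(g) {
    site <- single_fascicle_site(g)
    rec <- synthesize_recording(p, build_cuff_layout("cuff3"), site,
                                noise_sd = 0.2, fs = 6000, seed = 11,
                                gain_jitter_sd = 0, channel_jitter_sd = 0)
    on <- detect_onsets_from_markers(rec)
    tab <- build_feature_table(extract_trial_windows(rec, on, 0, 0.3))
    colMeans(tab$values)
  }
  base <- mav_means(c(1, 2))
  bumped <- mav_means(c(1.5, 2))   # raise one entry, same seed
  expect_true(all(bumped >= base - 1e-9))
})

test_that("sessions are bit-reproducible and share sources across cuffs", {
  cls <- proprioception_classes(on_s = 0.3, off_s = 0.1)
  p <- generate_protocol(cls, 2, 1, seed = 9)
  cuffs <- list(
    distal = list(layout = build_cuff_layout("cuff16"),
                  site = default_nerve_site("distal", cls)),
    proximal = list(layout = build_cuff_layout("cuff16"),
                    site = default_nerve_site("proximal", cls)))
  s1 <- simulate_session(p, cuffs, fs = 6000, seed = 21)
  s2 <- simulate_session(p, cuffs, fs = 6000, seed = 21)
  expect_identical(s1, s2)
  # with contact noise and channel jitter off, recordings are deterministic
  # functions of the shared source draws: same sources, different mixing
  clean <- simulate_session(p, cuffs, fs = 6000, seed = 21, noise_sd = 0,
                            channel_jitter_sd = 0)
  W_d <- compute_pickup_weights(cuffs$distal$layout, cuffs$distal$site)
  W_p <- compute_pickup_weights(cuffs$proximal$layout, cuffs$proximal$site)
  # both recordings must be exact linear images of one source matrix:
  # solve for sources from the distal cuff and predict the proximal one
  M_hat <- qr.solve(W_d, clean$distal$samples)
  expect_equal(W_p %*% M_hat, clean$proximal$samples, tolerance = 1e-8)
})

test_that("mismatched gain matrices are rejected", {
  cls <- tiny_classes()
  p <- generate_protocol(cls, 2, 1, seed = 1)
  site_bad <- single_fascicle_site(c(1, 2, 3))   # 3 classes vs 2 in protocol
  expect_error(
    synthesize_recording(p, build_cuff_layout("cuff3"), site_bad,
                         fs = 6000, seed = 1),
    "gain_matrix class dimension")
  # sampling rate below twice the source band edge
  expect_error(
    synthesize_recording(p, build_cuff_layout("cuff3"),
                         single_fascicle_site(c(1, 2)), fs = 4000, seed = 1),
    "twice the upper source band")
})

test_that("FSR trace marks nociception epochs and nothing else", {
  cls <- stimulus_classes(
    stimulus_class("pinch", "nociception", 1, 1),
    stimulus_class("angle", "proprioception", 1, 1, angle = 10))
  p <- generate_protocol(cls, 2, 1, seed = 31)
  fs <- 1000
  tr <- synthesize_fsr_trace(p, fs = fs, seed = 31, lead_in_s = 2)
  expect_identical(tr, synthesize_fsr_trace(p, fs = fs, seed = 31,
                                            lead_in_s = 2))
  det <- detect_onsets_from_fsr(tr, fs = fs)
  ev <- p$events
  noci_onsets <- 2 + ev$onset[ev$class_id == 1]
  expect_equal(nrow(det), 2L)                        # two plateaus
  expect_true(all(det$offset[-nrow(det)] < det$onset[-1]))
  expect_lt(max(abs(sort(det$onset) - sort(noci_onsets))), 0.06)
  # no nociception events -> flat noisy trace
  p2 <- generate_protocol(tiny_classes(), 2, 1, seed = 1)
  tr2 <- synthesize_fsr_trace(p2, fs = fs, seed = 1)
  expect_lt(max(abs(tr2)), 0.1)
})
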