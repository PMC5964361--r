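# Small builders shared across test files. Everything is generated in code;
# no stored fixtures.

# two quick classes with short epochs, for simulator unit tests
tiny_classes <- function(on_s = 0.3, off_s = 0.1) {
  stimulus_classes(
    stimulus_class("weak", "proprioception", on_s, off_s, angle = 10),
    stimulus_class("strong", "proprioception", on_s, off_s, angle = 30)
  )
}

# a single-fascicle site with an explicit 1 x K gain row
single_fascicle_site <- function(gains, baseline_gain = 0) {
  nerve_site_model("distal",
                   fascicles = list(fascicle_spec("only", c(0.2, 0), 0.1)),
                   gain_matrix = matrix(gains, nrow = 1),
                   baseline_gain = baseline_gain)
}

# a raw_recording wrapping an arbitrary channels x samples matrix on cuff3
wrap_recording <- function(samples, fs = 30000, markers = NULL) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) == 3)
  if (is.null(markers)) {
    markers <- data.frame(time = numeric(), class_id = numeric())
  }
  raw_recording(samples, fs = fs, markers = markers,
                layout = build_cuff_layout("cuff3"))
}

# MAV feature table with K well-separated Gaussian classes (trials x p)
gaussian_table <- function(n_per_class, K, p, sep, seed, sd = 1) {
  with_seed <- cuffsep:::with_seed
  with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(K), function(k) {
      mu <- rep(0, p)
      mu[(k - 1) %% p + 1] <- sep * k
      matrix(rnorm(n_per_class * p, sd = sd), n_per_class, p) +
        rep(mu, each = n_per_class)
    }))
    feature_table(abs(X) + 1e-9, labels = rep(seq_len(K), each = n_per_class))
  })
}

# 10-class / 6-class desk-scale MAV tables from a real simulated recording
desk_feature_table <- function(n_classes = c(10, 6), seed = 1) {
  n_classes <- match.arg(as.character(n_classes[1]), c("10", "6"))
  classes <- if (n_classes == "10") {
    full_stimulus_classes(on_s = 0.7, off_s = 0.25)
  } else {
    proprioception_classes(on_s = 0.7, off_s = 0.25)
  }
  protocol <- generate_protocol(classes, reps_per_block = 6, n_blocks = 1,
                                seed = seed)
  site <- default_nerve_site("distal", classes)
  rec <- synthesize_recording(protocol, build_cuff_layout("cuff16"), site,
                              fs = 4800, seed = seed,
                              source_band = c(300, 2400))
  taps <- design_bandpass_fir(800, 2200, 4800, 101)
  filt <- apply_filter(rec, taps)
  onsets <- detect_onsets_from_markers(filt)
  onsets$on_s <- classes$on_s[match(onsets$class_id, classes$class_id)]
  build_feature_table(extract_trial_windows(filt, onsets, 0.25, 0.4))
}
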