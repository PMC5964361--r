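#' Construct a raw multichannel recording object
#'
#' @param samples numeric matrix, channels x samples, nominal microvolts.
#' @param fs sampling rate, Hz.
#' @param markers data frame with columns `time` (s) and `class_id`; one row
#'   per stimulus onset. May have zero rows.
#' @param layout the `cuff_layout` that produced the channels.
#' @param fsr optional force-sensor trace (length = number of samples).
#' @param meta free-form provenance list (seed, site, config echo, ...).
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, markers, layout, fsr = NULL,
                          meta = list()) {
  samples <- as.matrix(samples)
  assert_that(is_scalar_num(fs) && fs > 0, "fs must be > 0")
  validate_cuff_layout(layout)
  assert_that(nrow(samples) == n_channels(layout),
              "samples must have one row per layout contact")
  assert_that(is.data.frame(markers) &&
                all(c("time", "class_id") %in% names(markers)),
              "markers must be a data frame with columns time, class_id")
  dur <- ncol(samples) / fs
  assert_that(nrow(markers) == 0L ||
                all(markers$time >= 0 & markers$time <= dur),
              "marker times must lie within the recording")
  if (!is.null(fsr)) {
    assert_that(length(fsr) == ncol(samples),
                "fsr trace must have the same length as the samples")
  }
  structure(list(samples = samples, fs = fs, markers = markers,
                 layout = layout, fsr = fsr, meta = meta),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d ch x %d samples (%.1f s at %g Hz), %d markers%s\n",
              nrow(x$samples), ncol(x$samples), ncol(x$samples) / x$fs, x$fs,
              nrow(x$markers), if (is.null(x$fsr)) "" else ", FSR trace"))
  invisible(x)
}

# Band-limited unit-variance Gaussian processes, one column per source.
# White Gaussian noise is masked in the frequency domain to [band[1], band[2]]
# Hz and rescaled by the kept spectral fraction so each process has unit
# variance in expectation. Uses the current RNG stream.
band_limited_sources <- function(n_src, n_samp, fs, band) {
  z <- matrix(rnorm(n_samp * n_src), nrow = n_samp, ncol = n_src)
  f <- (seq_len(n_samp) - 1) * fs / n_samp
  f <- pmin(f, fs - f)                      # fold to [0, fs/2]
  keep <- f >= band[1] & f <= band[2]
  frac <- sum(keep) / n_samp
  assert_that(frac > 0, "source band keeps no frequency bins")
  Z <- mvfft(z)
  Z[!keep, ] <- 0
  x <- Re(mvfft(Z, inverse = TRUE)) / n_samp
  x / sqrt(frac)
}

# Per-fascicle modulated source activity a_f(t) * b_f(t), fascicles x samples.
# The envelope is baseline_gain during OFF and baseline_gain +
# gain_matrix[f, c] * jitter[event, f] during the ON epoch of class c, where
# jitter is lognormal(0, sdlog = gain_jitter_sd) per event and fascicle
# (trial-to-trial afferent variability). Uses the current RNG stream.
source_activity <- function(protocol, site, fs, n_samp, lead_in_s,
                            source_band, gain_jitter_sd) {
  G <- site$gain_matrix
  nf <- nrow(G)
  ev <- protocol$events
  assert_that(ncol(G) == nrow(protocol$classes),
              "gain_matrix class dimension does not match the protocol classes")
  B <- t(band_limited_sources(nf, n_samp, fs, source_band))
  jit <- matrix(exp(rnorm(nrow(ev) * nf, 0, gain_jitter_sd)),
                nrow = nrow(ev), ncol = nf)
  A <- matrix(site$baseline_gain, nrow = nf, ncol = n_samp)
  for (k in seq_len(nrow(ev))) {
    s0 <- round((lead_in_s + ev$onset[k]) * fs)
    s1 <- round((lead_in_s + ev$onset[k] + ev$on_s[k]) * fs)
    idx <- (s0 + 1):min(s1, n_samp)
    cls <- match(ev$class_id[k], protocol$classes$class_id)
    A[, idx] <- site$baseline_gain + G[, cls] * jit[k, ]
  }
  A * B
}

# FSR trace for the nociception events of a protocol: 50 ms linear rise,
# plateau amplitude drawn uniformly in [0.8, 1.2], 50 ms fall; baseline noise
# sd 0.01 of the nominal plateau. Uses the current RNG stream.
fsr_trace_impl <- function(protocol, fs, n_samp, lead_in_s) {
  trace <- rnorm(n_samp, 0, 0.01)
  ev <- protocol$events
  cls <- protocol$classes
  noci <- cls$class_id[cls$modality == "nociception"]
  ramp_n <- max(1L, round(0.05 * fs))
  for (k in seq_len(nrow(ev))) {
    if (!(ev$class_id[k] %in% noci)) next
    amp <- runif(1, 0.8, 1.2)
    s0 <- round((lead_in_s + ev$onset[k]) * fs)
    s1 <- round((lead_in_s + ev$onset[k] + ev$on_s[k]) * fs)
    n_on <- s1 - s0
    prof <- amp * pmin(1, pmin(seq_len(n_on), rev(seq_len(n_on))) / ramp_n)
    idx <- (s0 + 1):min(s1, n_samp)
    trace[idx] <- trace[idx] + prof[seq_along(idx)]
  }
  trace
}

#' Simulate one recording session seen by one or more cuffs
#'
#' All cuffs observe the same fascicular source processes (the same nerve,
#' the same trial-to-trial gain jitter) but mix them through their own pickup
#' weights and receive independent per-contact noise. This honours the paired
#' design in which a distal and a proximal cuff record the same trials
#' simultaneously.
#'
#' @param protocol a [generate_protocol()] result.
#' @param cuffs named list; each element is `list(layout = <cuff_layout>,
#'   site = <nerve_site_model>)`. All sites must share the same fascicle
#'   count and gain matrix.
#' @param noise_sd per-contact additive white-noise standard deviation,
#'   microvolts. Default 0.5.
#' @param fs sampling rate, Hz (default 30000). Must be at least twice the
#'   upper source band edge.
#' @param seed integer seed; the entire session (sources, jitter, noise, FSR)
#'   is reproducible from it.
#' @param lead_in_s rest lead-in prepended before the first event so filters
#'   settle (default 1 s).
#' @param gain_jitter_sd lognormal sdlog of per-trial, per-fascicle gain
#'   jitter (default 0.3).
#' @param channel_jitter_sd lognormal sdlog of per-trial, per-contact gain
#'   instability (electrode impedance drift; default 0.1). Applied to the
#'   neural signal picked up by each contact, independently per cuff; this
#'   is what keeps weak spatial contrasts (nearly concentric fascicles)
#'   from being recoverable by averaging many channels.
#' @param source_band fascicular source band in Hz, default c(300, 3000) —
#'   brackets the 800–2200 Hz analysis band.
#' @return named list of `raw_recording`, one per cuff.
#' @export
simulate_session <- function(protocol, cuffs, noise_sd = 0.5, fs = 30000,
                             seed, lead_in_s = 1,
                             gain_jitter_sd = 0.3,
                             channel_jitter_sd = 0.1,
                             source_band = c(300, 3000)) {
  assert_that(inherits(protocol, "stim_protocol"), "protocol must be a stim_protocol")
  assert_that(is.list(cuffs) && length(cuffs) >= 1L, "cuffs must be a non-empty list")
  assert_that(fs >= 2 * source_band[2],
              "fs must be at least twice the upper source band edge")
  sites <- lapply(cuffs, `[[`, "site")
  G0 <- sites[[1]]$gain_matrix
  for (s in sites) {
    assert_that(identical(dim(s$gain_matrix), dim(G0)) &&
                  max(abs(s$gain_matrix - G0)) < 1e-12,
                "all cuffs in a session must share the same gain matrix")
  }
  n_samp <- round((lead_in_s + protocol_duration(protocol)) * fs)
  has_noci <- any(protocol$classes$modality == "nociception")
  markers <- data.frame(time = lead_in_s + protocol$events$onset,
                        class_id = protocol$events$class_id)
  with_seed(seed, {
    M <- source_activity(protocol, sites[[1]], fs, n_samp, lead_in_s,
                         source_band, gain_jitter_sd)
    fsr <- if (has_noci) fsr_trace_impl(protocol, fs, n_samp, lead_in_s) else NULL
    ev <- protocol$events
    out <- lapply(seq_along(cuffs), function(k) {
      layout <- cuffs[[k]]$layout
      W <- compute_pickup_weights(layout, sites[[k]])
      nch <- nrow(W)
      X <- W %*% M
      if (channel_jitter_sd > 0) {
        cj <- matrix(exp(rnorm(nrow(ev) * nch, 0, channel_jitter_sd)),
                     nrow = nrow(ev), ncol = nch)
        for (e in seq_len(nrow(ev))) {
          s0 <- round((lead_in_s + ev$onset[e]) * fs)
          s1 <- round((lead_in_s + ev$onset[e] + ev$on_s[e] + ev$off_s[e]) * fs)
          idx <- (s0 + 1):min(s1, n_samp)
          X[, idx] <- X[, idx] * cj[e, ]
        }
      }
      X <- X + matrix(rnorm(nch * n_samp, 0, noise_sd),
                      nrow = nch, ncol = n_samp)
      raw_recording(X, fs = fs, markers = markers, layout = layout, fsr = fsr,
                    meta = list(seed = as.integer(seed),
                                site = sites[[k]]$site,
                                cuff = layout$name,
                                noise_sd = noise_sd,
                                gain_jitter_sd = gain_jitter_sd,
                                channel_jitter_sd = channel_jitter_sd,
                                lead_in_s = lead_in_s))
    })
    names(out) <- names(cuffs)
    out
  })
}

#' Synthesize one multichannel cuff recording
#'
#' Convenience wrapper around [simulate_session()] for a single cuff. The
#' recorded signal on contact *i* is
#' `x_i(t) = sum_f w[i, f] a_f(t) b_f(t) + n_i(t)`
#' with `b_f` independent unit-variance Gaussian processes band-limited to
#' `source_band`, `a_f` the class-gain envelope (baseline during OFF), and
#' `n_i` white Gaussian contact noise.
#'
#' @inheritParams simulate_session
#' @param layout a `cuff_layout`.
#' @param site a `nerve_site_model`.
#' @return a `raw_recording` (with an FSR trace when the protocol contains
#'   nociception events).
#' @export
synthesize_recording <- function(protocol, layout, site, noise_sd = 0.5,
                                 fs = 30000, seed, lead_in_s = 1,
                                 gain_jitter_sd = 0.3,
                                 channel_jitter_sd = 0.1,
                                 source_band = c(300, 3000)) {
  simulate_session(protocol,
                   cuffs = list(rec = list(layout = layout, site = site)),
                   noise_sd = noise_sd, fs = fs, seed = seed,
                   lead_in_s = lead_in_s, gain_jitter_sd = gain_jitter_sd,
                   channel_jitter_sd = channel_jitter_sd,
                   source_band = source_band)[[1]]
}

#' Synthesize a force-sensitive-resistor (FSR) trace for a protocol
#'
#' The instrumented forceps signal used to delimit nociceptive pinches:
#' near-zero baseline (noise sd 0.01 of the plateau scale), and within each
#' nociception ON epoch a 50 ms linear rise to a per-event plateau drawn in
#' \[0.8, 1.2\] followed by a 50 ms fall. Non-nociception events contribute
#' nothing; a protocol without nociception yields a flat noisy trace.
#'
#' @inheritParams simulate_session
#' @return numeric vector of length `round((lead_in_s + duration) * fs)`.
#' @export
synthesize_fsr_trace <- function(protocol, fs, seed, lead_in_s = 1) {
  n_samp <- round((lead_in_s + protocol_duration(protocol)) * fs)
  with_seed(seed, fsr_trace_impl(protocol, fs, n_samp, lead_in_s))
}
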