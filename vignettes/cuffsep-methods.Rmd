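---
title: "Methods: simulating and decoding multichannel nerve-cuff ENG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding multichannel nerve-cuff ENG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuffsep)
```

## The scientific question

Extraneural cuff electrodes record whole-nerve afferent activity (ENG)
stably for long periods, which makes them attractive sensors for closed-loop
sensorimotor prostheses. Two design questions dominate: does adding contacts
to a cuff (a 16-channel concentric cuff versus a simple 3-ring cuff) buy
enough separability to justify the added complexity, and does it matter
*where* along the nerve the cuff sits? The sciatic nerve is effectively
unifascicular proximally and splits into tibial, peroneal and sural
divisions distally, so a distal cuff faces spatially segregated sources
while a proximal cuff faces a nearly homogeneous one.

`cuffsep` implements the complete offline analysis used to answer these
questions — mean-absolute-value (MAV) features, linear discriminant analysis
(LDA), stratified balanced five-fold cross-validation, exhaustive
electrode-pair search, paired cuff/site comparisons — together with a
forward simulator that reproduces the *spatial and statistical structure*
the analysis relies on. The raw animal recordings behind the original
comparisons were never deposited, so animal-specific accuracies are not
reproducible; what is reproducible, and what the test suite checks, are the
analytic quantities (chance levels, design sizes, filter responses, Bayes
rates) and the qualitative orderings (distal > proximal; channel count pays
off distally).

## Forward model

### Geometry and pickup

A cuff layout places point contacts (16-channel cuff: 4 rings x 4 contacts,
90 degrees apart, 4.25 mm x 1.0 mm ID) or full-ring contacts (3-channel
cuff: 3 rings, 1 mm apart) on the inner cylinder. Each fascicle *f* is a
disc in the cross-section; contact *i* receives its activity with weight

$$ w_{if} = \left( \frac{d_0}{d_0 + d_{if}} \right)^{\gamma}, $$

where $d_{if}$ is the in-plane distance from the contact (on the circle of
radius 0.5 mm) to the fascicle centre. Ring contacts average this weight
over 36 equally spaced angular positions (< 0.1 % error versus a continuous
ring; verified against a 3600-point quadrature in the tests). This is a
bounded, monotone stand-in for a lead field, not a volume-conductor
solution.

**Choice of $d_0$ and $\gamma$.** The behavioural contract is that with the
distal geometry (fascicle centres at $(\pm 0.3, 0)$ mm) the
tibial/peroneal weight ratio must vary across the four contacts of a ring
by at least a factor 2, while with the proximal geometry ($(\pm 0.05, 0)$
mm) it must vary by no more than 1.2 — the 16-channel cuff can "see" the
fascicles only where they are separated. With $\gamma = 2$, both bounds are
satisfiable only for $d_0$ between roughly 1.7 and 3.0 mm; a smaller,
seemingly more physical softening constant (e.g. 0.1 mm) makes even the
almost-concentric proximal geometry strongly selective (ratio spread 1.95)
and breaks the proximal contract. The package therefore defaults to
$d_0 = 2.0$ mm, $\gamma = 2$ (distal spread 2.62, proximal 1.17). Since the
model is phenomenological, $d_0$ is a shape parameter of the decay, not a
tissue property.

### Sources, gains and trial variability

Each fascicle carries an independent unit-variance Gaussian process
band-limited to 300–3000 Hz — deliberately wider than the 800–2200 Hz
analysis band, so the bandpass filter removes some but not all source
power. During the ON epoch of class $c$ the envelope of fascicle $f$ is
$\alpha_0 + g_{fc}$, during OFF it is the rest baseline $\alpha_0 = 0.1$.
The default proprioceptive gains encode the two effects seen in real
feature spaces: $g_{f,\theta} = (|\theta|/30)\,(1 + [\text{fascicle
matches sign}(\theta)])$, with tibial matched to negative and peroneal to
positive angles — so larger excursions raise MAV on *all* electrodes
(magnitude code), while the MAV *ratio* between electrodes distinguishes
positive from negative angles (spatial code, available only where the
pickup weights differ). Nociception and touch drive a third
(sural/cutaneous) fascicle with fixed gains (heel pinch 1.5, toe pinch 1.0,
heavy touch 0.5, light touch 0.3).

Two variability terms make the class-conditional feature distributions
realistic rather than degenerate:

* **per-trial, per-fascicle gain jitter** (lognormal, sdlog 0.3) — the
  trial-to-trial variability of the afferent volley;
* **per-trial, per-contact gain instability** (lognormal, sdlog 0.1) —
  electrode impedance drift.

Both are essential, and the second deserves emphasis. The MAV of a window
containing $N_\mathrm{eff} \approx 2\,BW\,T$ effectively independent
samples has a relative standard error of about
$\sqrt{(\pi/2 - 1)/N_\mathrm{eff}}$ — roughly 2–3 % for the windows used
here. Without contact-level variability, *any* systematic spatial contrast
larger than that, including the 5 % proximal ratio contrast, is recoverable
by an LDA with 16 channels, and every configuration saturates at 100 %.
With 10 % contact-gain drift, the weak proximal spatial code drowns while
the strong distal one (~30 % contrasts) survives — which is exactly the
published phenomenology: proximal cuffs separate stimulus *magnitude* but
confuse angle *sign*; distal multi-contact cuffs separate both. The values
0.3 and 0.1 were fixed once, on plausibility grounds, before the
qualitative acceptance checks were run.

Additive white contact noise (default 0.5 µV nominal) completes the model:
$x_i(t) = \sum_f w_{if}\, a_f(t)\, b_f(t) + n_i(t)$. Absolute scale is
irrelevant downstream (MAV and LDA are scale-covariant), so no calibration
is attempted.

### Protocols and paired sessions

`generate_protocol()` lays pseudo-randomised blocks end-to-end: within each
block every class appears exactly `reps_per_block` times in a seeded
order. The canonical designs are ten classes (six angles, two pinches, two
Von Frey touches) with 0.5 s analysis windows, and six angles with 2.5 s
windows; 3 s ON / 3 s OFF epochs (1 s/1 s for the ten-class design's
pinches), ten repetitions per block, five blocks. One proprioceptive block
is 60 movements; a six-angle session is 300 trials.

`simulate_session()` gives every cuff of a session the *same* source
processes and jitter draws and independent contact noise — the two cuffs
record the same trials simultaneously, which is what licenses per-fold
score differences. A 1 s rest lead-in precedes the first event so the
filter settles.

## Preprocessing

* **Filter.** Windowed-sinc (Hamming) FIR, 800–2200 Hz, 401 taps at
  30 kHz, applied zero-phase (group delay compensated by shifting
  $(M-1)/2$ samples), so window timing is exact. The taps are DC-corrected
  (mean subtracted) so a constant input is nulled exactly. The design meets
  ±0.5 dB over 900–2100 Hz and > 40 dB attenuation at 100 Hz and 10 kHz;
  the original analysis names only the band, so design method, order and
  phase handling are package choices, and no result depends on them beyond
  these response tolerances.
* **Segmentation.** Proprioception/touch onsets come from recorded event
  markers, returned verbatim; pinch epochs come from the force (FSR) trace
  via a sustained (>= 20 ms) crossing of `median + 5 MAD` of the first
  second of baseline. On simulated data both agree within 60 ms.
* **Windows.** Sample indices are 0-based, windows half-open,
  time-to-sample conversion uses round-half-even; window $k$ covers
  $[\mathrm{round}((t_k + 0.25)\,f_s), \mathrm{round}((t_k + 0.25 +
  L)\,f_s))$. Windows that would overrun their ON epoch are rejected at
  extraction (and impossible configurations — a 2.5 s window on a 1 s
  epoch — already at config validation).
* **Trial rejection.** A trial is dropped when any channel's peak exceeds
  `median + 8 MAD` of that channel's per-trial peaks. The criterion is a
  package invention (the original work reports removals but no rule) and
  is config-exposed and logged. Note that per-trial peaks are
  Gumbel-tailed, so the false-rejection probability is ~1e-3 per
  channel-trial rather than zero; the tests assert a rate below 0.5 %, not
  an absolute zero. In paired sessions a trial rejected on either cuff is
  dropped from both.

## Features and classifier

MAV is the mean absolute value of the filtered window per channel, the
standard time-domain ENG feature. Min–max normalisation (per channel, to
[0, 1], constants to 0) exists for scatter plots only and is never fed to
the classifier.

The LDA is written from scratch: class means, pooled within-class
covariance with denominator $n - K$, shrinkage
$\Sigma(\lambda) = (1-\lambda)S + \lambda\,\overline{\mathrm{diag}(S)}\,I$
with default $\lambda = 0.05$, uniform priors (the design is balanced and
scores are reported balanced anyway), and deterministic ties toward the
lowest class id. At $\lambda = 1$ it reduces to nearest class mean. It is
validated two ways: on a two-class equal-covariance Gaussian problem at
Mahalanobis distance 2 it attains the Bayes rate $\Phi(1) \approx 0.8413$
within 0.02, and it agrees with the reference implementation in MASS on
>= 99 % of points over 50 random instances (ties excluded).

Scores are **balanced** (macro-averaged recall, in percent). Five-fold
cross-validation uses seeded stratified folds (per-class shuffle, dealt
round-robin), and the headline number is the **median of the five fold
scores**. The fold assignment is *shared* between the two cuffs of a
session so fold differences are paired; the original text does not state
stratification, but unstratified folds could empty a class from a training
split, so stratification is adopted and documented. The exhaustive
electrode-pair search evaluates all $\binom{c}{2}$ pairs with the same
folds and ranks by *mean* fold accuracy — the median takes too few values
across 120 candidates and ties excessively; the divergence from the
headline statistic is deliberate. Confusion matrices pool held-out
predictions over folds; cuff differences of confusion matrices are
row-normalised by default (rows of the difference then sum to zero), with
raw counts available by flag.

## Desk-scale configuration

The published protocol scale (30 kHz, 3 s epochs, 50 trials per class)
needs minutes of CPU per simulated session. `desk_scale_config()` shrinks
only the time axis and repetition count: 4.8 kHz sampling, 0.7 s ON /
0.25 s OFF, 0.4 s windows at 0.25 s offset, 101 taps, source band
300–2400 Hz (the band ordering source ⊃ filter band is preserved), 10
repetitions per angle for the six-class design (exactly one published
block) and 6 per class for the ten-class design. Class structure, gains,
geometry, fold logic and thresholds are untouched. Under this
configuration the full qualitative suite (20 seeds x 3 designs) runs in
about three minutes on one CPU.

What a green qualitative test establishes: *given* fascicles that are
spatially separated distally and nearly concentric proximally, and given
contact-level gain instability, the pipeline's orderings match the
published ones (distal-16 > proximal-16 in >= 18/20 seeds; the 16-vs-3
advantage is larger when the 16-channel cuff is distal). What it does not
establish: animal-specific accuracy values, absolute SNR realism, spike
waveform realism, or any motion/stimulation artefact behaviour — none of
which the simulator models.

## Worked example

```{r example, eval = FALSE}
cfg <- desk_scale_config("exp2", seed = 5)
report <- run_experiment(cfg, pair_search_cuffs = "distal")
report
#> <run_report exp2> 60 events, 0 rejected
#>   distal   cuff16 median CV 50.0%
#>   proximal cuff16 median CV 33.3%
#>   distal - proximal median fold difference: +25.0 points
make_figures(report, "figures/")
```

## Known limitations

* The pickup model is phenomenological; no finite-element or
  cable-equation volume conduction, no action-potential waveforms, no
  stimulation or motion artefacts.
* Rest-state ENG level and per-class SNR are stated assumptions
  (baseline gain 0.1, noise 0.5 µV nominal), not estimates from data.
* One simulated "animal" is one seed; there is no systematic inter-animal
  variability model.
* Axial ring positions within the 16-channel cuff are assumed evenly
  spaced; the pickup model is purely cross-sectional, so this choice is
  cosmetic.
* Real-time / moving-window decoding and alternative features or
  classifiers are out of scope by design.
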