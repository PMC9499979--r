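---
title: "Methods: synthetic soundscapes, click classification, and noise-condition statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic soundscapes, click classification, and noise-condition statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscape)
```

## Scope and rationale

`pamscape` implements the computational chain of a long-term passive
acoustic monitoring (PAM) study of Cuvier's beaked whales (*Ziphius
cavirostris*) exposed to vessel-based noise sources: echolocation click
detection and rule-based classification, screening of long recordings
for anthropogenic signals (ultrasonic antifouling systems, navigational
echosounders, vessel engine noise), standard soundscape metrics, and a
nonparametric comparison of hourly whale acoustic presence across noise
conditions.

Long-term raw PAM recordings are rarely shareable (a two-year deployment
at 200 kHz is tens of terabytes), so the package is built around a
synthetic-scene generator with exact ground truth. Every downstream
stage is validated against scenes whose event times, source levels and
spectra are known by construction. That choice also fixes what the test
suite can and cannot show: passing tests demonstrate that the detectors
and statistics behave correctly on signals *with the documented
spectral-temporal structure at the configured levels*, not that they
would match a human analyst on real ocean recordings, which contain
propagation effects, overlapping biological sound, and source variants
the generator does not emulate.

## The synthetic scene model

A scene (`scene_spec()`) is a flat-spectrum Gaussian noise floor
(default 40 dB re 1 µPa²/Hz, emulating recorder self-noise) plus scaled
source waveforms, rendered at 200 kHz/16-bit by default:

* **Cuvier-type FM pulse** (`template_cuvier()`): a linear upsweep under
  a Tukey envelope with a centre emphasis, plus two weak additive tones.
  Defaults: peak frequency 40 kHz, sweep rate 30 kHz/ms, −10 dB duration
  450 µs, secondary spectral peaks at 17 and 23 kHz, inter-pulse
  interval uniform in 0.4–0.5 s. The envelope shape was chosen so that
  the *measured* quantities land on the nominal ones: the spectral dome
  pins the peak to the sweep centre instead of a chirp-spectrum ripple,
  and the rendered support is 1.30× the nominal duration because the
  −10 dB width of this envelope is correspondingly narrower. `duration`
  therefore means "measured −10 dB duration", the convention in which
  click durations are reported.
* **Delphinid-like confuser** (`template_delphinid()`): a short
  (120 µs), unswept, lower-frequency (22 kHz) click whose features fall
  inside the FM-pulse deletion region.
* **Echosounder pings** (`template_echosounder()`): Gaussian-windowed
  tone bursts. The 28-kHz class peaks at 28.8 kHz with energy confined
  to ~27–31 kHz; the 50-kHz class keeps ≥95% of its energy in 49–51 kHz.
* **Ultrasonic antifouling comb** (`template_ua_comb()`): tonal
  components from 19.4 kHz up to ~42 kHz ("anchored"), ~88 kHz
  ("transiting") or ~166 kHz ("close_range"), pulsed 50 ms every 200 ms
  by default. The pulse repetition schedule is a free parameter of the
  emulation — no published value constrains it — and the component set
  includes a line in the 28.4–29.0 kHz range, which is why the 28-kHz
  echosounder proxy band deliberately sits at 29.1–29.3 kHz.
* **Vessel noise** (`template_vessel()`): band-limited Gaussian noise
  below 300 Hz.
* **Disk-write artifact**: 15 s of broadband noise, +20 dB over the
  floor, every 75 s. It only needs to be reliably detectable so that the
  soundscape-metric omission logic is testable.

Levels are *received* levels at the recorder (dB re 1 µPa); there is no
propagation model, because a single fixed sensor only ever measures
received levels. Event timing jitter is drawn from the scene seed before
any noise, so ground truth is independent of the noise realisation, and
rendering is chunked on a fixed 75-s grid so that any window of a scene
is bit-identical to the corresponding slice of the full render — this is
what lets `run_pipeline()` stream multi-hour scenes without
materialising them.

The 16-bit full scale maps to 140 dB re 1 µPa peak by default, placing
the 40 dB noise floor ≈50 dB above quantization noise while leaving
≈35 dB of headroom over the default click level.

## Click detection and segment classification

Candidates are found on a 10-kHz-high-passed copy of the signal
(4th-order Butterworth, zero phase) with the Teager–Kaiser energy
operator Ψ[x](n) = x(n)² − x(n−1)x(n+1), smoothed over 0.2 ms. The
detection threshold is median + 12·MAD of the smoothed energy — robust
to the impulsive outliers the detector is looking for — with a 5-ms
lockout. No published threshold exists for this stage, so it is a
configurable default.

Two further detector-level choices matter:

* **Transient gate and duration bound.** A candidate's smoothed squared
  envelope must exceed the local background (median within ±50 ms) by
  18 dB, and its measured −10 dB duration must not exceed 1.5 ms.
  Echolocation clicks are sub-millisecond isolated transients over a
  quiet background. A continuously transmitting antifouling comb
  produces envelope maxima riding on its own high background (beats
  measure well under the gate, clicks well over it), and the onsets of
  *pulsed* comb transmissions — tens of milliseconds long — fail the
  duration bound, as standard click detectors also enforce. The gate is
  computed on the squared envelope rather than the Teager–Kaiser energy
  because the TK operator's sin²(Ω) frequency weighting would make the
  margin depend on the sampling rate.
* **Feature conventions.** Peak frequency is the maximum of the
  spectrum after ~1.5 kHz smoothing (raw chirp spectra carry ripples
  that would capture an argmax); centre frequency is the spectral
  centroid over the analysis band; duration is the −10 dB Hilbert
  envelope width after ~40 µs smoothing (beat ripple between the pulse's
  polycyclic components would otherwise fragment the envelope); sweep
  rate is the least-squares slope of the spectrogram ridge over frames
  within 12 dB of the loudest.

Classification follows the published rule set exactly, per 75-s
segment anchored at the recording start (the trailing partial segment is
processed by the same rules): segments with ≤7 initial detections are
*insufficient*; a candidate is deleted when its peak frequency is below
32 kHz, centre frequency below 25 kHz, duration below 355 µs **and**
sweep rate below 23 kHz/ms; a segment is positive when strictly more
than 13% of its initial detections survive. All comparisons are strict —
ties never delete and never classify. The deletion connective reads as
conjunctive in its source description and that is the default, but
per-criterion (disjunctive) deletion is common in this family of
pipelines, so `deletion_logic = "disjunctive"` is available; tests cover
both. The original pipeline's trained-analyst verification step has no
algorithmic counterpart here: segment decisions are auto-accepted. One
consequence is documented honestly: 28-kHz-class echosounder ping
trains, which an analyst would reject, pass the duration bound (~1.1 ms
measured) and satisfy the retained-fraction rule (their centre
frequency exceeds 25 kHz), so beaked-whale logs from scenes with dense
ping trains overcount unless reviewed.

## Anthropogenic-signal screening

The original screening was performed by a human analyst over long-term
spectral averages (LTSAs); the detectors here are explicit rule-based
stand-ins with tunable margins, validated only against synthetic ground
truth and never claimed to replicate analyst judgment.

The LTSA itself follows the published configuration: 5-s mean of
magnitude-squared spectra at 100 Hz resolution full-band, and at 10 Hz
resolution after decimation by 20 for the low-frequency (vessel) band.
Decimation offers a polyphase FIR path and a boxcar (block-mean) path;
the boxcar's passband is flat far below the output Nyquist, which is all
the ≤300 Hz vessel band needs, at a fraction of the cost — the streaming
pipeline uses it. `run_pipeline()` also averages every 4th FFT frame
into the LTSA bins by default (an unbiased, slightly noisier mean) to
keep multi-hour screening cheap; `compute_ltsa()` itself defaults to
every frame.

* **UA**: a time bin is flagged when ≥3 narrowband maxima ≥6 dB above
  the bin's local floor (median level above 19 kHz) form a comb above
  19 kHz. A qualifying line must drop ≥4 dB within ±500 Hz — continuous
  comb tones are one 100-Hz bin wide, whereas the tonal components of a
  450-µs click train spread over ~2 kHz — and encounters shorter than
  15 s are dropped, since antifouling systems transmit continuously.
* **Echosounders**: persistent narrowband energy confined to 27–31 kHz
  (28-kHz class) or 49–51 kHz (50-kHz class), ≥6 dB over the out-of-band
  floor, without an accompanying comb (which would indicate UA).
* **Vessel noise**: mean level below 300 Hz in the mid-band LTSA
  exceeding a rolling per-bin baseline (median over 10 min) by 6 dB.

Flagged bins are merged into encounters with a 10-s gap tolerance. The
gap tolerance and margins are unconstrained by any published criterion
(the original counts were analyst judgments), so they are parameters
with documented defaults rather than calibrated values.

## Soundscape metrics

The processing chain reproduces the published order of operations:

1. **Welch PSD**: one 200,000-point Hann-windowed FFT per second at 0%
   overlap (window = FFT length, i.e. a modified periodogram per
   second), one-sided density in µPa²/Hz, corrected by the system
   transfer function. With this window, an on-bin sinusoid's *peak bin*
   under-reads by 1.76 dB (the Hann equivalent noise bandwidth); the
   Parseval-exact statement, which the tests assert, is that the density
   *integrated over the tone's spectral neighbourhood* equals its
   mean-square level.
2. **Per-minute medians** are taken in linear power and then converted
   to dB — medians do not commute with the log, so the order matters —
   over no fewer than 30 usable seconds per minute; seconds overlapping
   disk-write intervals are excluded first, and under-covered minutes
   are reported missing. dB conversion clamps at the configured
   instrument floor, mirroring the fact that recorder self-noise bounds
   reported minima.
3. **Third-octave levels (TOLs)**: the 1-Hz PSD integrated over 39
   proportional bands. Band edges are exact base-10 (centres 10^(n/10),
   n = 11…49, edges ×10^(±1/20)); the published description names
   nominal centres "13 Hz to 80 kHz", which are the rounded nominals of
   this same 39-band ladder (12.5 Hz … 80 kHz). The nominal-125-Hz band,
   the standard vessel-noise indicator, is additionally reported as a
   density by subtracting 10·log₁₀(bw) ≈ 14.6 dB.
4. **Proxy bands**: per-minute medians of the 200-Hz-bin PSD at
   19.3–19.5 kHz (UA), 29.1–29.3 kHz (28-kHz echosounders, clear of the
   UA line at 28.4–29.0 kHz) and 49.9–50.1 kHz (50-kHz echosounders).
   A 200-Hz bin is the mean linear density over its 200 1-Hz bins, so a
   single tone of mean-square level L reads L − 10·log₁₀(200): a
   within-bin median would read the bin's noise floor instead and could
   not see a tonal source at all, which is why the mean is the right
   within-bin statistic before the across-time median.

A known statistical subtlety: the per-minute *median* of a band power
summed over k 1-Hz bins carries a small negative bias (order −ln 2/k in
power) for the narrowest bands (k ≈ 3 at 12.5 Hz). This is a property of
the median estimator itself, visible in the white-noise tests, not an
implementation artefact.

## Hourly statistics

Hours are labelled with one of eight noise conditions — every
presence/absence combination of UA, echosounder and vessel encounters —
using any-overlap semantics (one minute of UA flags the hour; no
published rule states the original convention). Beaked-whale minutes are
UTC-aligned half-open bins touched by an encounter. The comparison is a
Kruskal–Wallis test (tie-corrected, via `stats::kruskal.test`) of hourly
detection minutes across conditions, df = non-empty groups − 1, followed
by Dunn-type z tests on mean ranks with Bonferroni correction. The
original analysis used a generic multiple-comparison routine on the KW
ranks whose exact statistic is not documented; Dunn's test is the
standard rank-based choice and produces the same qualitative grouping on
strong effects. Mean-rank "comparison intervals" (±z·SE/√2 at the
Bonferroni-adjusted level) are emitted for the interval plot:
non-overlapping intervals indicate a significant pair.

`noise_condition_test()` wraps the chain in a classed object with
`print`/`summary`/`plot` methods.

## Problem sizes and numerical choices

The test suite exercises the chain at desk scale, chosen as the smallest
sizes at which each property is meaningful rather than as approximations
of any field dataset: scene-level tests use 10–300 s scenes (mostly at a
100-kHz rate, which comfortably contains every default template), the
segment-rule oracle runs 1,000 random candidate tables, the type-I-error
simulation runs 1,000 Kruskal–Wallis replicates at 8×200 hours, and the
end-to-end avoidance test uses a 2-hour scene (a quiet hour of click
trains, then an hour of continuous antifouling comb with reduced click
activity). In that scene the comb's received level is set to 85 dB per
component — a source a few kilometres away rather than alongside the
recorder — so that the hour contrast reflects the generated reduction
in click-train rate; at much higher comb levels the detector's
transient gate additionally masks genuine clicks, which would make the
contrast trivially large for the wrong reason. Headline field results that depend on the original multi-year
dataset — its χ², its encounter counts, its seasonal noise shifts — are
out of reach of any synthetic reconstruction and are not asserted
anywhere.

Degenerate inputs are rejected loudly (zero-duration pulses, aliased
templates, empty combs, all-zero snippets, sub-LTSA-bin recordings,
fewer than two non-empty statistical groups); scenes that exceed 16-bit
full scale are rescaled with a warning and the factor recorded. Ties at
every classification threshold go, strictly, to "not deleted" / "not
classified".

## Known limitations

* All detector margins are validated against the generator's source
  models only; real UA units, echosounders and vessels vary in ways the
  templates do not capture.
* The delphinid discriminator of the original pipeline (a trained
  expert system) is represented only by the published deletion criteria;
  species separation beyond "Cuvier-type vs other" is out of scope.
* Without the analyst verification step, echosounder ping trains can
  inflate beaked-whale segment counts (see above).
* The statistics treat hours as exchangeable; temporal autocorrelation
  of presence is not modelled, matching the original analysis.
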