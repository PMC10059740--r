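---
title: "Methods: fever surveillance from continuous infrared doorway recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fever surveillance from continuous infrared doorway recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

A fixed infrared camera watches an automatic entrance door. Its software
continuously records, at 9 samples per second (a 27 FPS sensor decimated to
every third frame), two scalars per sample: the **maximum** temperature of a
rectangular region R1 where faces appear, and the **mean** temperature of a
small region R2 on the glass door, used as an ambient reference. Persons
passing the door raise the R1 maximum from its ambient baseline
(`r "~26"` °C indoors) to skin temperature for a few seconds; hot objects
(a carried coffee cup) and sub-second grazing passes produce similar
excursions that must not be counted as persons.

Two person-identification routes are modelled:

* **TTI (temperature–time identification)** works on the continuous trace.
  Maximal runs of samples *strictly above* a threshold `t_lim = 33` °C are
  extracted; runs separated by at most `merge_gap_s = 1` s are fused (the
  same person lingering or turning); a fused segment counts as a person
  only if its peak lies in the inclusive plausibility range
  `[33, 40]` °C *and* its duration strictly exceeds 1 s. The person's
  temperature is the segment peak — the maximum over the whole pass.
* **FTI (face temperature identification)** emulates alarm-driven
  single-frame capture: the alarm triggers on the first sample above 33 °C,
  one frame is captured at the first sample at least 0.6 s later (the focus
  delay at the door), and the alarm stays off until a sub-threshold sample
  rearms it — at most one frame per alarm cycle. A ground-truth orientation
  oracle stands in for the head detector that would classify the frame:
  frames on front-facing persons yield FTI detections carrying that single
  sample's temperature; back-of-head frames are diagnostics only; frames on
  hot objects yield nothing.

Because FTI samples one instant of the same noisy trace that TTI maximises
over, a matched FTI temperature can never exceed the TTI peak, and because
TTI additionally counts in-range hot objects and the warm tail of back-of-head
passes, daily TTI counts dominate daily FTI counts. Both directions are
asserted in the test suite over a simulated month.

Downstream, detections are aggregated per day (count, hourly histogram,
mean/sd, fraction above the 37.5 °C fever cut — strictly greater — and the
Fisher–Pearson moment skewness $g_1 = m_3 / m_2^{3/2}$) and pooled per
consecutive 7-day week. Weekly series are z-scored (n−1 sd) and correlated
(Pearson) with a weekly acute-respiratory-infection (ARI) incidence series
per 100,000 population. Skewness and fever fraction are the epidemiologically
interesting statistics: a rise in febrile passers-by fattens the right tail
of the weekly temperature distribution before it moves the mean.

## The synthetic world

Real doorway recordings and regional incidence data are confidential, so the
package ships a generator whose defaults *are* the stated study conditions:

| parameter | default | meaning |
|---|---|---|
| opening hours | 9–21 h | doors closed otherwise |
| arrival profile | `default_rate_profile()` | ~657/day, peaks at 10 h and 13–18 h (>60/h) |
| `p_front` | 0.7 | fraction facing the camera |
| face temperature | N(35.1, 0.9²) °C, truncated to [33.5, 39.5] | afebrile skin-over-face maximum |
| back of head | face draw − 3.0 °C | mostly below the 33 °C threshold |
| fever | N(37.8, 0.4²) °C, replaces the face draw | prevalence `0.01 + 2e-5 × ARI incidence` |
| dwell time | U(1.2, 4.0) s | at-peak time in view |
| short passes | 30/day, U(0.3, 0.8) s, U(33.1, 34.5) °C | sub-second grazing crossings |
| hot objects | 5/day, U(1.5, 6) s, U(34, 60) °C | cups, etc.; those ≤ 40 °C stress the range filter |
| baselines | R1 26 °C, R2 20 °C | ambient; > 80σ below threshold |
| noise | sd 0.08 °C per sample | sensor NETD |
| sampling | 9 Hz → 777,600 samples/day | recorder setting |

Arrivals follow a non-homogeneous Poisson process simulated by thinning a
homogeneous process at the profile maximum; the hourly profile gives the
intensity shape. Each event is rendered as a **trapezoid**: 0.3 s rise and
fall shoulders flanking a plateau at the event's peak temperature whose
length equals the event's dwell time. The shoulders flank (rather than eat
into) the dwell so that the above-threshold time of a person matches the
stated dwell — that is the quantity the TTI duration filter semantically
tests; had the shoulders been counted inside the dwell, every person's
excursion would be ~0.47 s shorter than nominal and persons with dwell
below ~1.5 s would be silently undetectable. Events are kept 1.5 s clear of
each other by pushing starts right (the door physically separates people);
`allow_overlap = TRUE` disables this for stress tests. Per-sample Gaussian
noise is added on top; the peak is drawn once per event.

The seasonal ARI model is a cosine wave, `baseline + amplitude ·
cos(2πw/period) + noise`, clamped at zero, with defaults 1000 ± 800 per
100k over a 52-week period and 30 per 100k reporting noise. A 26-week study
therefore spans one seasonal extreme to the other, mirroring a
spring-to-winter surveillance window, with weekly incidence ranging roughly
200–1800 per 100k — central-European ARI magnitudes. Fever prevalence
couples linearly to incidence and the fever draw *replaces* the normal one.

**RNG discipline.** One master seed; per-day substreams are derived by a
Lehmer-style mix of (seed, day index), so any single day of a long study is
independently reproducible and `generate_study()` is bit-identical under a
fixed seed.

### What the generator does not emulate

No radiometric physics (emissivity, reflected temperature — streams are
final °C values), no images and no head-detector errors (the orientation
oracle is perfect, so FTI misclassification is absent), no within-event
temperature structure beyond the trapezoid (no neck/scarf gradients), no
acclimatisation effects, no day-of-week or holiday structure in arrivals,
and no reporting artefacts in the ARI series. A green recovery test
establishes that the *algorithms* recover what this world contains — not
that the real-world correlation between doorway fever fractions and ARI
incidence has any particular value.

## Numerical conventions

* Run membership is **strict** (`R1 > t_lim`); the plausibility range is
  **inclusive** at both ends; duration must be **strictly** longer than the
  minimum; gaps merge when **≤** `merge_gap_s`. These match the natural
  reading of "higher than", "inside", "longer than", "more than one second
  away"; the behaviour at exactly 1.000 s (gap merges, duration rejects) is
  pinned by boundary tests.
* Durations and gaps are sample counts over the sampling rate; no
  interpolation between samples. Segment indices are 0-based with exclusive
  ends, so sample *i* sits at *i*/rate seconds since midnight.
* Detection timestamp = segment start; the peak instant is kept as a
  diagnostic column.
* Runs touching midnight are processed as-is (the venue is closed then).
* Merging only ever reduces the number of *segments*, but not necessarily
  the number of *detections*: two sub-second runs that individually fail
  the duration rule can fuse into one segment that passes it. The suite
  pins this interplay with an explicit counterexample instead of asserting
  a false monotonicity.
* Recording files print times with 3 decimals; at 9 Hz the printed grid is
  therefore rounded. The reader fits the uniform grid by least squares
  (unbiased against rounding, unlike an endpoint estimate), snaps
  near-integer rates, and rejects files whose residuals exceed the rounding
  precision plus 1e-6 s, naming the offending line.
* Moment statistics use the n−1 standard deviation; daily/weekly moments
  are reported as missing below 3 detections or at zero variance. Weekly
  statistics are recomputed over pooled temperatures, never averaged over
  daily values; partial weeks are flagged and excluded from correlation by
  default.

## Design choices on open ground

* The passer-by temperature distribution is anchored to the summary
  statistics the TTI route reports on real data (mean ≈ 35.1 °C,
  sd ≈ 0.9 °C). Those statistics conflate true skin temperature with
  detection effects; the generator treats them as the underlying face
  distribution, which is the conservative choice for testing the pipeline.
* Whether the headline field correlation used daily or weekly windows, TTI
  or FTI detections, is not fixed by the method description; the package
  exposes the statistic and method as parameters and defaults to weekly
  TTI (the cadence of incidence reporting, and the route with more data).
* The recovery tests use front-only scenarios: with the default 3 °C
  back-of-head offset, most back passes peak below 33 °C and are
  *physically* invisible to TTI — the threshold is doing its intended job —
  so truth-count equality is only well-posed for events whose rendered peak
  exceeds the threshold.

## Verification outline

Each operation is tested against hand-traced examples; the complete TTI
chain is additionally tested for exact agreement with an independent
brute-force oracle (enumerate above-threshold index runs, merge by repeated
pairwise scanning, filter) on 1,000 random-walk streams. Property tests
cover determinism under seeds, merge idempotence, range invariants,
z-score/skewness/Pearson invariances, and end-to-end recovery: in a 26-week
default study the weekly fever fraction correlates with the ARI series at
r ≈ 0.97 (seed 1), collapsing to |r| < 0.5 when the coupling is switched
off. Scaled-down replicates (8-week studies at 3 Hz) keep the multi-study
comparison inside the suite's runtime budget.
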