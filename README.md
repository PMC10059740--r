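# feversurv

Syndromic fever surveillance from a fixed infrared camera watching an
entrance door.

A cheap IR camera aimed at an automatic door records, continuously at 9 Hz,
the maximum temperature of a face region (R1) and the mean temperature of an
ambient reference region (R2). Every person passing the door leaves a short
above-threshold excursion in the R1 trace. `feversurv` turns such traces
into epidemiology:

* **TTI — temperature–time identification.** Segment the trace into persons:
  maximal runs with `R1 > 33 °C`, runs ≤ 1 s apart merged, segments kept
  when the peak lies in the plausible range `[33, 40] °C` **and** the
  duration strictly exceeds 1 s (rejecting coffee cups at 45 °C and
  sub-second grazing passes). The person's temperature is the segment peak.
* **FTI — face temperature identification.** Emulate alarm-driven
  single-frame capture (trigger above 33 °C, one frame 0.6 s later, rearm
  after a sub-threshold sample) with a ground-truth front/back-of-head
  oracle in place of a CNN; front-of-head frames yield detections.
* **Surveillance statistics.** Daily and weekly counts, hourly profiles,
  mean/sd of temperatures, fraction of detections above the 37.5 °C fever
  cut, and the Fisher–Pearson skewness g₁ = m₃/m₂^(3/2) of the temperature
  distribution; weekly series are z-scored and Pearson-correlated with a
  weekly acute-respiratory-infection (ARI) incidence series per 100,000.
* **A synthetic world with ground truth.** Non-homogeneous Poisson arrivals
  (thinning), trapezoidal thermal signatures, face temperatures
  N(35.1, 0.9²) °C, back-of-head 3 °C lower, fevers N(37.8, 0.4²) °C with
  prevalence coupled linearly to ARI incidence, hot-object and short-pass
  confounders, and 0.08 °C sensor noise — enabling recovery tests of the
  whole chain, since real recordings are confidential.

See `vignettes/fever-surveillance.Rmd` for the full model description and
the numerical conventions.

## Worked example

```r
library(feversurv)

cfg <- scenario_config()                    # the default simulated world
day <- generate_day(cfg, as.Date("2022-04-22"), p_fever = 0.03, seed = 1)
day$stream
#> <daily_stream> 2022-04-22: 777600 samples at 9 Hz (24.0 h), R1 max 48.46 C
table(day$truth$kind)
#>   hot_object  person_back person_front   short_pass
#>            5          198          460           35

tti <- detect_persons_tti(day$stream)
frames <- simulate_alarm_captures(day$stream, day$truth)
fti <- detect_persons_fti(frames, day$stream$date)
sprintf("TTI: %d persons, mean %.3f C | FTI: %d persons, mean %.3f C",
        nrow(tti), mean(tti$temp_c), nrow(fti), mean(fti$temp_c))
#> "TTI: 505 persons, mean 35.259 C | FTI: 460 persons, mean 35.238 C"

summarize_day(tti, day$stream$date)[, 1:6]
#>         date n_persons mean_temp_c sd_temp_c frac_fever  skewness
#> 1 2022-04-22       505    35.25864  1.055533 0.02376238 0.3511221
```

Reading: of 698 simulated events, TTI identifies 505 persons — all 460
front-facing passers-by, the warm tail of back-of-head passes, and the rare
hot object that sneaks into the 33–40 °C range — while FTI sees exactly the
460 faces. 2.4% of detected temperatures exceed the 37.5 °C fever cut
(the day was generated at 3% prevalence among persons), and the positive
skewness reflects the febrile right tail. TTI counts and temperatures sit
above FTI's, as expected when one route maximises over the whole pass and
the other samples a single instant.

A full 26-week study pipeline (simulate → detect → weekly aggregate →
correlate) recovers the fever–ARI coupling at r ≈ 0.97 (seed 1), and
r ≈ 0.19 when the coupling is switched off — see
`tests/testthat/test-acceptance.R`.

The same chain is scriptable from a shell:

```sh
Rscript -e 'quit(status = feversurv::cli())' simulate \
    --weeks 26 --seed 1 --out study/
Rscript -e 'quit(status = feversurv::cli())' detect \
    --method both --in study/ --out detections.csv
Rscript -e 'quit(status = feversurv::cli())' summarize \
    --in detections.csv --by week --out weekly.csv
Rscript -e 'quit(status = feversurv::cli())' correlate \
    --summaries weekly.csv --ari study/ari.csv \
    --statistic frac_fever --out correlation.json
```

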