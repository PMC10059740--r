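# End-to-end study pipeline: simulate a multi-week study, detect with TTI,
# aggregate weekly, correlate a statistic with the ARI series.
run_study_correlation <- function(seed, n_weeks = 26, fever_ari_slope = 2e-5,
                                  sample_rate = 9, statistic = "frac_fever") {
  cfg <- scenario_config(fever_ari_slope = fever_ari_slope,
                         sample_rate = sample_rate)
  study <- generate_study(cfg, n_weeks, days_per_week = 7, seed = seed,
                          day_fn = function(stream, truth, date)
                            detect_persons_tti(stream))
  dets <- do.call(rbind, study$days)
  daily <- do.call(rbind, lapply(sort(unique(dets$date)), function(d)
    summarize_day(dets[dets$date == d, , drop = FALSE], d)))
  weekly <- weekly_aggregate(daily, dets)
  correlate_with_ari(weekly, study$ari, statistic)$pearson_r
}
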