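# Brute-force TTI oracle, independent of the package's rle-based path:
# enumerate above-threshold indices, group them into maximal runs, merge by
# repeated pairwise gap scanning, filter by range and duration.
oracle_detect <- function(x, rate, cfg = tti_config()) {
  above <- which(x > cfg$t_lim)
  if (length(above) == 0L)
    return(data.frame(detect_time_s = numeric(0), temp_c = numeric(0),
                      duration_s = numeric(0)))
  runs <- unname(split(above, cumsum(c(1L, diff(above) != 1L))))
  segs <- lapply(runs, function(ii) c(min(ii), max(ii)))  # 1-based inclusive
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(segs)) {
      gap_samples <- segs[[i + 1L]][1] - segs[[i]][2] - 1L
      if (gap_samples / rate <= cfg$merge_gap_s) {
        segs[[i]] <- c(segs[[i]][1], segs[[i + 1L]][2])
        segs[[i + 1L]] <- NULL
        merged <- TRUE
      } else i <- i + 1L
    }
    if (!merged) break
  }
  out <- lapply(segs, function(s) {
    peak <- max(x[s[1]:s[2]])
    dur <- (s[2] - s[1] + 1L) / rate
    if (peak >= cfg$t_min_limit && peak <= cfg$t_max_limit &&
        dur > cfg$min_duration_s)
      data.frame(detect_time_s = (s[1] - 1L) / rate, temp_c = peak,
                 duration_s = dur)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(detect_time_s = numeric(0), temp_c = numeric(0),
                      duration_s = numeric(0))
  out
}

# distinct fixed seeds for replicate loops
mix_seed_for_test <- function(a, i) a * 1000L + i

# a daily_stream wrapper around a raw R1 vector (ambient R2)
make_stream <- function(x, rate = 9, date = as.Date("2022-04-22")) {
  daily_stream(date, rate, x, rep(20, length(x)))
}

# random-walk stream repeatedly crossing the 33 C threshold (and sometimes
# the 40 C upper limit), clamped to a physical range
random_walk_stream <- function(n = 540, rate = 9, start = 32, step_sd = 0.5) {
  pmin(pmax(start + cumsum(rnorm(n, 0, step_sd)), 25), 46)
}

expect_same_detections <- function(dets, oracle) {
  expect_equal(nrow(dets), nrow(oracle))
  expect_equal(dets$detect_time_s, oracle$detect_time_s)
  expect_equal(dets$temp_c, oracle$temp_c)
  expect_equal(dets$duration_s, oracle$duration_s)
}
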