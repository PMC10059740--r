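# Synthetic generation of continuous doorway recordings with ground truth.

#' Default hourly arrival-rate profile (persons per hour)
#'
#' A 24-element vector shaped like a pharmacy day: opening hours 9-21 with a
#' morning peak around 10 h and a sustained afternoon plateau exceeding 60
#' persons/h between 13 and 18 h; roughly 650 arrivals per day in total.
#'
#' @return Numeric vector of length 24; element `h + 1` is the rate during
#'   clock hour `h`.
#' @export
#' @examples
#' sum(default_rate_profile())  # expected arrivals over a full day
default_rate_profile <- function() {
  prof <- numeric(24)
  prof[10:21] <- c(45, 65, 55, 50, 62, 63, 64, 65, 63, 55, 40, 30) # hours 9..20
  prof
}

#' Scenario configuration for the synthetic generator
#'
#' Bundles every tunable of the simulated world: opening hours, arrival
#' intensity, the temperature distributions of faces, backs of heads and
#' fevers, confounder rates (sub-second passes, hot objects such as coffee
#' cups), the ambient baselines of the two analysis regions, per-sample
#' sensor noise (NETD), and the sampling rate of the recorder.
#'
#' @param open_hour,close_hour Opening hours (clock hours, default 9 and 21).
#' @param hourly_rate_profile 24 non-negative arrival rates in persons/h;
#'   default [default_rate_profile()].
#' @param p_front Probability that a passer-by faces the camera (default 0.7).
#' @param face_temp_mean,face_temp_sd Normal parameters of the afebrile face
#'   temperature in degrees C (default 35.1, 0.9).
#' @param face_temp_bounds Truncation interval for face draws (default
#'   c(33.5, 39.5) degrees C).
#' @param back_temp_offset Degrees C subtracted from the face draw when the
#'   person shows the camera the back of the head (default 3.0).
#' @param fever_temp_mean,fever_temp_sd Normal parameters of febrile face
#'   temperature (default 37.8, 0.4 degrees C).
#' @param p_fever_base Baseline fever prevalence among passers-by (default 0.01).
#' @param fever_ari_slope Added fever probability per unit of weekly ARI
#'   incidence per 100,000 (default 2e-5).
#' @param event_duration_bounds At-peak dwell time interval of a person in
#'   front of the camera, seconds (default c(1.2, 4.0)).
#' @param short_pass_rate Expected sub-second grazing passes per day
#'   (default 30).
#' @param hot_object_rate Expected hot-object confounders per day (default 5).
#' @param hot_object_temp_bounds Peak temperature interval of hot objects
#'   (default c(34, 60) degrees C).
#' @param baseline_r1_mean,baseline_r2_mean Ambient baselines of the face
#'   region R1 and the door region R2 (default 26.0 and 20.0 degrees C; both
#'   must stay below the 33 degree person threshold).
#' @param noise_sd Per-sample thermal noise, degrees C (default 0.08, the
#'   sensor NETD).
#' @param sample_rate Recorder sampling rate in Hz (default 9: the camera's
#'   27 FPS decimated to every third frame, see [recorder_sample_rate()]).
#' @param min_gap_s Minimum clearance enforced between rendered event
#'   footprints, seconds (default 1.5; the automatic door separates people).
#' @param allow_overlap If `TRUE`, events may overlap freely (stress testing).
#' @param seed Optional integer master seed stored with the configuration.
#'
#' @return An object of class `scenario_config` (a validated named list).
#' @export
#' @examples
#' cfg <- scenario_config()
#' cfg$face_temp_mean
scenario_config <- function(open_hour = 9,
                            close_hour = 21,
                            hourly_rate_profile = default_rate_profile(),
                            p_front = 0.7,
                            face_temp_mean = 35.1,
                            face_temp_sd = 0.9,
                            face_temp_bounds = c(33.5, 39.5),
                            back_temp_offset = 3.0,
                            fever_temp_mean = 37.8,
                            fever_temp_sd = 0.4,
                            p_fever_base = 0.01,
                            fever_ari_slope = 2e-5,
                            event_duration_bounds = c(1.2, 4.0),
                            short_pass_rate = 30,
                            hot_object_rate = 5,
                            hot_object_temp_bounds = c(34, 60),
                            baseline_r1_mean = 26.0,
                            baseline_r2_mean = 20.0,
                            noise_sd = 0.08,
                            sample_rate = 9,
                            min_gap_s = 1.5,
                            allow_overlap = FALSE,
                            seed = NULL) {
  cfg <- list(
    open_hour = open_hour, close_hour = close_hour,
    hourly_rate_profile = as.numeric(hourly_rate_profile),
    p_front = p_front,
    face_temp_mean = face_temp_mean, face_temp_sd = face_temp_sd,
    face_temp_bounds = as.numeric(face_temp_bounds),
    back_temp_offset = back_temp_offset,
    fever_temp_mean = fever_temp_mean, fever_temp_sd = fever_temp_sd,
    p_fever_base = p_fever_base, fever_ari_slope = fever_ari_slope,
    event_duration_bounds = as.numeric(event_duration_bounds),
    short_pass_rate = short_pass_rate,
    hot_object_rate = hot_object_rate,
    hot_object_temp_bounds = as.numeric(hot_object_temp_bounds),
    baseline_r1_mean = baseline_r1_mean,
    baseline_r2_mean = baseline_r2_mean,
    noise_sd = noise_sd, sample_rate = sample_rate,
    min_gap_s = min_gap_s, allow_overlap = isTRUE(allow_overlap),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  opening hours     : %d-%d h, ~%.0f arrivals/day\n",
              x$open_hour, x$close_hour, sum(x$hourly_rate_profile)))
  cat(sprintf("  face temperature  : N(%.1f, %.2f^2) C, fever N(%.1f, %.2f^2) C\n",
              x$face_temp_mean, x$face_temp_sd,
              x$fever_temp_mean, x$fever_temp_sd))
  cat(sprintf("  fever prevalence  : %.3f + %.1e x ARI incidence\n",
              x$p_fever_base, x$fever_ari_slope))
  cat(sprintf("  recorder          : %g Hz, noise sd %.2f C, baselines R1 %.1f / R2 %.1f C\n",
              x$sample_rate, x$noise_sd, x$baseline_r1_mean, x$baseline_r2_mean))
  invisible(x)
}

validate_scenario_config <- function(cfg) {
  if (!inherits(cfg, "scenario_config"))
    stop_bad("not a scenario_config")
  if (length(cfg$hourly_rate_profile) != 24L || anyNA(cfg$hourly_rate_profile))
    stop_bad("`hourly_rate_profile` must be 24 non-missing rates")
  if (any(cfg$hourly_rate_profile < 0))
    stop_bad("arrival rates must be non-negative")
  assert_prob(cfg$p_front, "p_front")
  assert_prob(cfg$p_fever_base, "p_fever_base")
  assert_interval(cfg$face_temp_bounds, "face_temp_bounds")
  assert_interval(cfg$event_duration_bounds, "event_duration_bounds")
  assert_interval(cfg$hot_object_temp_bounds, "hot_object_temp_bounds")
  if (cfg$baseline_r1_mean >= 33 || cfg$baseline_r2_mean >= 33)
    stop_bad("baseline means must stay below 33 C (the person threshold)")
  if (!is.numeric(cfg$sample_rate) || cfg$sample_rate <= 0)
    stop_bad("`sample_rate` must be positive")
  if (cfg$noise_sd < 0) stop_bad("`noise_sd` must be non-negative")
  if (!(cfg$open_hour %in% 0:23) || !(cfg$close_hour %in% 1:24) ||
      cfg$open_hour >= cfg$close_hour)
    stop_bad("opening hours must satisfy 0 <= open_hour < close_hour <= 24")
  if (cfg$min_gap_s < 0) stop_bad("`min_gap_s` must be non-negative")
  cfg
}

#' Sampling rate of the continuous recorder
#'
#' The recorder keeps every `decimation`-th frame of the camera's native
#' frame rate; at the default 27 FPS with every third frame kept, 9
#' temperature samples per second are stored, i.e. 777,600 rows per day.
#'
#' @param fps Native camera frame rate (default 27).
#' @param decimation Keep every `decimation`-th frame (default 3).
#' @return Samples per second.
#' @export
#' @examples
#' recorder_sample_rate()            # 9
#' recorder_sample_rate() * 86400    # rows per full day
recorder_sample_rate <- function(fps = 27, decimation = 3) {
  if (fps <= 0 || decimation <= 0 || decimation != as.integer(decimation))
    stop_bad("`fps` must be positive and `decimation` a positive integer")
  fps / decimation
}

#' Simulate arrival times from an hourly rate profile
#'
#' Draws arrival times of a non-homogeneous Poisson process whose intensity
#' is piecewise constant per clock hour, by thinning a homogeneous process
#' run at the maximum rate over the opening window.
#'
#' @param profile 24 non-negative rates (persons/h); hours outside
#'   `[open_hour, close_hour)` are ignored.
#' @param open_hour,close_hour Opening window in clock hours.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Sorted numeric vector of arrival times in seconds since midnight,
#'   all within the opening window.
#' @export
#' @examples
#' a <- simulate_arrivals(default_rate_profile(), seed = 1)
#' length(a); range(a) / 3600
simulate_arrivals <- function(profile, open_hour = 9, close_hour = 21,
                              seed = NULL) {
  if (length(profile) != 24L || anyNA(profile))
    stop_bad("`profile` must be 24 non-missing hourly rates")
  if (any(profile < 0)) stop_bad("arrival rates must be non-negative")
  maybe_seed(seed)
  hours <- (open_hour + 1L):close_hour          # profile indices for open hours
  lambda_max <- max(profile[hours])
  if (lambda_max == 0) return(numeric(0))
  window_h <- close_hour - open_hour
  n_cand <- rpois(1L, lambda_max * window_h)
  if (n_cand == 0L) return(numeric(0))
  t_cand <- runif(n_cand, open_hour * 3600, close_hour * 3600)
  rate_at <- profile[floor(t_cand / 3600) + 1L]
  keep <- runif(n_cand) * lambda_max < rate_at
  sort(t_cand[keep])
}

# --- event synthesis ---------------------------------------------------------

# Rise/fall shoulder length of the trapezoidal thermal signature, seconds.
# An event's truth duration is its at-peak dwell; the rendered footprint is
# duration + 2 * EVENT_RISE_S.
EVENT_RISE_S <- 0.3

#' Rendered footprint of truth events, seconds since midnight
#'
#' @param truth A truth data frame from [generate_day()].
#' @return Two-column matrix `start`/`end` of the rendered support including
#'   the rise and fall shoulders.
#' @export
event_footprint <- function(truth) {
  cbind(start = truth$start_s,
        end = truth$start_s + truth$duration_s + 2 * EVENT_RISE_S)
}

# Draw the per-day event table (persons + confounders) without rendering.
draw_events <- function(cfg, p_fever) {
  arr <- simulate_arrivals(cfg$hourly_rate_profile, cfg$open_hour,
                           cfg$close_hour, seed = NULL)
  n_p <- length(arr)
  ev <- list()
  if (n_p > 0L) {
    front <- runif(n_p) < cfg$p_front
    fever <- runif(n_p) < p_fever
    temp <- rnorm_trunc(n_p, cfg$face_temp_mean, cfg$face_temp_sd,
                        cfg$face_temp_bounds[1], cfg$face_temp_bounds[2])
    temp[fever] <- rnorm(sum(fever), cfg$fever_temp_mean, cfg$fever_temp_sd)
    temp[!front] <- temp[!front] - cfg$back_temp_offset
    ev$persons <- data.frame(
      kind = ifelse(front, "person_front", "person_back"),
      start_s = arr,
      duration_s = runif(n_p, cfg$event_duration_bounds[1],
                         cfg$event_duration_bounds[2]),
      peak_temp_c = temp,
      fever = fever
    )
  }
  open_s <- cfg$open_hour * 3600
  close_s <- cfg$close_hour * 3600
  n_sp <- rpois(1L, cfg$short_pass_rate)
  if (n_sp > 0L) {
    ev$short <- data.frame(
      kind = "short_pass",
      start_s = runif(n_sp, open_s, close_s),
      duration_s = runif(n_sp, 0.3, 0.8),
      peak_temp_c = runif(n_sp, 33.1, 34.5),
      fever = FALSE
    )
  }
  n_h <- rpois(1L, cfg$hot_object_rate)
  if (n_h > 0L) {
    ev$hot <- data.frame(
      kind = "hot_object",
      start_s = runif(n_h, open_s, close_s),
      duration_s = runif(n_h, 1.5, 6.0),
      peak_temp_c = runif(n_h, cfg$hot_object_temp_bounds[1],
                          cfg$hot_object_temp_bounds[2]),
      fever = FALSE
    )
  }
  ev <- do.call(rbind, ev)
  if (is.null(ev) || nrow(ev) == 0L) {
    return(data.frame(kind = character(0), start_s = numeric(0),
                      duration_s = numeric(0), peak_temp_c = numeric(0),
                      fever = logical(0)))
  }
  ev <- ev[order(ev$start_s), , drop = FALSE]
  rownames(ev) <- NULL
  if (!cfg$allow_overlap && nrow(ev) > 1L) {
    # push starts right so footprints keep min_gap_s clearance
    span <- ev$duration_s + 2 * EVENT_RISE_S
    for (i in 2:nrow(ev)) {
      floor_start <- ev$start_s[i - 1] + span[i - 1] + cfg$min_gap_s
      if (ev$start_s[i] < floor_start) ev$start_s[i] <- floor_start
    }
    ev <- ev[ev$start_s + span < 86400, , drop = FALSE]
    rownames(ev) <- NULL
  }
  ev
}

# Paint trapezoidal events over a baseline; returns the noiseless R1 trace.
render_events <- function(n, rate, events, baseline) {
  r1 <- rep(baseline, n)
  if (nrow(events) == 0L) return(r1)
  for (i in seq_len(nrow(events))) {
    s <- events$start_s[i]
    d <- events$duration_s[i]
    peak <- events$peak_temp_c[i]
    if (peak <= baseline) next
    lo <- max(0L, ceiling(s * rate))                       # 0-based indices
    hi <- min(n - 1L, floor((s + d + 2 * EVENT_RISE_S) * rate))
    if (hi < lo) next
    t_rel <- (lo:hi) / rate - s
    ramp <- pmin(1, t_rel / EVENT_RISE_S,
                 (d + 2 * EVENT_RISE_S - t_rel) / EVENT_RISE_S)
    ramp[ramp < 0] <- 0
    idx <- (lo:hi) + 1L
    val <- baseline + (peak - baseline) * ramp
    r1[idx] <- pmax(r1[idx], val)
  }
  r1
}

#' Construct a daily stream object
#'
#' One day of uniformly sampled recorder output: the maximum temperature of
#' the face region R1 and the mean temperature of the ambient region R2.
#' Sample `i` (0-based) is taken at `i / sample_rate_hz` seconds since
#' midnight.
#'
#' @param date A `Date` (or string coercible to one).
#' @param sample_rate_hz Samples per second.
#' @param t_r1_max,t_r2_mean Equal-length numeric vectors, degrees C.
#' @return An object of class `daily_stream`.
#' @export
daily_stream <- function(date, sample_rate_hz, t_r1_max, t_r2_mean) {
  if (length(t_r1_max) != length(t_r2_mean))
    stop_bad("R1 and R2 traces must have equal length")
  if (sample_rate_hz <= 0) stop_bad("`sample_rate_hz` must be positive")
  structure(list(date = as.Date(date), sample_rate_hz = sample_rate_hz,
                 t_r1_max = as.numeric(t_r1_max),
                 t_r2_mean = as.numeric(t_r2_mean)),
            class = "daily_stream")
}

#' @export
print.daily_stream <- function(x, ...) {
  cat(sprintf("<daily_stream> %s: %d samples at %g Hz (%.1f h), R1 max %.2f C\n",
              format(x$date), length(x$t_r1_max), x$sample_rate_hz,
              length(x$t_r1_max) / x$sample_rate_hz / 3600,
              if (length(x$t_r1_max)) max(x$t_r1_max) else NA_real_))
  invisible(x)
}

#' Generate one synthetic day of recordings with ground truth
#'
#' Draws arrivals from the configured hourly profile, assigns each person an
#' orientation (face or back of head), a temperature (febrile with
#' probability `p_fever`, in which case the fever draw replaces the normal
#' one), and an at-peak dwell time; adds sub-second grazing passes and
#' hot-object confounders; renders every event as a trapezoid (0.3 s rise
#' and fall shoulders flanking a plateau at the event's peak temperature)
#' over the R1 baseline, and adds independent Gaussian sensor noise to both
#' regions.
#'
#' @param config A [scenario_config()].
#' @param date Calendar date of the simulated day.
#' @param p_fever Fever prevalence among persons for this day.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return A list with elements `stream` (a [daily_stream()]) and `truth`
#'   (a data frame with columns `kind`, `start_s`, `duration_s`,
#'   `peak_temp_c`, `fever`).
#' @export
#' @examples
#' day <- generate_day(scenario_config(sample_rate = 1), p_fever = 0.02, seed = 7)
#' table(day$truth$kind)
generate_day <- function(config, date = Sys.Date(), p_fever = config$p_fever_base,
                         seed = NULL) {
  config <- validate_scenario_config(config)
  assert_prob(p_fever, "p_fever")
  maybe_seed(seed)
  n <- round(86400 * config$sample_rate)
  truth <- draw_events(config, p_fever)
  r1 <- render_events(n, config$sample_rate, truth, config$baseline_r1_mean)
  r1 <- r1 + rnorm(n, 0, config$noise_sd)
  r2 <- config$baseline_r2_mean + rnorm(n, 0, config$noise_sd)
  list(stream = daily_stream(date, config$sample_rate, r1, r2), truth = truth)
}

#' Seasonal ARI incidence model
#'
#' Weekly incidence per 100,000 population: a cosine annual wave plus
#' Gaussian reporting noise, clamped at zero. The default half-cycle over 26
#' weeks mimics a surveillance window running from one seasonal extreme to
#' the other.
#'
#' @param baseline,amplitude Mean level and seasonal amplitude (per 100k).
#' @param period Wave period in weeks (default 52).
#' @param noise_sd Reporting noise sd (per 100k).
#' @return A validated list of class `ari_model`.
#' @export
ari_model <- function(baseline = 1000, amplitude = 800, period = 52,
                      noise_sd = 30) {
  if (period <= 0) stop_bad("`period` must be positive")
  if (noise_sd < 0) stop_bad("`noise_sd` must be non-negative")
  structure(list(baseline = baseline, amplitude = amplitude, period = period,
                 noise_sd = noise_sd), class = "ari_model")
}

ari_incidence <- function(model, weeks) {
  inc <- model$baseline +
    model$amplitude * cos(2 * pi * (weeks - 1) / model$period) +
    rnorm(length(weeks), 0, model$noise_sd)
  pmax(inc, 0)
}

#' Fever prevalence implied by ARI incidence
#'
#' `p_fever(week) = clamp(p_fever_base + fever_ari_slope * incidence, 0, 1)`.
#'
#' @param config A [scenario_config()].
#' @param incidence Weekly ARI incidence per 100,000 (vectorised).
#' @return Fever probabilities in `[0, 1]`.
#' @export
#' @examples
#' fever_prevalence(scenario_config(), 1000)  # 0.01 + 2e-5 * 1000 = 0.03
fever_prevalence <- function(config, incidence) {
  pmin(pmax(config$p_fever_base + config$fever_ari_slope * incidence, 0), 1)
}

#' Generate a multi-week surveillance study
#'
#' Simulates `n_weeks` consecutive weeks: a weekly ARI incidence series from
#' the seasonal [ari_model()], and `days_per_week` recorded days per week,
#' each generated with the fever prevalence implied by that week's incidence
#' via [fever_prevalence()]. Per-day RNG substreams are derived from the
#' master seed and the day index, so any day is independently reproducible.
#'
#' @param config A [scenario_config()].
#' @param n_weeks Number of weeks (>= 1).
#' @param days_per_week Recorded days per week (default 7).
#' @param ari An [ari_model()].
#' @param seed Master seed for the whole study.
#' @param start_date Date of the first day.
#' @param day_fn Optional `function(stream, truth, date)`; when supplied, each
#'   day's entry in `$days` is its return value and the raw stream is
#'   discarded after the call (a full study holds gigabytes of samples
#'   otherwise). When `NULL` each entry is `list(stream, truth)`.
#' @return A list with `days` (list of length `n_weeks * days_per_week`),
#'   `ari` (data frame `week_index`, `incidence_per_100k`), `p_fever`
#'   (per-week fever prevalence) and `dates`.
#' @export
generate_study <- function(config, n_weeks, days_per_week = 7,
                           ari = ari_model(), seed = 1,
                           start_date = as.Date("2022-04-22"),
                           day_fn = NULL) {
  config <- validate_scenario_config(config)
  if (n_weeks < 1) stop_bad("`n_weeks` must be >= 1")
  if (!inherits(ari, "ari_model")) ari <- do.call(ari_model, as.list(ari))
  set.seed(mix_seed(seed, 999983L))
  weeks <- seq_len(n_weeks)
  incidence <- ari_incidence(ari, weeks)
  p_fever <- fever_prevalence(config, incidence)
  if (days_per_week < 1 || days_per_week > 7)
    stop_bad("`days_per_week` must be in 1..7")
  # recorded days sit at the start of each calendar week so that 7-day
  # aggregation blocks coincide with simulation weeks
  wk <- rep(weeks, each = days_per_week)
  dow <- rep(seq_len(days_per_week), times = n_weeks)
  dates <- start_date + (wk - 1L) * 7L + (dow - 1L)
  days <- vector("list", n_weeks * days_per_week)
  for (w in weeks) {
    for (d in seq_len(days_per_week)) {
      i <- (w - 1L) * days_per_week + d
      day <- generate_day(config, date = dates[i], p_fever = p_fever[w],
                          seed = mix_seed(seed, i))
      days[[i]] <- if (is.null(day_fn)) day else
        day_fn(day$stream, day$truth, dates[i])
    }
  }
  list(days = days,
       ari = data.frame(week_index = weeks, incidence_per_100k = incidence),
       p_fever = p_fever, dates = dates)
}
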