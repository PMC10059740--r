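# Alarm-driven single-frame capture and face-temperature identification (FTI).
#
# The acquisition software watches the R1 maximum temperature: when it
# exceeds a threshold the alarm triggers and one frame is captured after a
# fixed focus delay; the alarm then stays off until a sub-threshold sample
# rearms it, so each cycle yields at most one frame. A ground-truth
# orientation oracle stands in for the head detector: the captured frame is
# labelled by the truth event it falls on (front of head, back of head, or
# none for hot objects and empty frames).

#' Alarm configuration
#'
#' @param threshold_c Trigger threshold on R1 (default 33 degrees C).
#' @param capture_delay_s Delay between trigger and frame capture (default
#'   0.6 s, chosen so the person is in focus at the door).
#' @return A list of class `alarm_config`.
#' @export
alarm_config <- function(threshold_c = 33.0, capture_delay_s = 0.6) {
  if (capture_delay_s < 0) stop_bad("`capture_delay_s` must be non-negative")
  structure(list(threshold_c = threshold_c, capture_delay_s = capture_delay_s),
            class = "alarm_config")
}

#' Simulate alarm-triggered frame captures
#'
#' Runs the armed/triggered/rearm state machine over a day's R1 trace:
#' starting armed, the first sample strictly above the threshold triggers an
#' alarm; the frame is captured at the first sample at or after the trigger
#' time plus the capture delay; the alarm is then disarmed until a sample at
#' or below the threshold rearms it. A trigger whose capture time falls past
#' the end of the stream yields no frame.
#'
#' Each frame is labelled with the ground-truth event whose rendered
#' footprint covers the capture instant: `head_front` for a person facing
#' the camera, `head_back` for back-of-head and sub-second passes, `none`
#' for hot objects or no event. Overlapping events resolve to the one with
#' the later start.
#'
#' @param stream A [daily_stream()].
#' @param truth Truth data frame from [generate_day()] for the same day.
#' @param config An [alarm_config()].
#' @return Data frame with columns `capture_time_s`, `temp_c`, `label`.
#' @export
simulate_alarm_captures <- function(stream, truth, config = alarm_config()) {
  x <- stream$t_r1_max
  rate <- stream$sample_rate_hz
  n <- length(x)
  above <- x > config$threshold_c
  delay_samples <- config$capture_delay_s * rate
  ups <- which(above)          # candidate trigger samples (1-based)
  downs <- which(!above)       # rearm samples
  cap_idx <- integer(0)
  i <- 1L                      # armed from this sample on
  repeat {
    k <- bsearch_ge(ups, i)                 # first trigger sample >= i
    if (k > length(ups)) break
    trig <- ups[k]
    cap <- trig + as.integer(ceiling(delay_samples - 1e-9))
    # capture at first sample at/after trigger_time + delay
    if (cap > n) break
    cap_idx <- c(cap_idx, cap)
    b <- bsearch_ge(downs, cap + 1L)        # first rearm sample > cap
    if (b > length(downs)) break
    i <- downs[b] + 1L
  }
  if (length(cap_idx) == 0L) {
    return(data.frame(capture_time_s = numeric(0), temp_c = numeric(0),
                      label = character(0)))
  }
  cap_time <- (cap_idx - 1L) / rate
  fp <- event_footprint(truth)
  label <- vapply(cap_time, function(tc) label_at(truth, tc, fp), character(1))
  data.frame(capture_time_s = cap_time, temp_c = x[cap_idx], label = label)
}

# first index of sorted integer vector `vec` with vec[idx] >= x
bsearch_ge <- function(vec, x) {
  lo <- 1L; hi <- length(vec) + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (vec[mid] < x) lo <- mid + 1L else hi <- mid
  }
  lo
}

# ground-truth orientation oracle at one instant
label_at <- function(truth, t, fp = event_footprint(truth)) {
  if (nrow(truth) == 0L) return("none")
  hit <- which(fp[, "start"] <= t & t <= fp[, "end"])
  if (length(hit) == 0L) return("none")
  ev <- hit[which.max(truth$start_s[hit])]   # later start wins on overlap
  switch(truth$kind[ev],
         person_front = "head_front",
         person_back = "head_back",
         short_pass = "head_back",
         "none")
}

#' Face-temperature identification from captured frames
#'
#' One FTI detection per `head_front` frame, with the single captured sample
#' as the person's temperature. Back-of-head frames carry no usable face
#' temperature and yield no detection (they remain countable in the frame
#' table); `none` frames (hot objects, empty captures) are dropped.
#'
#' @param frames Frame data frame from [simulate_alarm_captures()].
#' @param date Calendar date stamped onto the detections.
#' @return Detection data frame (`method` = `"FTI"`, `duration_s` = `NA`).
#' @export
detect_persons_fti <- function(frames, date = as.Date(NA)) {
  keep <- frames$label == "head_front"
  if (!any(keep)) return(empty_detections())
  f <- frames[keep, , drop = FALSE]
  data.frame(date = rep(as.Date(date), nrow(f)), method = "FTI",
             detect_time_s = f$capture_time_s, temp_c = f$temp_c,
             duration_s = NA_real_, peak_time_s = NA_real_)
}

#' Run TTI and FTI on one generated day
#'
#' Convenience wrapper used by the CLI and the study pipeline: runs
#' [detect_persons_tti()] and, when truth is available, the alarm capture /
#' FTI chain, returning one combined detection table.
#'
#' @param stream A [daily_stream()].
#' @param truth Truth data frame (required for FTI; `NULL` for TTI only).
#' @param method `"tti"`, `"fti"` or `"both"`.
#' @param tti A [tti_config()]; `alarm` an [alarm_config()].
#' @param alarm An [alarm_config()].
#' @return Detection data frame with a `method` column.
#' @export
detect_day <- function(stream, truth = NULL, method = c("both", "tti", "fti"),
                       tti = tti_config(), alarm = alarm_config()) {
  method <- match.arg(method)
  out <- list()
  if (method %in% c("both", "tti"))
    out$tti <- detect_persons_tti(stream, tti)
  if (method %in% c("both", "fti")) {
    if (is.null(truth))
      stop_bad("FTI needs ground-truth labels (`truth`)")
    frames <- simulate_alarm_captures(stream, truth, alarm)
    out$fti <- detect_persons_fti(frames, stream$date)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
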