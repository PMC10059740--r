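# Temperature-time identification (TTI) of persons in a continuous stream.
#
# The R1 trace is segmented into maximal runs of samples strictly above a
# person threshold; runs closer than a merge gap are fused (one person
# lingering in view); surviving segments are kept only if their peak lies in
# a humanly plausible range and their duration strictly exceeds a minimum.
# Segment indices are 0-based with exclusive ends, so sample i sits at
# i / sample_rate seconds since midnight and a segment [s, e) lasts
# (e - s) / sample_rate seconds.

#' TTI configuration
#'
#' @param t_lim Person threshold on the R1 maximum temperature; samples must
#'   be strictly above it to belong to a run (default 33 degrees C — people
#'   colder than that are not expected indoors).
#' @param t_min_limit,t_max_limit Inclusive plausibility range for the
#'   segment peak (defaults 33 and 40 degrees C; hotter peaks are objects
#'   such as coffee cups, not people).
#' @param min_duration_s A segment must last strictly longer than this to
#'   count as a person (default 1 s; shorter excursions are grazing passes).
#' @param merge_gap_s Runs separated by at most this many seconds are the
#'   same person (default 1 s).
#' @return A validated list of class `tti_config`.
#' @export
#' @examples
#' tti_config()
tti_config <- function(t_lim = 33.0, t_min_limit = 33.0, t_max_limit = 40.0,
                       min_duration_s = 1.0, merge_gap_s = 1.0) {
  if (t_min_limit > t_max_limit)
    stop_bad("`t_min_limit` must not exceed `t_max_limit`")
  if (min_duration_s <= 0) stop_bad("`min_duration_s` must be positive")
  if (merge_gap_s < 0) stop_bad("`merge_gap_s` must be non-negative")
  structure(list(t_lim = t_lim, t_min_limit = t_min_limit,
                 t_max_limit = t_max_limit, min_duration_s = min_duration_s,
                 merge_gap_s = merge_gap_s),
            class = "tti_config")
}

#' @export
print.tti_config <- function(x, ...) {
  cat(sprintf(
    "<tti_config> run if R1 > %g C; peak in [%g, %g] C; duration > %g s; merge gaps <= %g s\n",
    x$t_lim, x$t_min_limit, x$t_max_limit, x$min_duration_s, x$merge_gap_s))
  invisible(x)
}

empty_segments <- function() {
  data.frame(start_index = integer(0), end_index = integer(0),
             peak_temp_c = numeric(0), peak_index = integer(0),
             duration_s = numeric(0))
}

#' Find maximal above-threshold runs
#'
#' @param stream A [daily_stream()] (or any object with `t_r1_max` and
#'   `sample_rate_hz`).
#' @param t_lim Threshold; run membership requires `R1 > t_lim` (strict).
#' @return Data frame of segments with 0-based `start_index`, exclusive
#'   `end_index`, `peak_temp_c`, `peak_index`, `duration_s`; ordered and
#'   disjoint.
#' @export
find_runs <- function(stream, t_lim = 33.0) {
  x <- stream$t_r1_max
  if (length(x) == 0L) stop_bad("empty stream")
  above <- x > t_lim
  r <- rle(above)
  ends <- cumsum(r$lengths)           # 1-based inclusive ends
  starts <- ends - r$lengths + 1L     # 1-based starts
  keep <- which(r$values)
  if (length(keep) == 0L) return(empty_segments())
  out <- data.frame(start_index = starts[keep] - 1L, end_index = ends[keep])
  seg_stats(out, x, stream$sample_rate_hz)
}

# fill peak/duration columns from the trace
seg_stats <- function(seg, x, rate) {
  n <- nrow(seg)
  peak <- numeric(n); pidx <- integer(n)
  for (i in seq_len(n)) {
    idx <- (seg$start_index[i] + 1L):seg$end_index[i]
    j <- idx[which.max(x[idx])]
    peak[i] <- x[j]; pidx[i] <- j - 1L
  }
  seg$peak_temp_c <- peak
  seg$peak_index <- pidx
  seg$duration_s <- (seg$end_index - seg$start_index) / rate
  seg
}

#' Merge runs separated by short gaps
#'
#' Consecutive runs whose gap is at most `merge_gap_s` (measured as sample
#' count over the sampling rate, no interpolation) are one person and are
#' fused into a single segment spanning both; the peak is the maximum over
#' the merged span. Merging is idempotent.
#'
#' @param runs Segment data frame from [find_runs()]: sorted, disjoint.
#' @param merge_gap_s Maximum gap (seconds) that still joins two runs.
#' @param sample_rate Samples per second of the underlying stream.
#' @return Segment data frame.
#' @export
merge_runs <- function(runs, merge_gap_s = 1.0, sample_rate = 9) {
  if (nrow(runs) <= 1L) return(runs)
  if (is.unsorted(runs$start_index) ||
      any(runs$start_index[-1] < runs$end_index[-nrow(runs)]))
    stop_bad("`runs` must be sorted and disjoint")
  gap_s <- (runs$start_index[-1] - runs$end_index[-nrow(runs)]) / sample_rate
  grp <- cumsum(c(1L, as.integer(gap_s > merge_gap_s)))
  out <- data.frame(
    start_index = as.integer(tapply(runs$start_index, grp, min)),
    end_index = as.integer(tapply(runs$end_index, grp, max))
  )
  # gap samples are sub-threshold, so the merged peak is the max of run peaks
  pk <- tapply(seq_len(nrow(runs)), grp, function(i)
    i[which.max(runs$peak_temp_c[i])])
  out$peak_temp_c <- runs$peak_temp_c[unlist(pk)]
  out$peak_index <- runs$peak_index[unlist(pk)]
  out$duration_s <- (out$end_index - out$start_index) / sample_rate
  rownames(out) <- NULL
  out
}

empty_detections <- function() {
  data.frame(date = as.Date(character(0)), method = character(0),
             detect_time_s = numeric(0), temp_c = numeric(0),
             duration_s = numeric(0), peak_time_s = numeric(0))
}

#' Filter segments into person detections
#'
#' A segment is a person when its peak temperature lies inside the inclusive
#' plausibility range `[t_min_limit, t_max_limit]` and its duration strictly
#' exceeds `min_duration_s`. The detection carries the segment peak as the
#' person's temperature and the segment start as the detection time (peak
#' time kept for diagnostics).
#'
#' @param segments Segment data frame from [merge_runs()].
#' @param config A [tti_config()].
#' @param sample_rate Samples per second.
#' @param date Calendar date stamped onto the detections.
#' @return Detection data frame with columns `date`, `method` (`"TTI"`),
#'   `detect_time_s`, `temp_c`, `duration_s`, `peak_time_s`.
#' @export
filter_segments <- function(segments, config = tti_config(), sample_rate = 9,
                            date = as.Date(NA)) {
  keep <- segments$peak_temp_c >= config$t_min_limit &
    segments$peak_temp_c <= config$t_max_limit &
    segments$duration_s > config$min_duration_s
  seg <- segments[keep, , drop = FALSE]
  if (nrow(seg) == 0L) return(empty_detections())
  data.frame(date = rep(as.Date(date), nrow(seg)), method = "TTI",
             detect_time_s = seg$start_index / sample_rate,
             temp_c = seg$peak_temp_c,
             duration_s = seg$duration_s,
             peak_time_s = seg$peak_index / sample_rate)
}

#' Temperature-time identification of persons
#'
#' Full TTI chain on one day of continuous recording: threshold runs
#' ([find_runs()]), gap merging ([merge_runs()]), plausibility and duration
#' filtering ([filter_segments()]).
#'
#' @param stream A [daily_stream()].
#' @param config A [tti_config()].
#' @return Detections sorted by time (see [filter_segments()]).
#' @export
#' @examples
#' day <- generate_day(scenario_config(sample_rate = 1), seed = 7)
#' nrow(detect_persons_tti(day$stream))
detect_persons_tti <- function(stream, config = tti_config()) {
  runs <- find_runs(stream, config$t_lim)
  merged <- merge_runs(runs, config$merge_gap_s, stream$sample_rate_hz)
  filter_segments(merged, config, stream$sample_rate_hz, stream$date)
}
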