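# Daily/weekly surveillance statistics and correlation with ARI incidence.

#' Moment coefficient of skewness
#'
#' Fisher-Pearson moment coefficient `g1 = m3 / m2^(3/2)` with central
#' moments `m_k = mean((x - mean(x))^k)` (no small-sample bias correction).
#' Location- and positive-scale-invariant; negating the data negates it.
#'
#' @param values Numeric vector, at least 3 values with non-zero variance.
#' @return The skewness `g1`.
#' @export
#' @examples
#' skewness(c(1, 2, 3))     # 0
#' skewness(c(0, 0, 0, 1))  # 1.1547
skewness <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L)
    stop_bad("skewness needs at least 3 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop_bad("skewness undefined for zero-variance data")
  mean((values - m)^3) / m2^1.5
}

#' Summarise one day of detections
#'
#' Counts, hourly histogram of detection times, mean and standard deviation
#' (n-1 denominator) of detection temperatures, fraction of detections with
#' temperature strictly above the fever threshold, and skewness. Moment
#' statistics are `NA` when fewer than 3 detections (or zero variance).
#'
#' @param detections Detection data frame (one day, one method).
#' @param date The day being summarised.
#' @param fever_threshold_c Fever cut; strictly greater counts as fever
#'   (default 37.5 degrees C).
#' @return One-row data frame: `date`, `n_persons`, `mean_temp_c`,
#'   `sd_temp_c`, `frac_fever`, `skewness`, plus an `hourly_counts` list
#'   column (24 counts summing to `n_persons`).
#' @export
#' @examples
#' d <- data.frame(date = Sys.Date(), method = "TTI",
#'                 detect_time_s = c(34200, 35100, 51000),
#'                 temp_c = c(36, 36, 38), duration_s = 2, peak_time_s = NA)
#' summarize_day(d, Sys.Date())$frac_fever  # 1/3
summarize_day <- function(detections, date, fever_threshold_c = 37.5) {
  if (nrow(detections) > 0 && !all(is.na(detections$date)) &&
      any(detections$date != as.Date(date), na.rm = TRUE))
    stop_bad("detections carry a different date than `date`")
  temps <- detections$temp_c
  n <- length(temps)
  hours <- floor(detections$detect_time_s / 3600)
  hourly <- tabulate(hours + 1L, nbins = 24L)
  ok <- n >= 3L && var(temps) > 0
  data.frame(
    date = as.Date(date),
    n_persons = n,
    mean_temp_c = if (n >= 3L) mean(temps) else NA_real_,
    sd_temp_c = if (n >= 3L) sd(temps) else NA_real_,
    frac_fever = if (n > 0L) mean(temps > fever_threshold_c) else NA_real_,
    skewness = if (ok) skewness(temps) else NA_real_,
    hourly_counts = I(list(hourly))
  )
}

#' Aggregate detections into consecutive 7-day weeks
#'
#' Days are grouped into consecutive 7-day blocks starting at the first date
#' in `daily_summaries`. Weekly statistics are recomputed over the pooled
#' detection temperatures of the week (not averaged daily values). Weeks
#' with fewer than 7 summarised days are flagged `partial` (series edges,
#' non-recording days).
#'
#' @param daily_summaries Row-bound output of [summarize_day()].
#' @param detections Detection data frame covering the same days.
#' @param fever_threshold_c Fever cut (default 37.5 degrees C).
#' @return Data frame: `week_index`, `n_days`, `partial`, `n_persons`,
#'   `mean_temp_c`, `sd_temp_c`, `frac_fever`, `skewness`.
#' @export
weekly_aggregate <- function(daily_summaries, detections,
                             fever_threshold_c = 37.5) {
  if (nrow(daily_summaries) == 0L) {
    return(data.frame(week_index = integer(0), n_days = integer(0),
                      partial = logical(0), n_persons = integer(0),
                      mean_temp_c = numeric(0), sd_temp_c = numeric(0),
                      frac_fever = numeric(0), skewness = numeric(0)))
  }
  origin <- min(daily_summaries$date)
  week_of <- function(d) as.integer(floor(as.numeric(d - origin) / 7)) + 1L
  dw <- week_of(daily_summaries$date)
  ew <- week_of(as.Date(detections$date))
  out <- lapply(sort(unique(dw)), function(w) {
    temps <- detections$temp_c[ew == w]
    n <- length(temps)
    ok <- n >= 3L && var(temps) > 0
    data.frame(
      week_index = w,
      n_days = sum(dw == w),
      partial = sum(dw == w) < 7L,
      n_persons = n,
      mean_temp_c = if (n >= 3L) mean(temps) else NA_real_,
      sd_temp_c = if (n >= 3L) sd(temps) else NA_real_,
      frac_fever = if (n > 0L) mean(temps > fever_threshold_c) else NA_real_,
      skewness = if (ok) skewness(temps) else NA_real_
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' z-score normalisation
#'
#' `(x - mean(x)) / sd(x)` with the n-1 standard deviation; the output has
#' mean 0 and sd 1.
#'
#' @param series Numeric vector, length >= 2, non-constant.
#' @return Normalised vector.
#' @export
#' @examples
#' zscore_normalize(c(1, 2, 3))  # -1 0 1
zscore_normalize <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2L) stop_bad("need at least 2 points to normalise")
  s <- sd(series)
  if (s == 0) stop_bad("cannot z-score a constant series")
  (series - mean(series)) / s
}

#' Pearson correlation with least-squares line
#'
#' Product-moment correlation of `x` and `y` plus the slope and intercept of
#' the least-squares regression of `y` on `x`.
#'
#' @param x,y Equal-length numeric vectors (>= 3 points, non-constant).
#' @return A `correlation_result`: list with `pearson_r`, `slope`,
#'   `intercept`, `n_points`.
#' @export
#' @examples
#' pearson(c(1, 2, 3), c(1, 3, 2))$pearson_r  # 0.5
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_bad("`x` and `y` must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_bad("need at least 3 complete pairs")
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) stop_bad("correlation undefined for constant input")
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  r <- cxy / (sx * sy)
  slope <- cxy / sx^2
  structure(list(pearson_r = r, slope = slope,
                 intercept = mean(y) - slope * mean(x), n_points = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation> r = %.3f over %d points; y = %.3f x + %.3f\n",
              x$pearson_r, x$n_points, x$slope, x$intercept))
  invisible(x)
}

#' Correlate a weekly surveillance statistic with ARI incidence
#'
#' Aligns the weekly summaries with the ARI series on `week_index`
#' (partial weeks are excluded by default), z-normalises both series over
#' the overlapping weeks, and returns their Pearson correlation.
#'
#' @param weekly Output of [weekly_aggregate()].
#' @param ari Data frame `week_index`, `incidence_per_100k`.
#' @param statistic One of `"frac_fever"`, `"skewness"`, `"n_persons"`,
#'   `"mean_temp"`.
#' @param include_partial Include partial weeks (default `FALSE`).
#' @return A `correlation_result` (see [pearson()]).
#' @export
correlate_with_ari <- function(weekly, ari,
                               statistic = c("frac_fever", "skewness",
                                             "n_persons", "mean_temp"),
                               include_partial = FALSE) {
  statistic <- match.arg(statistic)
  col <- switch(statistic, mean_temp = "mean_temp_c", statistic)
  w <- if (include_partial) weekly else weekly[!weekly$partial, , drop = FALSE]
  m <- merge(w, ari, by = "week_index")
  m <- m[!is.na(m[[col]]) & !is.na(m$incidence_per_100k), , drop = FALSE]
  if (nrow(m) < 3L)
    stop_bad("need at least 3 overlapping weeks (got %d)", nrow(m))
  pearson(zscore_normalize(m$incidence_per_100k), zscore_normalize(m[[col]]))
}
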