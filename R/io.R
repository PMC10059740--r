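# File formats: daily recording files, detections CSV, ARI CSV, scenario
# config files, correlation JSON. Fixed CSV dialect: comma delimiter, period
# decimal separator, UTF-8, LF endings, no autodetection.

RECORDING_HEADER <- c("time_s", "t_r1_max_c", "t_r2_mean_c")
DETECTIONS_HEADER <- c("date", "method", "detect_time_s", "temp_c", "duration_s")
ARI_HEADER <- c("week_index", "incidence_per_100k")

#' Write one day of continuous recording
#'
#' Text file with header `time_s,t_r1_max_c,t_r2_mean_c`; times in seconds
#' since midnight with 3 decimals, temperatures with 2 decimals (the format
#' precision, 0.01 degrees C, is well below the sensor noise). The calendar
#' date travels in the filename (`YYYY-MM-DD.csv`).
#'
#' @param stream A [daily_stream()].
#' @param path Output path; [recording_path()] builds the conventional name.
#' @return `path`, invisibly.
#' @export
write_recording <- function(stream, path) {
  n <- length(stream$t_r1_max)
  t <- (seq_len(n) - 1L) / stream$sample_rate_hz
  dt <- data.table::data.table(
    time_s = sprintf("%.3f", t),
    t_r1_max_c = sprintf("%.2f", stream$t_r1_max),
    t_r2_mean_c = sprintf("%.2f", stream$t_r2_mean)
  )
  data.table::fwrite(dt, path, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Conventional recording filename for a date
#' @param dir Directory; `date` a `Date`.
#' @param date Calendar date.
#' @return `dir/YYYY-MM-DD.csv`
#' @export
recording_path <- function(dir, date) {
  file.path(dir, sprintf("%s.csv", format(as.Date(date), "%Y-%m-%d")))
}

#' Read one day of continuous recording
#'
#' Parses and validates a recording file: correct header, numeric fields,
#' strictly increasing times consistent with a constant sampling interval.
#' Printed times are rounded to 1 ms, so consistency is checked against the
#' reconstructed uniform grid within rounding precision plus a 1e-6 s
#' tolerance; the sampling rate is recovered from the mean interval. A
#' malformed row raises an error naming its line number; a header-only file
#' yields an empty stream with a warning.
#'
#' @param path Recording file path.
#' @param date Calendar date; default parsed from a `YYYY-MM-DD` filename.
#' @return A [daily_stream()].
#' @export
read_recording <- function(path, date = NULL) {
  if (!file.exists(path)) stop_bad("no such recording file: %s", path)
  if (is.null(date)) {
    m <- regmatches(basename(path),
                    regexpr("\\d{4}-\\d{2}-\\d{2}", basename(path)))
    date <- if (length(m)) as.Date(m) else as.Date(NA)
  }
  dt <- tryCatch(
    data.table::fread(path, sep = ",", header = TRUE, colClasses = "numeric",
                      fill = TRUE, showProgress = FALSE),
    error = function(e) stop_bad("cannot parse %s: %s", path, conditionMessage(e)))
  if (!identical(names(dt), RECORDING_HEADER))
    stop_bad("%s: expected header %s", path,
             paste(RECORDING_HEADER, collapse = ","))
  if (nrow(dt) == 0L) {
    warning(sprintf("%s: header only, returning empty stream", path))
    return(daily_stream(date, 9, numeric(0), numeric(0)))
  }
  bad <- which(!stats::complete.cases(dt))
  if (length(bad))
    stop_bad("%s: malformed row at line %d", path, bad[1] + 1L)
  t <- dt$time_s
  n <- length(t)
  if (n > 1L) {
    if (any(diff(t) <= 0))
      stop_bad("%s: non-monotonic time at line %d", path,
               which(diff(t) <= 0)[1] + 2L)
    # least-squares grid fit: unbiased against the 1 ms rounding of the
    # printed times (an endpoint-based interval estimate is not)
    i <- seq_len(n) - 1
    dt_hat <- sum((i - mean(i)) * (t - mean(t))) / sum((i - mean(i))^2)
    rate <- 1 / dt_hat
    if (abs(rate - round(rate)) < 1e-3) {
      rate <- round(rate)
      dt_hat <- 1 / rate
    }
    grid <- mean(t) + (i - mean(i)) * dt_hat
    off <- abs(t - grid)
    if (any(off > 5e-4 + 1e-6))
      stop_bad("%s: inconsistent sampling interval at line %d", path,
               which.max(off) + 1L)
  } else {
    rate <- 9
  }
  daily_stream(date, rate, dt$t_r1_max_c, dt$t_r2_mean_c)
}

#' Write / read a detections CSV
#'
#' Fixed header `date,method,detect_time_s,temp_c,duration_s`; the duration
#' field is empty for FTI rows (a single frame has no dwell time).
#'
#' @param detections Detection data frame ([detect_persons_tti()] /
#'   [detect_persons_fti()] output, possibly row-bound over days).
#' @param path CSV path.
#' @return `path` invisibly (write); detection data frame (read).
#' @export
write_detections <- function(detections, path) {
  dt <- data.table::data.table(
    date = format(as.Date(detections$date), "%Y-%m-%d"),
    method = detections$method,
    detect_time_s = sprintf("%.3f", detections$detect_time_s),
    temp_c = sprintf("%.2f", detections$temp_c),
    duration_s = ifelse(is.na(detections$duration_s), "",
                        sprintf("%.3f", detections$duration_s))
  )
  data.table::fwrite(dt, path, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop_bad("no such detections file: %s", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = list(character = c("date", "method")),
                          showProgress = FALSE)
  if (!identical(names(dt), DETECTIONS_HEADER))
    stop_bad("%s: expected header %s", path,
             paste(DETECTIONS_HEADER, collapse = ","))
  if (nrow(dt) && !all(dt$method %in% c("TTI", "FTI")))
    stop_bad("%s: method must be TTI or FTI", path)
  data.frame(date = as.Date(dt$date), method = dt$method,
             detect_time_s = as.numeric(dt$detect_time_s),
             temp_c = as.numeric(dt$temp_c),
             duration_s = as.numeric(dt$duration_s),
             peak_time_s = NA_real_)
}

#' Write / read a weekly ARI incidence CSV
#'
#' Header `week_index,incidence_per_100k`; incidence must be non-negative.
#'
#' @param ari Data frame with `week_index` and `incidence_per_100k`.
#' @param path CSV path.
#' @return `path` invisibly (write); data frame (read).
#' @export
write_ari <- function(ari, path) {
  if (any(ari$incidence_per_100k < 0)) stop_bad("incidence must be >= 0")
  data.table::fwrite(ari[, ARI_HEADER], path, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_ari
#' @export
read_ari <- function(path) {
  if (!file.exists(path)) stop_bad("no such ARI file: %s", path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          showProgress = FALSE)
  if (!identical(names(dt), ARI_HEADER))
    stop_bad("%s: expected header %s", path, paste(ARI_HEADER, collapse = ","))
  if (nrow(dt) && any(dt$incidence_per_100k < 0))
    stop_bad("%s: incidence must be >= 0", path)
  as.data.frame(dt)
}

#' Write / read a scenario configuration file
#'
#' Flat `key = value` text format; numeric vectors are comma-separated.
#' Reading reconstructs a validated [scenario_config()].
#'
#' @param config A [scenario_config()].
#' @param path Config file path.
#' @return `path` invisibly (write); a `scenario_config` (read).
#' @export
write_scenario_config <- function(config, path) {
  config <- validate_scenario_config(config)
  fields <- config[!vapply(config, is.null, logical(1))]
  lines <- vapply(names(fields), function(k) {
    v <- fields[[k]]
    v <- if (is.logical(v)) tolower(as.character(v)) else
      format(v, digits = 15, scientific = FALSE, trim = TRUE)
    sprintf("%s = %s", k, paste(v, collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_bad("no such config file: %s", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3L)
  if (length(bad)) stop_bad("%s: malformed line %d", path, bad[1])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- lapply(kv, function(m) {
    parts <- trimws(strsplit(m[3], ",")[[1]])
    if (all(parts %in% c("true", "false"))) return(parts == "true")
    as.numeric(parts)
  })
  names(vals) <- keys
  unknown <- setdiff(keys, names(formals(scenario_config)))
  if (length(unknown))
    stop_bad("%s: unknown config key(s): %s", path,
             paste(unknown, collapse = ", "))
  do.call(scenario_config, vals)
}

#' Write a correlation result as a small JSON report
#'
#' @param result A `correlation_result` from [pearson()] /
#'   [correlate_with_ari()].
#' @param path JSON path.
#' @param statistic Optional name of the correlated statistic.
#' @return `path`, invisibly.
#' @export
write_correlation_json <- function(result, path, statistic = NULL) {
  x <- list(statistic = statistic, pearson_r = result$pearson_r,
            slope = result$slope, intercept = result$intercept,
            n_points = result$n_points)
  x <- x[!vapply(x, is.null, logical(1))]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
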