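# Reading and writing Trikinetics-style DAM monitor files.
#
# The default dialect is the common DAMSystem monitor export: 42 tab-separated
# fields per line -- reading index, date ("D Mon YY"), time ("HH:MM:SS"),
# status code, 5 padding fields, light flag, then 32 channel counts. No header.

MONTHS_ABB <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

#' DAM file dialect options
#'
#' @param n_fields Total tab-separated fields per line.
#' @param n_channels Number of count channels (the trailing fields).
#' @param n_padding Padding fields between the status code and the light flag.
#' @param date_format One of `"dmony"` (`"1 Jan 17"`) or `"iso"`
#'   (`"2017-01-01"`).
#' @return A list of dialect options.
#' @export
dam_dialect <- function(n_fields = 42, n_channels = 32, n_padding = 5,
                        date_format = c("dmony", "iso")) {
  date_format <- match.arg(date_format)
  stopifnot(n_fields == 4 + n_padding + 1 + n_channels)
  list(n_fields = n_fields, n_channels = n_channels, n_padding = n_padding,
       date_format = date_format)
}

#' Construct a monitor table
#'
#' A monitor table holds the parsed readings of one DAM monitor: one row per
#' reading, 32 channel-count columns, with strictly increasing indices and
#' equally spaced timestamps. Readings with a status code other than 1 are
#' kept but listed in the attached validation report; downstream extraction
#' masks them.
#'
#' @param timestamps `POSIXct` vector, strictly increasing with constant
#'   spacing.
#' @param counts Integer matrix, one row per reading, `n_channels` columns,
#'   all values >= 0.
#' @param status Integer status codes (1 = valid); recycled from a scalar.
#' @param index Reading indices; default `1:n`.
#' @param monitor_id Text label.
#' @param light Light flags (0/1); recycled.
#' @param validation A data.frame describing flagged lines/readings
#'   (columns `line`, `reason`); empty by default.
#' @return An object of class `monitor_table`.
#' @export
monitor_table <- function(timestamps, counts, status = 1L, index = NULL,
                          monitor_id = "M1", light = 0L,
                          validation = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  stopifnot(length(timestamps) == n, all(counts >= 0))
  if (is.null(index)) index <- seq_len(n)
  if (length(status) == 1L) status <- rep(as.integer(status), n)
  if (length(light) == 1L) light <- rep(as.integer(light), n)
  if (n > 1) {
    d <- diff(as.numeric(timestamps))
    if (any(d <= 0)) stop("timestamps must be strictly increasing")
    if (max(d) - min(d) > 1e-6) stop("timestamps must be equally spaced")
    if (any(diff(index) <= 0)) stop("reading indices must be strictly increasing")
    interval_min <- d[1] / 60
  } else {
    interval_min <- 1
  }
  if (is.null(validation)) {
    validation <- data.frame(line = integer(0), reason = character(0),
                             stringsAsFactors = FALSE)
  }
  non_ok <- which(status != 1L)
  for (i in non_ok) {
    if (!any(validation$line == i & validation$reason == "status")) {
      validation <- rbind(validation,
                          data.frame(line = i,
                                     reason = "status",
                                     stringsAsFactors = FALSE))
    }
  }
  structure(
    list(monitor_id = as.character(monitor_id), index = as.integer(index),
         timestamps = timestamps, status = as.integer(status),
         light = as.integer(light),
         counts = matrix(as.integer(counts), nrow = n, ncol = ncol(counts)),
         reading_interval = interval_min, validation = validation),
    class = "monitor_table"
  )
}

#' @export
print.monitor_table <- function(x, ...) {
  cat(sprintf(
    "monitor_table '%s': %d readings x %d channels, %g-min interval, %d flagged\n",
    x$monitor_id, nrow(x$counts), ncol(x$counts), x$reading_interval,
    nrow(x$validation)))
  invisible(x)
}

format_dam_date <- function(t, date_format) {
  lt <- as.POSIXlt(t, tz = "UTC")
  if (date_format == "iso") {
    format(t, "%Y-%m-%d")
  } else {
    sprintf("%d %s %02d", lt$mday, MONTHS_ABB[lt$mon + 1], lt$year %% 100)
  }
}

parse_dam_datetime <- function(date_str, time_str, date_format) {
  if (date_format == "iso") {
    out <- as.POSIXct(paste(date_str, time_str), tz = "UTC",
                      format = "%Y-%m-%d %H:%M:%S")
  } else {
    parts <- strsplit(trimws(date_str), "[ ]+")
    day <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1)))
    mon <- match(vapply(parts, `[`, "", 2), MONTHS_ABB)
    yy <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
    year <- ifelse(yy < 70, 2000 + yy, 1900 + yy)
    out <- as.POSIXct(sprintf("%04d-%02d-%02d %s", year, mon, day, time_str),
                      tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
    out[is.na(day) | is.na(mon) | is.na(yy)] <- NA
  }
  out
}

#' Read a DAM monitor file
#'
#' Parses a tab-separated Trikinetics-style monitor file into a
#' [monitor_table()]. Readings with a status code other than 1 are kept and
#' recorded in the table's validation report, never silently dropped. Files
#' whose lines are out of time order are rejected unless `resort = TRUE`.
#'
#' @param path File path.
#' @param dialect A [dam_dialect()].
#' @param monitor_id Label for the table; default the file name.
#' @param resort If `TRUE`, re-sort out-of-order lines by timestamp instead of
#'   failing.
#' @return A [monitor_table()].
#' @export
read_monitor_file <- function(path, dialect = dam_dialect(),
                              monitor_id = basename(path), resort = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(monitor_table(as.POSIXct(character(0), tz = "UTC"),
                         matrix(integer(0), 0, dialect$n_channels),
                         status = integer(0), index = integer(0),
                         monitor_id = monitor_id))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != dialect$n_fields)) {
    bad <- which(nf != dialect$n_fields)[1]
    stop(sprintf(
      "line %d has %d tab-separated fields, expected %d; check the dialect (n_fields/n_channels)",
      bad, nf[bad], dialect$n_fields))
  }
  m <- matrix(unlist(fields), nrow = length(lines), byrow = TRUE)
  ts <- parse_dam_datetime(m[, 2], m[, 3], dialect$date_format)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf("unparseable date/time on line %d: '%s %s'",
                 bad, m[bad, 2], m[bad, 3]))
  }
  idx <- as.integer(m[, 1])
  status <- as.integer(m[, 4])
  light_col <- 4 + dialect$n_padding + 1
  light <- as.integer(m[, light_col])
  counts <- matrix(as.integer(m[, (light_col + 1):dialect$n_fields]),
                   nrow = length(lines))
  if (anyNA(counts) || any(counts < 0)) {
    stop("non-numeric or negative channel counts found")
  }
  ord <- seq_along(ts)
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    if (!resort) {
      stop("timestamps are not strictly increasing; pass resort = TRUE to re-sort")
    }
    ord <- order(ts)
  }
  monitor_table(ts[ord], counts[ord, , drop = FALSE], status = status[ord],
                index = idx[ord], monitor_id = monitor_id,
                light = light[ord])
}

#' Write a DAM monitor file
#'
#' Emits tab-separated text in the table's dialect, one reading per line:
#' index, date, time, status, padding fields, light flag, and the channel
#' counts. [read_monitor_file()] on the output reproduces the table.
#'
#' @param table A [monitor_table()].
#' @param path Output file path.
#' @param dialect A [dam_dialect()]; channel count must match the table.
#' @return Invisibly, `path`.
#' @export
write_monitor_file <- function(table, path, dialect = dam_dialect()) {
  stopifnot(inherits(table, "monitor_table"))
  n <- nrow(table$counts)
  if (ncol(table$counts) != dialect$n_channels) {
    stop("table channel count does not match the dialect")
  }
  if (n == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  pad <- matrix("0", n, dialect$n_padding)
  lines <- paste(
    table$index,
    format_dam_date(table$timestamps, dialect$date_format),
    format(table$timestamps, "%H:%M:%S"),
    table$status,
    apply(pad, 1, paste, collapse = "\t"),
    table$light,
    apply(table$counts, 1, paste, collapse = "\t"),
    sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Extract one channel as an activity series
#'
#' @param table A [monitor_table()].
#' @param channel Channel number, 1-32.
#' @param schedule A [light_schedule()] attached to the series.
#' @param fly_id Label; default `"<monitor>:ch<channel>"`.
#' @return An [activity_series()] at the table's native bin size. Bins from
#'   non-status-1 readings are masked. The series total equals the column
#'   sum of the table.
#' @export
to_activity_series <- function(table, channel, schedule = light_schedule(),
                               fly_id = NULL) {
  stopifnot(inherits(table, "monitor_table"))
  if (channel < 1 || channel > ncol(table$counts)) {
    stop(sprintf("channel must be in 1..%d", ncol(table$counts)))
  }
  if (is.null(fly_id)) {
    fly_id <- sprintf("%s:ch%02d", table$monitor_id, as.integer(channel))
  }
  activity_series(table$counts[, channel],
                  start = table$timestamps[1],
                  bin_minutes = table$reading_interval,
                  schedule = schedule, fly_id = fly_id,
                  mask = table$status == 1L)
}
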