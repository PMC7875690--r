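#' @keywords internal
#' @import stats
#' @importFrom jsonlite fromJSON toJSON
#' @importFrom utils head read.csv
"_PACKAGE"

## Event-stream data model ----------------------------------------------------

EVENT_KINDS <- c("activity", "steps", "location", "heartbeat", "screen",
                 "interaction", "plan_created")
ACTIVITY_CLASSES <- c("still", "walking", "running", "cycling", "in_vehicle",
                      "unknown")
SCREEN_STATES <- c("on", "off")
INTERACTION_VIEWS <- c("daily_vis", "multiday_vis", "plan_list", "dashboard")
INTERACTION_SOURCES <- c("notification", "dashboard", "shortcut")

# canonical (all-NA-able) payload columns shared by every record
PAYLOAD_COLS <- c("activity_class", "confidence", "step_delta", "lat", "lon",
                  "accuracy_m", "screen_state", "view", "source", "plan_id")

empty_records <- function() {
  df <- data.frame(
    ts = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
    kind = character(0),
    activity_class = character(0), confidence = numeric(0),
    step_delta = numeric(0), lat = numeric(0), lon = numeric(0),
    accuracy_m = numeric(0), screen_state = character(0),
    view = character(0), source = character(0), plan_id = character(0),
    stringsAsFactors = FALSE
  )
  df
}

#' Construct an event stream
#'
#' An event stream is the raw substrate of the toolkit: the time-ordered
#' record of everything a participant's phone logged — activity-transition
#' records, step deltas, location fixes, 20-minute liveness heartbeats,
#' screen on/off events, in-app interactions, and plan-creation stamps.
#' Timestamps are stored in UTC; the stream carries the participant's IANA
#' timezone so that all clock-hour binning can use local time.
#'
#' @param participant_id single string identifying the participant.
#' @param tz IANA timezone name (e.g. \code{"Europe/Berlin"}).
#' @param records data frame with columns \code{ts} (POSIXct, UTC),
#'   \code{kind}, and the kind-specific payload columns (others \code{NA}).
#' @return an object of class \code{event_stream}.
#' @export
event_stream <- function(participant_id, tz = "UTC", records = empty_records()) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  if (!tz %in% OlsonNames()) stop("unknown IANA timezone: ", tz)
  records <- normalize_records(records)
  records <- sort_records(records)
  validate_records(records)
  structure(list(participant_id = participant_id, tz = tz, records = records),
            class = "event_stream")
}

normalize_records <- function(records) {
  stopifnot(is.data.frame(records))
  tmpl <- empty_records()
  for (col in names(tmpl)) {
    if (!col %in% names(records)) records[[col]] <- rep(NA, nrow(records))
    mode_fun <- if (is.character(tmpl[[col]])) as.character else
      if (inherits(tmpl[[col]], "POSIXct")) identity else as.numeric
    records[[col]] <- mode_fun(records[[col]])
  }
  records <- records[, names(tmpl), drop = FALSE]
  # the data model is ms-resolution; quantize so log round-trips are exact
  records$ts <- as.POSIXct(round(as.numeric(records$ts) * 1000) / 1000,
                           origin = "1970-01-01", tz = "UTC")
  rownames(records) <- NULL
  records
}

# stable sort: ts, then declared kind order, then input position
sort_records <- function(records) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$ts, match(records$kind, EVENT_KINDS), method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_records <- function(records, line_no = NULL) {
  fail <- function(i, field, msg) {
    where <- if (is.null(line_no)) sprintf("record %d", i) else
      sprintf("line %d", line_no[i])
    stop(sprintf("%s, field '%s': %s", where, field, msg), call. = FALSE)
  }
  first_bad <- function(bad, field, msg) {
    i <- which(bad)
    if (length(i)) fail(i[1L], field, msg)
  }
  k <- records$kind
  first_bad(is.na(records$ts), "ts", "missing or unparseable timestamp")
  first_bad(!k %in% EVENT_KINDS, "kind", "unknown kind")
  a <- k == "activity"
  first_bad(a & (is.na(records$activity_class) |
                   !records$activity_class %in% ACTIVITY_CLASSES),
            "activity_class", "must be one of the activity classes")
  first_bad(a & (is.na(records$confidence) | records$confidence < 0 |
                   records$confidence > 100),
            "confidence", "must be in [0, 100]")
  s <- k == "steps"
  first_bad(s & (is.na(records$step_delta) | records$step_delta < 0),
            "step_delta", "must be a non-negative number")
  l <- k == "location"
  first_bad(l & (is.na(records$lat) | abs(records$lat) > 90),
            "lat", "must be in [-90, 90]")
  first_bad(l & (is.na(records$lon) | abs(records$lon) > 180),
            "lon", "must be in [-180, 180]")
  first_bad(k == "screen" & (is.na(records$screen_state) |
                               !records$screen_state %in% SCREEN_STATES),
            "screen_state", "must be 'on' or 'off'")
  ia <- k == "interaction"
  first_bad(ia & (is.na(records$view) | !records$view %in% INTERACTION_VIEWS),
            "view", "must be a known view")
  first_bad(ia & (is.na(records$source) |
                    !records$source %in% INTERACTION_SOURCES),
            "source", "must be a known source")
  first_bad(k == "plan_created" & is.na(records$plan_id), "plan_id", "required")
  invisible(records)
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("<event_stream> participant %s, tz %s, %d records\n",
              x$participant_id, x$tz, nrow(x$records)))
  if (nrow(x$records) > 0) {
    cat(sprintf("  %s .. %s\n", format(min(x$records$ts)), format(max(x$records$ts))))
    print(table(x$records$kind))
  }
  invisible(x)
}

## Timestamp helpers ----------------------------------------------------------

# parse ISO-8601 with offset ("2026-03-01T08:00:00.500+01:00" or "Z"),
# millisecond resolution, returned as UTC POSIXct
parse_ts <- function(x) {
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OS%z", tz = "UTC")
  # round to ms so that write/parse round-trips are exact
  as.POSIXct(round(as.numeric(out) * 1000) / 1000, origin = "1970-01-01", tz = "UTC")
}

# format UTC POSIXct as ISO-8601 +00:00 at ms precision (no %OS truncation)
format_ts <- function(ts) {
  ms_total <- round(as.numeric(ts) * 1000)
  secs <- floor(ms_total / 1000)
  ms <- ms_total - secs * 1000
  base <- format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
                 "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  sprintf("%s.%03d+00:00", base, ms)
}

## Log format (newline-delimited JSON, one record per line) -------------------

#' Parse a newline-delimited JSON event log
#'
#' Each non-empty line is one JSON object with fields \code{ts} (ISO-8601
#' with offset), \code{kind}, and the payload keys of that kind. Records are
#' returned sorted by timestamp (ties: kind order, then input order) and
#' validated against the payload invariants.
#'
#' @param lines character vector of log lines, or a file path (single string
#'   naming an existing file).
#' @param participant_id,tz stream metadata; participants are one-file-one-id.
#' @return an \code{event_stream}.
#' @export
parse_event_log <- function(lines, participant_id = "unknown", tz = "UTC") {
  if (length(lines) == 1L && !grepl("[{\n]", lines) && file.exists(lines))
    lines <- readLines(lines, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L)
    return(event_stream(participant_id, tz))
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) stop(sprintf(
                      "line %d: malformed JSON (%s)", i, conditionMessage(e)),
                      call. = FALSE))
    if (is.null(obj$ts) || is.null(obj$kind))
      stop(sprintf("line %d: missing 'ts' or 'kind'", i), call. = FALSE)
    row <- list(ts = parse_ts(obj$ts), kind = as.character(obj$kind))
    for (col in PAYLOAD_COLS)
      row[[col]] <- if (is.null(obj[[col]])) NA else obj[[col]]
    rows[[j]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  records <- normalize_records(records)
  validate_records(records, line_no = keep)
  ord <- order(records$ts, match(records$kind, EVENT_KINDS), method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  structure(list(participant_id = participant_id, tz = tz, records = records),
            class = "event_stream")
}

#' Serialize an event stream to newline-delimited JSON
#'
#' The inverse of [parse_event_log()]: \code{parse_event_log(write_event_log(s))}
#' reproduces \code{s} exactly.
#'
#' @param stream an \code{event_stream}.
#' @param path optional file to write to.
#' @return character vector of log lines (invisibly when \code{path} given).
#' @export
write_event_log <- function(stream, path = NULL) {
  stopifnot(inherits(stream, "event_stream"))
  rec <- stream$records
  lines <- character(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    obj <- list(ts = format_ts(rec$ts[i]), kind = rec$kind[i])
    for (col in PAYLOAD_COLS) {
      v <- rec[[col]][i]
      if (!is.na(v)) obj[[col]] <- v
    }
    # digits = I(17): shortest-exact is not available, 17 significant digits
    # guarantee the double round-trips bit for bit
    lines[i] <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

## Coverage -------------------------------------------------------------------

#' Compute heartbeat-based data coverage
#'
#' The logger writes a heartbeat every 20 minutes precisely so that silence
#' can be told apart from stillness: any record is liveness evidence, and a
#' silence longer than \code{max_gap_minutes} is an outage gap. Covered time
#' is the window minus the union of such gaps (the flanks before the first
#' and after the last record count as gaps when they exceed the tolerance).
#'
#' @param stream an \code{event_stream}.
#' @param window length-2 POSIXct (start, end), end > start.
#' @param max_gap_minutes gap tolerance; default 25 = 20-min heartbeat period
#'   plus 5 minutes of scheduling slack.
#' @return a \code{coverage_report}: list with \code{window}, \code{gaps}
#'   (data frame start/end), \code{covered_fraction}, and
#'   \code{per_day_fraction} (named by local date).
#' @export
compute_coverage <- function(stream, window, max_gap_minutes = 25) {
  stopifnot(inherits(stream, "event_stream"), length(window) == 2L)
  window <- as.POSIXct(window, tz = "UTC")
  if (!window[2] > window[1]) stop("window end must be after window start")
  stopifnot(max_gap_minutes > 0)
  max_gap <- max_gap_minutes * 60

  ts <- as.numeric(stream$records$ts)
  ts <- sort(ts[ts >= as.numeric(window[1]) & ts <= as.numeric(window[2])])
  pts <- c(as.numeric(window[1]), ts, as.numeric(window[2]))
  d <- diff(pts)
  gap_idx <- which(d > max_gap)
  gaps <- data.frame(start = pts[gap_idx], end = pts[gap_idx + 1L])
  total_gap <- sum(gaps$end - gaps$start)
  win_len <- as.numeric(window[2]) - as.numeric(window[1])
  covered_fraction <- 1 - total_gap / win_len

  # per local day fraction over the day's intersection with the window
  day_starts <- local_day_seq(window, stream$tz)
  per_day <- vapply(seq_len(nrow(day_starts)), function(i) {
    lo <- max(day_starts$start[i], as.numeric(window[1]))
    hi <- min(day_starts$end[i], as.numeric(window[2]))
    if (hi <= lo) return(NA_real_)
    ov <- overlap_total(gaps, lo, hi)
    1 - ov / (hi - lo)
  }, numeric(1))
  names(per_day) <- day_starts$date

  structure(list(
    window = window,
    gaps = data.frame(
      start = as.POSIXct(gaps$start, origin = "1970-01-01", tz = "UTC"),
      end = as.POSIXct(gaps$end, origin = "1970-01-01", tz = "UTC")),
    covered_fraction = covered_fraction,
    per_day_fraction = per_day[!is.na(per_day)],
    max_gap_minutes = max_gap_minutes,
    tz = stream$tz
  ), class = "coverage_report")
}

# sum of overlap between [lo, hi] and a set of disjoint [start, end] intervals
overlap_total <- function(intervals, lo, hi) {
  if (nrow(intervals) == 0L) return(0)
  sum(pmax(0, pmin(intervals$end, hi) - pmax(intervals$start, lo)))
}

# local calendar days (start/end instants in epoch seconds) touching a window
local_day_seq <- function(window, tz) {
  d1 <- as.Date(format(window[1], "%Y-%m-%d", tz = tz))
  d2 <- as.Date(format(window[2] - 1e-3, "%Y-%m-%d", tz = tz))
  dates <- seq(d1, d2, by = "day")
  starts <- as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = tz))
  ends <- as.numeric(as.POSIXct(paste(dates + 1, "00:00:00"), tz = tz))
  data.frame(date = as.character(dates), start = starts, end = ends)
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %s .. %s\n covered %.2f%%, %d gap(s) > %g min\n",
              format(x$window[1]), format(x$window[2]),
              100 * x$covered_fraction, nrow(x$gaps), x$max_gap_minutes))
  invisible(x)
}
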