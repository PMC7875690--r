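## Visualization-ready pattern aggregates ---------------------------------------
## These structures back the two feedback views: the daily view (hour bars
## linked to trajectories and places on a map) and the multi-day view
## (per-hour sedentary frequency across selected days, optionally for one
## place). Interactivity in the original app reduces here to the
## hour-to-place link table.

#' Assemble the daily pattern for one date
#'
#' @param stream the \code{event_stream}.
#' @param labeled_bins labeled bins from [label_hours()] on the same stream.
#' @param place_set a \code{place_set} from [cluster_places()].
#' @param date local date.
#' @return a \code{daily_pattern}: list with \code{date}, \code{hour_bars}
#'   (24 rows: hour, label, steps), \code{trajectories} (one entry per fix
#'   run between consecutive stay points: fixes, step_total, start/end),
#'   \code{places} (places with dwell on the date), and
#'   \code{hour_place_links} (sedentary-hour -> place_id).
#' @export
daily_pattern <- function(stream, labeled_bins, place_set, date) {
  date <- as.character(date)
  bars <- labeled_bins[labeled_bins$date == date,
                       c("hour", "label", "steps"), drop = FALSE]
  if (nrow(bars) == 0L) stop("date ", date, " outside the stream window")
  rownames(bars) <- NULL
  tz <- stream$tz
  day_start <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = tz))
  day_end <- day_start + 86400

  # trajectories: fix runs between consecutive stay points, clipped to the day
  fixes <- location_fixes(stream)
  sp <- place_set$stay_points
  rec <- stream$records
  step_ts <- as.numeric(rec$ts[rec$kind == "steps"])
  step_dx <- rec$step_delta[rec$kind == "steps"]
  bounds <- sort(unique(c(day_start,
                          as.numeric(sp$start_ts), as.numeric(sp$end_ts),
                          day_end)))
  trajectories <- list()
  # moving intervals = day minus stay-point intervals
  if (nrow(sp) > 0L) {
    stays <- data.frame(start = as.numeric(sp$start_ts), end = as.numeric(sp$end_ts))
    stays <- stays[order(stays$start), , drop = FALSE]
  } else stays <- data.frame(start = numeric(0), end = numeric(0))
  cur <- day_start
  gaps <- list()
  for (i in seq_len(nrow(stays))) {
    s <- max(stays$start[i], day_start); e <- min(stays$end[i], day_end)
    if (e <= day_start || s >= day_end) next
    if (s > cur) gaps[[length(gaps) + 1L]] <- c(cur, s)
    cur <- max(cur, e)
  }
  if (cur < day_end) gaps[[length(gaps) + 1L]] <- c(cur, day_end)
  fts <- as.numeric(fixes$ts)
  for (g in gaps) {
    sel <- fts >= g[1] & fts < g[2]
    if (sum(sel) < 2L) next  # no tracked movement in this interval
    trajectories[[length(trajectories) + 1L]] <- list(
      start_ts = as.POSIXct(g[1], origin = "1970-01-01", tz = "UTC"),
      end_ts = as.POSIXct(g[2], origin = "1970-01-01", tz = "UTC"),
      fixes = fixes[sel, c("ts", "lat", "lon")],
      step_total = sum(step_dx[step_ts >= g[1] & step_ts < g[2]]))
  }

  links <- link_sedentary_hours(place_set, labeled_bins[labeled_bins$date == date, ],
                                tz = tz)
  day_places <- place_set$places[place_set$places$place_id %in%
                                   unique(place_set$stay_points$place_id[
                                     !is.na(place_set$stay_points$place_id) &
                                     as.numeric(place_set$stay_points$end_ts) > day_start &
                                     as.numeric(place_set$stay_points$start_ts) < day_end]),
                                 , drop = FALSE]
  structure(list(date = date, hour_bars = bars, trajectories = trajectories,
                 places = day_places, hour_place_links = links),
            class = "daily_pattern")
}

#' Aggregate daily patterns into a multi-day pattern
#'
#' For each clock hour, counts on how many of the selected days the hour was
#' sedentary — restricted, when \code{place_filter} is given, to hours linked
#' to that place.
#'
#' @param daily_patterns list of \code{daily_pattern} objects (>= 1).
#' @param place_filter optional place_id.
#' @return a \code{multiday_pattern}: list with \code{dates},
#'   \code{place_filter}, \code{hour_freq} (data frame hour 0-23, count).
#' @export
multiday_pattern <- function(daily_patterns, place_filter = NULL) {
  if (length(daily_patterns) == 0L) stop("empty day selection")
  counts <- integer(24)
  for (dp in daily_patterns) {
    sed_hours <- dp$hour_bars$hour[dp$hour_bars$label == "sedentary"]
    if (!is.null(place_filter)) {
      linked <- dp$hour_place_links
      sed_hours <- intersect(sed_hours,
                             linked$hour[linked$place_id == place_filter])
    }
    counts[sed_hours + 1L] <- counts[sed_hours + 1L] + 1L
  }
  structure(list(dates = vapply(daily_patterns, `[[`, "", "date"),
                 place_filter = place_filter,
                 hour_freq = data.frame(hour = 0:23, count = counts)),
            class = "multiday_pattern")
}

#' Serialize a pattern to JSON
#'
#' Schema-stable JSON for downstream plotting; [parse_pattern_json()]
#' round-trips the aggregate fields.
#'
#' @param pattern a \code{daily_pattern} or \code{multiday_pattern}.
#' @param path optional output file.
#' @return JSON string.
#' @export
export_pattern_json <- function(pattern, path = NULL) {
  obj <- if (inherits(pattern, "multiday_pattern")) {
    list(type = "multiday", dates = as.list(pattern$dates),
         place_filter = pattern$place_filter,
         hour_freq = pattern$hour_freq)
  } else if (inherits(pattern, "daily_pattern")) {
    list(type = "daily", date = pattern$date,
         hour_bars = pattern$hour_bars,
         n_trajectories = length(pattern$trajectories),
         trajectories = lapply(pattern$trajectories, function(tr)
           list(start_ts = format_ts(tr$start_ts), end_ts = format_ts(tr$end_ts),
                step_total = tr$step_total, n_fixes = nrow(tr$fixes))),
         places = pattern$places[, c("place_id", "lat", "lon", "radius_m",
                                     "total_dwell_min")],
         hour_place_links = pattern$hour_place_links)
  } else stop("not a pattern object")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Parse pattern JSON
#'
#' @param js JSON string from [export_pattern_json()].
#' @return list mirroring the serialized structure.
#' @export
parse_pattern_json <- function(js) {
  jsonlite::fromJSON(js, simplifyVector = TRUE)
}
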