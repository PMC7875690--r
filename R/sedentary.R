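## Hourly binning and the 250-step sedentary rule ------------------------------

#' Labeling configuration
#'
#' An hour is sedentary when fewer than \code{threshold} steps were recorded
#' in it (strict less-than; 250 steps is roughly the two minutes of walking
#' per hour associated with lower mortality risk, and is the Fitbit hourly
#' goal). Hours with less than \code{min_coverage} of their duration backed
#' by liveness evidence are labeled \code{unknown} rather than sedentary: a
#' switched-off phone looks exactly like a still one.
#'
#' @param threshold step count; an hour with strictly fewer steps is sedentary.
#' @param min_coverage minimum covered fraction for an hour to be labelable.
#' @return a \code{label_config} list.
#' @export
label_config <- function(threshold = 250L, min_coverage = 0.5) {
  stopifnot(threshold > 0, min_coverage >= 0, min_coverage <= 1)
  structure(list(threshold = as.integer(threshold), min_coverage = min_coverage),
            class = "label_config")
}

#' Bin step activity into local clock hours
#'
#' Produces one bin per local clock hour \code{[h:00, h+1:00)} intersecting
#' the coverage window. Steps are the sum of step deltas with timestamps in
#' the bin (half-open: an event at exactly h:00 belongs to hour h). The
#' covered fraction of a bin is covered time inside the bin divided by the
#' full bin length, so partial edge bins are penalized.
#'
#' @param stream an \code{event_stream}.
#' @param coverage a \code{coverage_report} computed on the same stream.
#' @return data frame with columns \code{participant_id}, \code{date} (local),
#'   \code{hour}, \code{steps}, \code{covered_fraction}, \code{label}
#'   (all \code{NA} until [label_hours()]).
#' @export
bin_hours <- function(stream, coverage) {
  stopifnot(inherits(stream, "event_stream"), inherits(coverage, "coverage_report"))
  tz <- stream$tz
  window <- coverage$window
  ws <- as.numeric(window[1]); we <- as.numeric(window[2])

  # local hour grid covering the window
  first_local <- as.POSIXct(format(window[1], "%Y-%m-%d %H:00:00", tz = tz), tz = tz)
  grid <- seq(first_local, window[2], by = "hour")
  if (as.numeric(grid[length(grid)]) < we)
    grid <- c(grid, grid[length(grid)] + 3600)
  starts <- as.numeric(grid[-length(grid)])
  ends <- as.numeric(grid[-1L])

  rec <- stream$records
  step_ts <- as.numeric(rec$ts[rec$kind == "steps"])
  step_dx <- rec$step_delta[rec$kind == "steps"]
  gaps <- data.frame(start = as.numeric(coverage$gaps$start),
                     end = as.numeric(coverage$gaps$end))

  n <- length(starts)
  # steps per bin: half-open [start, end) via findInterval on the hour grid
  steps <- integer(n)
  if (length(step_ts)) {
    bin_of <- findInterval(step_ts, starts)
    ok <- bin_of >= 1L & step_ts < ends[pmax(bin_of, 1L)]
    agg <- tapply(step_dx[ok], bin_of[ok], sum)
    steps[as.integer(names(agg))] <- as.integer(round(agg))
  }
  covf <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(starts[i], ws); hi <- min(ends[i], we)
    cov_time <- if (hi <= lo) 0 else (hi - lo) - overlap_total(gaps, lo, hi)
    covf[i] <- cov_time / (ends[i] - starts[i])
  }
  mid <- as.POSIXct(starts, origin = "1970-01-01", tz = "UTC")
  data.frame(
    participant_id = stream$participant_id,
    date = format(mid, "%Y-%m-%d", tz = tz),
    hour = as.integer(format(mid, "%H", tz = tz)),
    steps = steps,
    covered_fraction = covf,
    label = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Apply the sedentary/active/unknown labels
#'
#' @param bins output of [bin_hours()].
#' @param cfg a [label_config()].
#' @return \code{bins} with \code{label} filled in.
#' @export
label_hours <- function(bins, cfg = label_config()) {
  stopifnot(is.data.frame(bins), inherits(cfg, "label_config"))
  bins$label <- ifelse(bins$covered_fraction < cfg$min_coverage, "unknown",
                       ifelse(bins$steps < cfg$threshold, "sedentary", "active"))
  bins
}

#' Daily sedentary hours
#'
#' Counts the hours labeled sedentary on one local date. Unknown hours are
#' excluded from the count (not imputed) and reported via the
#' \code{unknown_hours} attribute. Note that without sleep detection the
#' count includes sleeping time; baseline-vs-intervention change scores
#' difference it out under stable sleep.
#'
#' @param bins labeled bins from [label_hours()].
#' @param date local date (string or Date).
#' @return integer count with attribute \code{unknown_hours}.
#' @export
daily_sedentary_hours <- function(bins, date) {
  day <- bins[bins$date == as.character(date), , drop = FALSE]
  out <- sum(day$label == "sedentary", na.rm = TRUE)
  attr(out, "unknown_hours") <- sum(day$label == "unknown", na.rm = TRUE)
  out
}

#' Per-day label summary for one or more participants
#'
#' @param bins labeled bins (may span participants).
#' @return data frame: participant_id, date, sedentary, active, unknown.
#' @export
daily_hour_summary <- function(bins) {
  agg <- aggregate(cbind(sedentary = bins$label == "sedentary",
                         active = bins$label == "active",
                         unknown = bins$label == "unknown"),
                   by = list(participant_id = bins$participant_id, date = bins$date),
                   FUN = sum)
  agg[order(agg$participant_id, agg$date), , drop = FALSE]
}

#' Baseline-vs-intervention change in daily sedentary hours
#'
#' Per participant, the mean daily sedentary hours are computed over the
#' baseline dates and over the intervention dates (excluded dates — e.g.
#' interview days with partial data — contribute to neither), and the change
#' is intervention minus baseline, so negative values are reductions.
#'
#' @param daily data frame with columns \code{participant_id}, \code{date},
#'   \code{sed_hours} (e.g. from [daily_hour_summary()], renaming
#'   \code{sedentary}).
#' @param baseline_dates,intervention_dates,excluded_dates character/Date
#'   vectors of local dates; baseline and intervention must be disjoint.
#' @return a \code{change_summary}: list with \code{per_participant} (data
#'   frame id, baseline_mean, intervention_mean, change) and group
#'   mean/sd/median of the changes.
#' @export
phase_change <- function(daily, baseline_dates, intervention_dates,
                         excluded_dates = character(0)) {
  stopifnot(all(c("participant_id", "date", "sed_hours") %in% names(daily)))
  baseline_dates <- as.character(baseline_dates)
  intervention_dates <- as.character(intervention_dates)
  excluded_dates <- as.character(excluded_dates)
  if (length(intersect(baseline_dates, intervention_dates)) > 0)
    stop("baseline and intervention date sets overlap")
  daily <- daily[!daily$date %in% excluded_dates, , drop = FALSE]

  ids <- unique(daily$participant_id)
  rows <- lapply(ids, function(id) {
    d <- daily[daily$participant_id == id, ]
    b <- d$sed_hours[d$date %in% baseline_dates]
    iv <- d$sed_hours[d$date %in% intervention_dates]
    if (length(b) == 0L || length(iv) == 0L)
      stop("participant ", id, " has no data in one of the phases")
    data.frame(participant_id = id,
               baseline_mean = mean(b),
               intervention_mean = mean(iv),
               change = mean(iv) - mean(b),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  structure(list(
    per_participant = per,
    group_mean_change = mean(per$change),
    group_sd_change = if (nrow(per) > 1) sd(per$change) else 0,
    group_median_change = median(per$change)
  ), class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("<change_summary> n=%d: mean %+.2f, SD %.2f, median %+.2f h/day\n",
              nrow(x$per_participant), x$group_mean_change,
              x$group_sd_change, x$group_median_change))
  invisible(x)
}
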