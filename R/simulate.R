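## Synthetic participants with known ground truth --------------------------------
##
## The generator reproduces the logging semantics of the phone app, not human
## mobility at large: activity is sampled every 5 s but a record is written
## only on a state change; step deltas are written while stepping; location
## is updated only during movement; a heartbeat timestamp is written every
## 20 min; and background-service outages silence everything. Each stream
## comes with its ground truth (per-hour labels, place occupancy, daily
## sedentary hours, place centroids, check schedule), so every downstream
## module can be validated end to end without any real data.

#' A simulated place
#'
#' @param name place label (e.g. "home").
#' @param lat,lon WGS84 centre.
#' @param gps_noise_sd_m Gaussian noise SD applied to fixes near the place.
#' @return a \code{sim_place} list.
#' @export
sim_place <- function(name, lat, lon, gps_noise_sd_m = 5) {
  stopifnot(gps_noise_sd_m >= 0)
  structure(list(name = name, lat = lat, lon = lon,
                 gps_noise_sd_m = gps_noise_sd_m), class = "sim_place")
}

default_places <- function() {
  list(sim_place("home", 47.6780, 9.1650),
       sim_place("office", 47.6900, 9.1880),
       sim_place("cafe", 47.6850, 9.1780))
}

# An office-worker day. Blocks tile 24 h; "stay" blocks are still at a place,
# "walk" blocks move (commutes route between the previous and next stay
# places). steps_per_hour controls the hourly label: < 250 is sedentary.
default_schedule <- function() {
  data.frame(
    type = c("stay", "walk", "stay", "walk", "stay", "walk", "stay"),
    place = c("home", NA, "office", "cafe", "office", NA, "home"),
    start_hour = c(0, 8, 9, 12, 13, 17, 18),
    duration_h = c(8, 1, 3, 1, 4, 1, 6),
    steps_per_hour = c(0, 3000, 60, 800, 60, 3000, 80),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defaults emulate the pilot-study conditions: 20-min heartbeats, 5-s
#' activity sampling (change-only recording), an office-worker schedule with
#' three personal places, and no outages. One pseudo-random stream is used,
#' seeded once, so identical seeds give identical streams.
#'
#' @param places list of [sim_place()]s.
#' @param daily_schedule data frame of blocks (type, place, start_hour,
#'   duration_h, steps_per_hour) tiling 24 h without overlap.
#' @param heartbeat_min heartbeat period, minutes.
#' @param activity_sample_s activity sampling period, seconds.
#' @param outage_windows data frame (day, start_hour, end_hour) of logger
#'   outages (1-based study day).
#' @param n_days number of simulated days.
#' @param seed integer seed.
#' @param effect_hours_per_day injected change in daily sedentary hours from
#'   \code{effect_start_day} on (negative = reduction); realized by
#'   converting the tail of the day's latest sedentary block time into
#'   walking, with fractional effects spread across days so the mean matches.
#' @param effect_start_day first study day (1-based) the effect applies to.
#' @param checks_per_day mean number of visualization checks emitted per day
#'   (Poisson); sources are drawn notification-vs-dashboard at the observed
#'   pilot split.
#' @param start_date first local date of the stream.
#' @param tz IANA timezone.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(places = default_places(),
                       daily_schedule = default_schedule(),
                       heartbeat_min = 20, activity_sample_s = 5,
                       outage_windows = NULL,
                       n_days = 7, seed = 1L,
                       effect_hours_per_day = 0, effect_start_day = NULL,
                       checks_per_day = 0,
                       start_date = "2026-03-02", tz = "Europe/Berlin") {
  sched <- daily_schedule[order(daily_schedule$start_hour), , drop = FALSE]
  ends <- sched$start_hour + sched$duration_h
  if (any(abs(sched$start_hour[-1] - ends[-nrow(sched)]) > 1e-9) ||
      sched$start_hour[1] != 0 || abs(ends[nrow(sched)] - 24) > 1e-9)
    stop("schedule blocks must tile 24 h without overlap")
  structure(list(places = places, daily_schedule = sched,
                 heartbeat_min = heartbeat_min,
                 activity_sample_s = activity_sample_s,
                 outage_windows = outage_windows, n_days = n_days,
                 seed = as.integer(seed),
                 effect_hours_per_day = effect_hours_per_day,
                 effect_start_day = effect_start_day,
                 checks_per_day = checks_per_day,
                 start_date = start_date, tz = tz),
            class = "sim_config")
}

place_by_name <- function(places, name) {
  for (p in places) if (p$name == name) return(p)
  stop("unknown place: ", name)
}

# metres -> degrees at a latitude
jitter_latlon <- function(lat, lon, sd_m, n = length(lat)) {
  dlat <- rnorm(n, 0, sd_m) / 111320
  dlon <- rnorm(n, 0, sd_m) / (111320 * cos(lat * pi / 180))
  list(lat = lat + dlat, lon = lon + dlon)
}

# realized per-day integer hour flips for a fractional mean effect
effect_flips <- function(effect_abs, day_index) {
  round(day_index * effect_abs) - round((day_index - 1) * effect_abs)
}

#' Simulate one participant
#'
#' @param cfg a [sim_config()].
#' @param participant_id id given to the generated stream.
#' @return list with \code{stream} (an \code{event_stream}) and \code{truth}:
#'   \code{hour_labels} (date, hour, steps, label), \code{daily_sed_hours},
#'   \code{occupancy} (date, hour, place, minutes), \code{place_centroids},
#'   \code{check_schedule}, \code{outages}.
#' @export
simulate_participant <- function(cfg, participant_id = "sim1") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tz <- cfg$tz
  day0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = tz)
  rows <- list()
  truth_hours <- list(); truth_occ <- list(); checks <- list()
  last_activity <- ""

  walk_rate_effect <- 1500  # steps/h for effect-injected walking tails

  eff_day0 <- if (is.null(cfg$effect_start_day)) cfg$n_days + 1L else
    cfg$effect_start_day
  eff_abs <- abs(cfg$effect_hours_per_day)
  eff_sign <- sign(cfg$effect_hours_per_day)

  for (day in seq_len(cfg$n_days)) {
    date <- format(day0 + (day - 1) * 86400, "%Y-%m-%d", tz = tz)
    dstart <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = tz))
    sched <- cfg$daily_schedule
    # effect injection: convert the tail of the latest sedentary stay block(s)
    # into walking for `flips` whole hours (reduction), or the reverse sign
    # is ignored (only reductions are modelled)
    flips <- if (day >= eff_day0 && eff_sign < 0)
      effect_flips(eff_abs, day - eff_day0 + 1L) else 0L
    hourly_steps <- numeric(24)
    hourly_occ <- list()

    # expand schedule to per-hour programmed step rates and occupancy
    for (b in seq_len(nrow(sched))) {
      h0 <- sched$start_hour[b]; h1 <- h0 + sched$duration_h[b]
      rate <- sched$steps_per_hour[b]
      for (h in seq(floor(h0), ceiling(h1) - 1)) {
        frac <- min(h + 1, h1) - max(h, h0)
        if (frac <= 0) next
        hourly_steps[h + 1] <- hourly_steps[h + 1] + rate * frac
        if (sched$type[b] == "stay")
          hourly_occ[[length(hourly_occ) + 1L]] <- data.frame(
            date = date, hour = h, place = sched$place[b],
            minutes = 60 * frac, stringsAsFactors = FALSE)
      }
    }

    # choose hours to flip: latest sedentary stay hours of the day
    flip_hours <- integer(0)
    if (flips > 0L) {
      sed_stay_hours <- sort(unique(unlist(lapply(seq_len(nrow(sched)), function(b) {
        if (sched$type[b] != "stay") return(integer(0))
        hs <- seq(floor(sched$start_hour[b]),
                  ceiling(sched$start_hour[b] + sched$duration_h[b]) - 1)
        hs[hourly_steps[hs + 1] < 250]
      }))), decreasing = TRUE)
      flip_hours <- utils::head(sed_stay_hours, flips)
      hourly_steps[flip_hours + 1] <- walk_rate_effect
    }

    ## ---- emit records -------------------------------------------------------
    # heartbeats
    hb <- seq(dstart, dstart + 86399, by = cfg$heartbeat_min * 60)
    rows[[length(rows) + 1L]] <- data.frame(ts = hb, kind = "heartbeat")

    # per-block activity transitions, steps, fixes
    for (b in seq_len(nrow(sched))) {
      t0 <- dstart + sched$start_hour[b] * 3600
      t1 <- t0 + sched$duration_h[b] * 3600
      act <- if (sched$type[b] == "walk") "walking" else "still"
      if (act != last_activity) {
        rows[[length(rows) + 1L]] <- data.frame(
          ts = t0, kind = "activity", activity_class = act,
          confidence = round(runif(1, 85, 100)))
        last_activity <- act
      }
      # steps: per-minute integer deltas whose hourly sums match the
      # programmed rates exactly (cumulative rounding)
      block_hours <- seq(floor(sched$start_hour[b]),
                         ceiling(sched$start_hour[b] + sched$duration_h[b]) - 1)
      for (h in block_hours) {
        lo <- max(h, sched$start_hour[b]); hi <- min(h + 1, sched$start_hour[b] + sched$duration_h[b])
        if (hi <= lo) next
        if (h %in% flip_hours) {
          # the block owning the start of a flipped hour emits the whole
          # walking tail; other blocks sharing the hour emit nothing
          if (sched$type[b] != "stay" || lo > h) next
          share <- walk_rate_effect
        } else {
          share <- sched$steps_per_hour[b] * (hi - lo)
        }
        if (share <= 0) next
        mins <- seq(dstart + lo * 3600, dstart + hi * 3600 - 1, by = 60)
        cum <- round(seq_along(mins) / length(mins) * share)
        deltas <- diff(c(0, cum))
        keep <- deltas > 0
        if (any(keep)) rows[[length(rows) + 1L]] <- data.frame(
          ts = mins[keep], kind = "steps", step_delta = deltas[keep])
      }
      # location fixes only during movement
      if (sched$type[b] == "walk") {
        prev_b <- if (b > 1) b - 1 else nrow(sched)
        next_b <- if (b < nrow(sched)) b + 1 else 1
        from <- place_by_name(cfg$places, sched$place[prev_b])
        to <- place_by_name(cfg$places, sched$place[next_b])
        fts <- seq(t0, t1, by = 60)
        frac <- (fts - t0) / (t1 - t0)
        if (!is.na(sched$place[b])) {
          # walk anchored at a place: round trip prev -> place -> next
          via <- place_by_name(cfg$places, sched$place[b])
          out <- frac <= 0.5
          lat <- ifelse(out, from$lat + (via$lat - from$lat) * 2 * frac,
                        via$lat + (to$lat - via$lat) * (2 * frac - 1))
          lon <- ifelse(out, from$lon + (via$lon - from$lon) * 2 * frac,
                        via$lon + (to$lon - via$lon) * (2 * frac - 1))
        } else {
          lat <- from$lat + (to$lat - from$lat) * frac
          lon <- from$lon + (to$lon - from$lon) * frac
        }
        jj <- jitter_latlon(lat, lon, from$gps_noise_sd_m)
        rows[[length(rows) + 1L]] <- data.frame(
          ts = fts, kind = "location", lat = jj$lat, lon = jj$lon,
          accuracy_m = from$gps_noise_sd_m)
      }
    }

    # visualization checks
    if (cfg$checks_per_day > 0) {
      k <- rpois(1, cfg$checks_per_day)
      if (k > 0) {
        cts <- dstart + sort(runif(k, 8 * 3600, 22 * 3600))
        srcs <- ifelse(runif(k) < 302 / 442, "notification", "dashboard")
        views <- ifelse(runif(k) < 0.8, "daily_vis", "multiday_vis")
        rows[[length(rows) + 1L]] <- data.frame(
          ts = cts, kind = "interaction", view = views, source = srcs)
        checks[[length(checks) + 1L]] <- data.frame(
          date = date, n = k, stringsAsFactors = FALSE)
      }
    }

    ## ---- ground truth -------------------------------------------------------
    occ <- if (length(hourly_occ)) do.call(rbind, hourly_occ) else NULL
    if (!is.null(occ) && flips > 0L)
      occ$minutes[occ$hour %in% flip_hours] <- 0
    truth_occ[[length(truth_occ) + 1L]] <- occ
    truth_hours[[length(truth_hours) + 1L]] <- data.frame(
      date = date, hour = 0:23, steps = hourly_steps,
      label = ifelse(hourly_steps < 250, "sedentary", "active"),
      stringsAsFactors = FALSE)
  }

  rec <- do.call(rbind, lapply(rows, function(df) {
    df$ts <- as.POSIXct(df$ts, origin = "1970-01-01", tz = "UTC")
    normalize_records(df)
  }))

  # outages silence every record kind
  outs <- cfg$outage_windows
  if (!is.null(outs) && nrow(outs) > 0) {
    for (i in seq_len(nrow(outs))) {
      od <- as.numeric(day0) + (outs$day[i] - 1) * 86400
      o0 <- od + outs$start_hour[i] * 3600; o1 <- od + outs$end_hour[i] * 3600
      rec <- rec[!(as.numeric(rec$ts) >= o0 & as.numeric(rec$ts) < o1), ]
    }
  }

  stream <- event_stream(participant_id, tz = tz, records = rec)
  hours <- do.call(rbind, truth_hours)
  daily <- aggregate(list(sed_hours = hours$label == "sedentary"),
                     by = list(date = hours$date), FUN = sum)
  truth <- list(
    hour_labels = hours,
    daily_sed_hours = daily,
    occupancy = if (length(truth_occ)) do.call(rbind, truth_occ) else NULL,
    place_centroids = data.frame(
      name = vapply(cfg$places, `[[`, "", "name"),
      lat = vapply(cfg$places, `[[`, 0, "lat"),
      lon = vapply(cfg$places, `[[`, 0, "lon")),
    check_schedule = if (length(checks)) do.call(rbind, checks) else NULL,
    outages = outs)
  list(stream = stream, truth = truth)
}

#' Simulate a two-group study
#'
#' Builds the three-phase study timeline: an excluded entry day, a baseline
#' week, an excluded mid-study interview day, the intervention weeks, and an
#' excluded exit day. Group assignment alternates by enrollment index (odd
#' indices to group A). Group-specific effects are injected from the first
#' intervention day. Each participant's generator is seeded from
#' \code{(seed, index)}, so the bundle is reproducible and participants are
#' independent.
#'
#' @param nA,nB group sizes.
#' @param baseline_days,intervention_days phase lengths in days.
#' @param effect_A,effect_B injected change in daily sedentary hours
#'   (negative = reduction).
#' @param seed study-level seed.
#' @param checks_per_day mean daily visualization checks (group A only; the
#'   control group had no visualizations).
#' @param ... passed through to [sim_config()].
#' @return list with \code{participants} (each: id, group, stream, truth),
#'   \code{baseline_dates}, \code{intervention_dates}, \code{excluded_dates}.
#' @export
simulate_study <- function(nA = 8, nB = 8, baseline_days = 7,
                           intervention_days = 14, effect_A = 0, effect_B = 0,
                           seed = 1L, checks_per_day = 0, ...) {
  stopifnot(nA >= 1, nB >= 1)
  n_days <- 1 + baseline_days + 1 + intervention_days + 1
  start_date <- "2026-03-02"
  dates <- as.character(seq(as.Date(start_date), by = "day", length.out = n_days))
  excluded <- dates[c(1, baseline_days + 2, n_days)]
  baseline <- dates[2:(baseline_days + 1)]
  intervention <- dates[(baseline_days + 3):(n_days - 1)]
  eff_start <- baseline_days + 3

  participants <- list()
  for (i in seq_len(nA + nB)) {
    group <- if (i %% 2 == 1) "A" else "B"
    # skip once one group is full (sizes need not be equal)
    nA_so_far <- sum(vapply(participants, function(p) p$group == "A", TRUE))
    nB_so_far <- length(participants) - nA_so_far
    if (group == "A" && nA_so_far >= nA) group <- "B"
    if (group == "B" && nB_so_far >= nB) group <- "A"
    eff <- if (group == "A") effect_A else effect_B
    cfg <- sim_config(n_days = n_days, seed = cfg_seed(seed, i),
                      effect_hours_per_day = eff, effect_start_day = eff_start,
                      checks_per_day = if (group == "A") checks_per_day else 0,
                      start_date = start_date, ...)
    id <- sprintf("%s%d", group, if (group == "A") nA_so_far + 1 else nB_so_far + 1)
    sim <- simulate_participant(cfg, participant_id = id)
    participants[[length(participants) + 1L]] <-
      list(id = id, group = group, stream = sim$stream, truth = sim$truth)
  }
  list(participants = participants, baseline_dates = baseline,
       intervention_dates = intervention, excluded_dates = excluded,
       dates = dates)
}

# derived per-participant seed, kept inside 32-bit integer range
cfg_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% .Machine$integer.max)
}

#' Run the full sedentary pipeline on one simulated participant
#'
#' Convenience wrapper used by tests and examples: coverage, hour binning,
#' labeling, and daily summaries for one stream over its full span.
#'
#' @param stream an \code{event_stream}.
#' @param dates local dates to keep (default: all).
#' @param cfg a [label_config()].
#' @return list \code{coverage}, \code{bins} (labeled), \code{daily} (data
#'   frame participant_id, date, sed_hours).
#' @export
pipeline_daily_hours <- function(stream, dates = NULL, cfg = label_config()) {
  tz <- stream$tz
  rng <- range(stream$records$ts)
  d1 <- format(rng[1], "%Y-%m-%d", tz = tz)
  d2 <- format(rng[2], "%Y-%m-%d", tz = tz)
  window <- c(as.POSIXct(paste(d1, "00:00:00"), tz = tz),
              as.POSIXct(paste(as.Date(d2) + 1, "00:00:00"), tz = tz))
  cov <- compute_coverage(stream, window)
  bins <- label_hours(bin_hours(stream, cov), cfg)
  if (!is.null(dates)) bins <- bins[bins$date %in% as.character(dates), ]
  daily <- aggregate(list(sed_hours = bins$label == "sedentary"),
                     by = list(participant_id = bins$participant_id,
                               date = bins$date), FUN = sum)
  list(coverage = cov, bins = bins, daily = daily)
}
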