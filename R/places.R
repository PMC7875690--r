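## Personal sedentary-place detection ------------------------------------------
## stay-point extraction from location fixes, greedy spatial clustering,
## and linkage of sedentary hours to the place they were spent at.

EARTH_RADIUS_M <- 6371000

#' Great-circle distance (haversine)
#'
#' Spherical distance on the mean Earth radius (6,371 km). Adequate at the
#' sub-kilometre scales of personal place detection; no projection is used.
#'
#' @param lat1,lon1,lat2,lon2 WGS84 degrees (vectorized).
#' @return distance in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Place-detection configuration
#'
#' @param dist_threshold_m fixes within this distance of a run's first fix
#'   belong to the same stay candidate (default 50 m, about GPS accuracy
#'   indoors plus building scale).
#' @param time_threshold_min minimum dwell for a run to become a stay point.
#' @param merge_radius_m stay points within this distance of a place centroid
#'   join that place.
#' @param min_sedentary_dwell_min places with less total dwell are dropped.
#' @return a \code{place_config} list.
#' @export
place_config <- function(dist_threshold_m = 50, time_threshold_min = 10,
                         merge_radius_m = 50, min_sedentary_dwell_min = 30) {
  stopifnot(dist_threshold_m > 0, time_threshold_min > 0,
            merge_radius_m > 0, min_sedentary_dwell_min > 0)
  structure(list(dist_threshold_m = dist_threshold_m,
                 time_threshold_min = time_threshold_min,
                 merge_radius_m = merge_radius_m,
                 min_sedentary_dwell_min = min_sedentary_dwell_min),
            class = "place_config")
}

#' Extract stay points from a fix sequence
#'
#' Classic stay-point scan: starting at each anchor fix, the run extends over
#' consecutive fixes while they remain within \code{dist_threshold_m} of the
#' anchor; a maximal run spanning at least \code{time_threshold_min} becomes
#' a stay point whose centroid is the arithmetic mean of member coordinates.
#' The scan then resumes after the emitted run, so stay points never overlap
#' in time. Deterministic.
#'
#' @param fixes data frame with \code{ts} (POSIXct), \code{lat}, \code{lon},
#'   time-ordered.
#' @param cfg a [place_config()].
#' @return data frame of stay points: \code{lat}, \code{lon},
#'   \code{start_ts}, \code{end_ts}, \code{duration_min},
#'   \code{member_fix_count}.
#' @export
detect_stay_points <- function(fixes, cfg = place_config()) {
  stopifnot(is.data.frame(fixes))
  n <- nrow(fixes)
  empty <- data.frame(lat = numeric(0), lon = numeric(0),
                      start_ts = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
                      end_ts = as.POSIXct(numeric(0), origin = "1970-01-01", tz = "UTC"),
                      duration_min = numeric(0), member_fix_count = integer(0))
  if (n < 2L) return(empty)
  if (is.unsorted(fixes$ts)) stop("fixes must be time-ordered")
  out <- list(); i <- 1L
  while (i < n) {
    d <- haversine_m(fixes$lat[i], fixes$lon[i], fixes$lat[(i + 1L):n], fixes$lon[(i + 1L):n])
    beyond <- which(d >= cfg$dist_threshold_m)
    j <- if (length(beyond) == 0L) n else i + beyond[1L] - 1L  # last fix in run
    span_min <- as.numeric(difftime(fixes$ts[j], fixes$ts[i], units = "mins"))
    if (span_min >= cfg$time_threshold_min) {
      idx <- i:j
      out[[length(out) + 1L]] <- data.frame(
        lat = mean(fixes$lat[idx]), lon = mean(fixes$lon[idx]),
        start_ts = fixes$ts[i], end_ts = fixes$ts[j],
        duration_min = span_min, member_fix_count = length(idx))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cluster stay points into personal places
#'
#' Greedy agglomerative merge in chronological order: each stay point joins
#' the first existing place whose centroid lies within \code{merge_radius_m},
#' updating that centroid to the dwell-time-weighted mean of its members;
#' otherwise it founds a new place. Places with total dwell under
#' \code{min_sedentary_dwell_min} are dropped. Place ids (\code{"P1"},
#' \code{"P2"}, ...) rank places by total dwell, ties by first occurrence.
#'
#' @param stay_points output of [detect_stay_points()].
#' @param cfg a [place_config()].
#' @return a \code{place_set}: list with \code{places} (data frame place_id,
#'   lat, lon, radius_m, total_dwell_min, n_stay_points, founded_order) and
#'   \code{stay_points} (the input with an assigned \code{place_id} column,
#'   \code{NA} for stay points of dropped places).
#' @export
cluster_places <- function(stay_points, cfg = place_config()) {
  sp <- stay_points
  cl_lat <- numeric(0); cl_lon <- numeric(0); cl_dwell <- numeric(0)
  assign <- integer(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    k <- 0L
    if (length(cl_lat) > 0L) {
      d <- haversine_m(sp$lat[i], sp$lon[i], cl_lat, cl_lon)
      hit <- which(d <= cfg$merge_radius_m)
      if (length(hit) > 0L) k <- hit[1L]
    }
    if (k == 0L) {
      cl_lat <- c(cl_lat, sp$lat[i]); cl_lon <- c(cl_lon, sp$lon[i])
      cl_dwell <- c(cl_dwell, sp$duration_min[i])
      k <- length(cl_lat)
    } else {
      w <- cl_dwell[k] + sp$duration_min[i]
      cl_lat[k] <- (cl_lat[k] * cl_dwell[k] + sp$lat[i] * sp$duration_min[i]) / w
      cl_lon[k] <- (cl_lon[k] * cl_dwell[k] + sp$lon[i] * sp$duration_min[i]) / w
      cl_dwell[k] <- w
    }
    assign[i] <- k
  }
  keep <- which(cl_dwell >= cfg$min_sedentary_dwell_min)
  # rank by total dwell desc, ties by founding order
  keep <- keep[order(-cl_dwell[keep], keep)]
  id_of <- rep(NA_character_, length(cl_lat))
  id_of[keep] <- paste0("P", seq_along(keep))

  places <- data.frame(
    place_id = id_of[keep],
    lat = cl_lat[keep], lon = cl_lon[keep],
    total_dwell_min = cl_dwell[keep],
    n_stay_points = vapply(keep, function(k) sum(assign == k), integer(1)),
    founded_order = keep,
    stringsAsFactors = FALSE)
  places$radius_m <- vapply(keep, function(k) {
    m <- assign == k
    if (!any(m)) return(0)
    max(haversine_m(cl_lat[k], cl_lon[k], sp$lat[m], sp$lon[m]))
  }, numeric(1))
  sp$place_id <- id_of[assign]
  structure(list(places = places, stay_points = sp, config = cfg),
            class = "place_set")
}

#' @export
print.place_set <- function(x, ...) {
  cat(sprintf("<place_set> %d place(s) from %d stay point(s)\n",
              nrow(x$places), nrow(x$stay_points)))
  if (nrow(x$places)) print(x$places[, c("place_id", "lat", "lon", "radius_m",
                                         "total_dwell_min")])
  invisible(x)
}

# dwell minutes of each assigned stay point inside a local-clock hour
hour_dwell_by_place <- function(place_set, hour_start, hour_end) {
  sp <- place_set$stay_points
  sp <- sp[!is.na(sp$place_id), , drop = FALSE]
  if (nrow(sp) == 0L) return(numeric(0))
  lo <- pmax(as.numeric(sp$start_ts), hour_start)
  hi <- pmin(as.numeric(sp$end_ts), hour_end)
  dw <- pmax(0, hi - lo) / 60
  tapply(dw, sp$place_id, sum)
}

#' Link sedentary hours to places
#'
#' Each sedentary hour is linked to the place where the largest share of that
#' hour's stay-point dwell occurred (ties broken toward the earlier-founded
#' place); hours with no dwell at any place stay unlinked. At most one place
#' per hour.
#'
#' @param place_set a \code{place_set} from [cluster_places()].
#' @param labeled_bins labeled bins from [label_hours()].
#' @param tz the stream's IANA timezone (bins are local-clock).
#' @return data frame \code{date}, \code{hour}, \code{place_id},
#'   \code{dwell_min} — one row per linked sedentary hour.
#' @export
link_sedentary_hours <- function(place_set, labeled_bins, tz = "UTC") {
  sed <- labeled_bins[labeled_bins$label == "sedentary", , drop = FALSE]
  founded <- place_set$places$place_id[order(place_set$places$founded_order)]
  rows <- list()
  for (i in seq_len(nrow(sed))) {
    hs <- as.numeric(as.POSIXct(sprintf("%s %02d:00:00", sed$date[i], sed$hour[i]),
                                tz = tz))
    dw <- hour_dwell_by_place(place_set, hs, hs + 3600)
    dw <- dw[dw > 0]
    if (length(dw) == 0L) next
    best <- max(dw)
    cand <- names(dw)[dw == best]
    pick <- cand[order(match(cand, founded))][1L]  # tie -> earlier-founded
    rows[[length(rows) + 1L]] <- data.frame(
      date = sed$date[i], hour = sed$hour[i], place_id = pick,
      dwell_min = unname(best), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(date = character(0), hour = integer(0),
                      place_id = character(0), dwell_min = numeric(0)))
  do.call(rbind, rows)
}

#' Export places as GeoJSON
#'
#' @param place_set a \code{place_set}.
#' @param links optional output of [link_sedentary_hours()].
#' @param path optional file path.
#' @return GeoJSON string (FeatureCollection of Point features).
#' @export
places_geojson <- function(place_set, links = NULL, path = NULL) {
  feats <- lapply(seq_len(nrow(place_set$places)), function(i) {
    p <- place_set$places[i, ]
    lh <- if (is.null(links)) list() else {
      l <- links[links$place_id == p$place_id, ]
      lapply(seq_len(nrow(l)), function(j) list(date = l$date[j], hour = l$hour[j]))
    }
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(p$lon, p$lat)),
         properties = list(place_id = p$place_id, radius_m = p$radius_m,
                           total_dwell_min = p$total_dwell_min,
                           linked_hours = lh))
  })
  js <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Location fixes of a stream as a data frame
#'
#' @param stream an \code{event_stream}.
#' @return data frame \code{ts}, \code{lat}, \code{lon}, \code{accuracy_m}.
#' @export
location_fixes <- function(stream) {
  rec <- stream$records
  f <- rec[rec$kind == "location", c("ts", "lat", "lon", "accuracy_m")]
  rownames(f) <- NULL
  f
}
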