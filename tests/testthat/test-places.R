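test_that("haversine matches the closed form and an independent implementation", {
  expect_equal(haversine_m(47.1, 9.2, 47.1, 9.2), 0)
  # one degree of equatorial arc on a 6371 km sphere
  expect_equal(haversine_m(0, 0, 0, 1), 6371000 * pi / 180, tolerance = 1e-10)

  set.seed(7)
  lat1 <- runif(25, -80, 80); lon1 <- runif(25, -179, 179)
  lat2 <- lat1 + rnorm(25, 0, 0.5); lon2 <- lon1 + rnorm(25, 0, 0.5)
  # symmetry
  expect_equal(haversine_m(lat1, lon1, lat2, lon2),
               haversine_m(lat2, lon2, lat1, lon1))
  # oracle: geosphere on the same sphere radius
  ora <- geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                  r = 6371000)
  expect_equal(haversine_m(lat1, lon1, lat2, lon2), ora, tolerance = 1e-9)
})

test_that("stay-point scan finds dwells and ignores continuous movement", {
  cfg <- place_config(dist_threshold_m = 50, time_threshold_min = 10)

  # 2 h at one coordinate -> one stay point of 120 min (span first..last fix)
  f <- dwell_fixes(47.68, 9.17, "2026-03-02 08:00:00", mins = 121)
  sp <- detect_stay_points(f, cfg)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$duration_min, 120)
  expect_equal(sp$member_fix_count, 121L)
  expect_equal(sp$lat, 47.68, tolerance = 1e-6)

  # two clusters 1 km apart joined by movement -> exactly 2 stay points
  f2 <- rbind(dwell_fixes(47.68, 9.17, "2026-03-02 08:00:00", 60),
              move_fixes(47.68, 9.17, 47.689, 9.17, "2026-03-02 09:00:00", 10),
              dwell_fixes(47.689, 9.17, "2026-03-02 09:10:00", 60))
  sp2 <- detect_stay_points(f2, cfg)
  expect_equal(nrow(sp2), 2L)
  # non-overlapping in time
  expect_true(all(head(sp2$end_ts, -1) <= tail(sp2$start_ts, -1)))

  # continuous 100 m/min movement -> no dwell
  f3 <- move_fixes(47.68, 9.17, 47.68 + 120 * 100 / 111320, 9.17,
                   "2026-03-02 08:00:00", 120)
  expect_equal(nrow(detect_stay_points(f3, cfg)), 0L)
})

test_that("every stay-point member fix stays within the distance threshold", {
  set.seed(11)
  cfg <- place_config()
  f <- rbind(dwell_fixes(47.68, 9.17, "2026-03-02 08:00:00", 45, jitter_m = 8),
             move_fixes(47.68, 9.17, 47.7, 9.2, "2026-03-02 08:45:00", 30),
             dwell_fixes(47.7, 9.2, "2026-03-02 09:15:00", 45, jitter_m = 8))
  sp <- detect_stay_points(f, cfg)
  for (i in seq_len(nrow(sp))) {
    member <- f$ts >= sp$start_ts[i] & f$ts <= sp$end_ts[i]
    seed_fix <- which(member)[1]
    d <- haversine_m(f$lat[seed_fix], f$lon[seed_fix],
                     f$lat[member], f$lon[member])
    expect_true(all(d < cfg$dist_threshold_m))
  }
})

test_that("greedy clustering merges, filters by dwell, and ranks by dwell", {
  cfg <- place_config()
  # five identical stay points -> one place, centroid preserved
  sp <- data.frame(lat = 47.68, lon = 9.17,
                   start_ts = utc("2026-03-02 08:00:00") + (0:4) * 7200,
                   end_ts = utc("2026-03-02 09:00:00") + (0:4) * 7200,
                   duration_min = 60, member_fix_count = 61L)
  ps <- cluster_places(sp, cfg)
  expect_equal(nrow(ps$places), 1L)
  expect_equal(ps$places$lat, 47.68)
  expect_equal(ps$places$total_dwell_min, 300)

  # a single 5-min stay point is below the dwell floor
  sp5 <- sp[1, ]; sp5$duration_min <- 5
  expect_equal(nrow(cluster_places(sp5, cfg)$places), 0L)

  # two separated clusters rank by dwell: the 10 h place is P1
  sp2 <- rbind(sp,                                   # 300 min at A
               within(sp, {lat <- 47.70; duration_min <- 150}))  # 750 min at B
  sp2$duration_min[6:10] <- 150
  ps2 <- cluster_places(sp2, cfg)
  expect_equal(nrow(ps2$places), 2L)
  expect_equal(ps2$places$place_id, c("P1", "P2"))
  expect_equal(ps2$places$lat[1], 47.70)  # larger dwell first
})

test_that("programmed places are recovered from a simulated week", {
  sim <- simulate_participant(sim_config(n_days = 7, seed = 13))
  sp <- detect_stay_points(location_fixes(sim$stream))
  ps <- cluster_places(sp)
  truth <- sim$truth$place_centroids
  # home and office carry essentially all dwell; the lunch spot is a via
  # point of the walking loop, not a stay
  expect_equal(nrow(ps$places), 2L)
  d_home <- min(haversine_m(ps$places$lat, ps$places$lon,
                            truth$lat[truth$name == "home"],
                            truth$lon[truth$name == "home"]))
  d_office <- min(haversine_m(ps$places$lat, ps$places$lon,
                              truth$lat[truth$name == "office"],
                              truth$lon[truth$name == "office"]))
  expect_lt(d_home, 50)
  expect_lt(d_office, 50)
  # home dominates dwell -> ranked first
  dd <- haversine_m(ps$places$lat[1], ps$places$lon[1],
                    truth$lat[truth$name == "home"],
                    truth$lon[truth$name == "home"])
  expect_lt(dd, 50)
})

test_that("clustering is deterministic given input order and config", {
  sim <- simulate_participant(sim_config(n_days = 3, seed = 17))
  sp <- detect_stay_points(location_fixes(sim$stream))
  p1 <- cluster_places(sp)
  p2 <- cluster_places(sp)
  expect_identical(p1$places, p2$places)
})

test_that("sedentary hours link to the majority-dwell place", {
  cfg <- place_config()
  # place A occupied 08:00-08:40, place B 08:40-09:00 on the same hour
  sp <- data.frame(
    lat = c(47.68, 47.70), lon = c(9.17, 9.17),
    start_ts = utc(c("2026-03-02 07:30:00", "2026-03-02 08:40:00")),
    end_ts = utc(c("2026-03-02 08:40:00", "2026-03-02 10:00:00")),
    duration_min = c(70, 80), member_fix_count = c(2L, 2L))
  ps <- cluster_places(sp, cfg)
  bins <- data.frame(participant_id = "p", date = "2026-03-02", hour = 7:9,
                     steps = 0L, covered_fraction = 1, label = "sedentary")
  links <- link_sedentary_hours(ps, bins, tz = "UTC")
  a_id <- ps$stay_points$place_id[1]; b_id <- ps$stay_points$place_id[2]
  expect_equal(links$place_id[links$hour == 8], a_id)  # 40 vs 20 min
  expect_equal(links$place_id[links$hour == 9], b_id)
  # an hour with no dwell stays unlinked
  expect_false(6 %in% links$hour)
  # at most one link per hour
  expect_false(any(duplicated(links[c("date", "hour")])))
})

test_that("simulated linked hours per place match programmed occupancy", {
  sim <- simulate_participant(sim_config(n_days = 3, seed = 19))
  res <- pipeline_daily_hours(sim$stream)
  ps <- cluster_places(detect_stay_points(location_fixes(sim$stream)))
  links <- link_sedentary_hours(ps, res$bins, tz = sim$stream$tz)
  # every linked hour is sedentary in the bins
  m <- merge(links, res$bins, by = c("date", "hour"))
  expect_true(all(m$label == "sedentary"))
  # office hours (09-12, 13-17 minus lunch walk) link to the office place
  occ <- sim$truth$occupancy
  office_hours <- unique(occ[occ$place == "office" & occ$minutes >= 30, c("date", "hour")])
  linked_office <- merge(office_hours, links, by = c("date", "hour"))
  # the office place is the one nearest the truth centroid
  truth <- sim$truth$place_centroids
  d <- haversine_m(ps$places$lat, ps$places$lon,
                   truth$lat[truth$name == "office"], truth$lon[truth$name == "office"])
  office_id <- ps$places$place_id[which.min(d)]
  expect_true(all(linked_office$place_id == office_id))
})
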