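test_that("parsing handles empty input, re-sorts, and validates payloads", {
  expect_equal(nrow(parse_event_log(character(0))$records), 0L)
  expect_equal(nrow(parse_event_log(c("", "  "))$records), 0L)

  lines <- c(
    log_line("2026-03-02T10:00:00.000+00:00", "heartbeat"),
    log_line("2026-03-02T08:00:00.000+00:00", "steps", step_delta = 10),
    log_line("2026-03-02T09:00:00.000+00:00", "screen", screen_state = "on"))
  s <- parse_event_log(lines)
  expect_equal(nrow(s$records), 3L)
  expect_equal(s$records$kind, c("steps", "screen", "heartbeat"))
  expect_false(is.unsorted(s$records$ts))

  bad <- log_line("2026-03-02T08:00:00.000+00:00", "steps", step_delta = -5)
  expect_error(parse_event_log(c(lines[1], bad)), "line 2.*step_delta")
  expect_error(parse_event_log(log_line("2026-03-02T08:00:00+00:00", "teleport")),
               "kind")
  expect_error(parse_event_log("{not json"), "line 1")
})

test_that("equal timestamps keep kind order then input order", {
  lines <- c(
    log_line("2026-03-02T08:00:00.000+00:00", "heartbeat"),
    log_line("2026-03-02T08:00:00.000+00:00", "steps", step_delta = 1),
    log_line("2026-03-02T08:00:00.000+00:00", "steps", step_delta = 2))
  s <- parse_event_log(lines)
  expect_equal(s$records$kind, c("steps", "steps", "heartbeat"))
  expect_equal(s$records$step_delta[1:2], c(1, 2))  # stable on input order
})

test_that("write/parse round-trips simulated streams exactly", {
  for (seed in c(1, 99)) {
    sim <- simulate_participant(sim_config(n_days = 1, seed = seed,
                                           checks_per_day = 3))
    out <- write_event_log(sim$stream)
    back <- parse_event_log(out, participant_id = sim$stream$participant_id,
                            tz = sim$stream$tz)
    expect_identical(back$records, sim$stream$records)
  }
  expect_length(write_event_log(event_stream("p")), 0L)
  one <- event_stream("p", records = data.frame(ts = utc("2026-03-02 08:00:00"),
                                                kind = "heartbeat"))
  line <- write_event_log(one)
  expect_length(line, 1L)
  expect_match(line, "\"kind\":\"heartbeat\"")
})

test_that("coverage follows interval arithmetic on constructed gaps", {
  w <- c(utc("2026-03-02 00:00:00"), utc("2026-03-03 00:00:00"))

  s <- heartbeat_stream("2026-03-02 00:00:00", "2026-03-03 00:00:01")
  expect_equal(compute_coverage(s, w)$covered_fraction, 1.0)

  # dense events except a 6 h silence -> 0.75 of the 24 h window
  dense <- c(seq(utc("2026-03-02 00:00:00"), utc("2026-03-02 09:00:00"), by = 600),
             seq(utc("2026-03-02 15:00:00"), utc("2026-03-03 00:00:00"), by = 600))
  s2 <- event_stream("p", "UTC", data.frame(ts = dense, kind = "heartbeat"))
  cov <- compute_coverage(s2, w)
  expect_equal(cov$covered_fraction, 0.75)
  expect_equal(nrow(cov$gaps), 1L)
  expect_equal(as.numeric(cov$gaps$end - cov$gaps$start, units = "hours"), 6)

  # single record at the midpoint: both 12 h flanks are gaps
  s3 <- event_stream("p", "UTC", data.frame(ts = w[1] + 43200, kind = "heartbeat"))
  expect_equal(compute_coverage(s3, w)$covered_fraction, 0.0)

  expect_error(compute_coverage(s, rev(w)), "window end")
})

test_that("coverage is monotone in max_gap and in added records", {
  w <- c(utc("2026-03-02 00:00:00"), utc("2026-03-03 00:00:00"))
  set.seed(42)
  ts <- sort(w[1] + runif(20, 0, 86400))
  s <- event_stream("p", "UTC", data.frame(ts = ts, kind = "heartbeat"))
  gaps_grid <- c(5, 15, 25, 60, 120, 1500)
  cf <- vapply(gaps_grid, function(g)
    compute_coverage(s, w, max_gap_minutes = g)$covered_fraction, numeric(1))
  expect_true(all(diff(cf) >= 0))
  expect_true(all(cf >= 0 & cf <= 1))
  expect_equal(cf[length(cf)], 1.0)  # tolerance beyond window length

  base <- compute_coverage(s, w)$covered_fraction
  for (i in 1:5) {
    added <- data.frame(ts = c(ts, w[1] + i * 9000), kind = "heartbeat")
    s_plus <- event_stream("p", "UTC", added)
    expect_gte(compute_coverage(s_plus, w)$covered_fraction, base)
  }
})

test_that("per-day coverage fractions respect the per-day windows", {
  # two full days, second day silent
  s <- heartbeat_stream("2026-03-02 00:00:00", "2026-03-03 00:00:01")
  w <- c(utc("2026-03-02 00:00:00"), utc("2026-03-04 00:00:00"))
  cov <- compute_coverage(s, w)
  expect_equal(unname(cov$per_day_fraction["2026-03-02"]), 1.0)
  expect_lt(unname(cov$per_day_fraction["2026-03-03"]), 0.02)
})
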