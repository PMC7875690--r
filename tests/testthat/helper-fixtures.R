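# Small programmatic fixtures shared across test files.

utc <- function(x) as.POSIXct(x, tz = "UTC")

# a stream of heartbeats every `period_min` minutes across [start, end)
heartbeat_stream <- function(start, end, period_min = 20, id = "p1", tz = "UTC") {
  hb <- seq(utc(start), utc(end) - 1, by = period_min * 60)
  event_stream(id, tz, data.frame(ts = hb, kind = "heartbeat"))
}

# one serialized record line
log_line <- function(ts, kind, ...) {
  jsonlite::toJSON(c(list(ts = ts, kind = kind), list(...)), auto_unbox = TRUE)
}

# fix sequence dwelling at (lat, lon) from t0 for `mins` minutes, one fix/min
dwell_fixes <- function(lat, lon, t0, mins, jitter_m = 0) {
  ts <- seq(utc(t0), by = 60, length.out = mins)
  n <- length(ts)
  data.frame(ts = ts,
             lat = lat + rnorm(n, 0, jitter_m / 111320),
             lon = lon + rnorm(n, 0, jitter_m / 111320))
}

# fixes moving from a to b over `mins` minutes
move_fixes <- function(lat1, lon1, lat2, lon2, t0, mins) {
  ts <- seq(utc(t0), by = 60, length.out = mins)
  frac <- seq(0, 1, length.out = mins)
  data.frame(ts = ts, lat = lat1 + (lat2 - lat1) * frac,
             lon = lon1 + (lon2 - lon1) * frac)
}

# independent high-resolution quadrature oracle for the JZS Bayes factor
# (Simpson's rule on a wide bracket; never calls the package integrator)
jzs_bf10_oracle <- function(t, df, n_eff, scale = sqrt(2) / 2,
                            span = 60, n_nodes = 40001) {
  d <- seq(-span, span, length.out = n_nodes)
  h <- d[2] - d[1]
  f <- suppressWarnings(dt(t, df, ncp = d * sqrt(n_eff))) * dcauchy(d, 0, scale)
  w <- rep(c(2, 4), length.out = n_nodes); w[1] <- 1; w[n_nodes] <- 1
  (sum(w * f) * h / 3) / dt(t, df)
}

# same for the correlation Bayes factor with a uniform prior on rho
pearson_bf10_oracle <- function(r, n, n_nodes = 4001) {
  lik <- function(rho) (1 - rho^2)^((n - 1) / 2) *
    integrate(function(w) (cosh(w) - rho * r)^(-(n - 1)), 0, Inf,
              rel.tol = 1e-12)$value
  rho <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n_nodes)
  h <- rho[2] - rho[1]
  f <- vapply(rho, lik, numeric(1)) * 0.5
  w <- rep(c(2, 4), length.out = n_nodes); w[1] <- 1; w[n_nodes] <- 1
  (sum(w * f) * h / 3) / lik(0)
}
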