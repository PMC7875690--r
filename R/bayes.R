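## Default Bayesian t tests, Bayesian Pearson correlation, and the
## small-sample nonparametric tests.
##
## The Bayes factor for a t design contrasts H0: delta = 0 against
## H1: delta ~ Cauchy(0, scale) on the standardized effect size (the JZS
## setup). BF10 = integral of f(t | delta) over the prior, divided by
## f(t | 0), where f is the noncentral t density with noncentrality
## delta * sqrt(n_eff). All integration is deterministic adaptive quadrature
## (no MCMC); posterior quantiles come from numerical CDF inversion.

#' Prior specification for Bayes factors
#'
#' @param family \code{"cauchy_on_delta"} (t designs) or
#'   \code{"stretched_beta_on_rho"} (correlations).
#' @param scale Cauchy scale (default \eqn{\sqrt{2}/2 \approx 0.707}, the
#'   conventional default of Bayesian t tests) or the stretched-beta width
#'   \eqn{\kappa} (default 1, a uniform prior on \eqn{(-1, 1)}).
#' @param truncation \code{"none"}, \code{"positive"}, or \code{"negative"} —
#'   one-sided tests renormalize the prior on the selected half-line.
#' @return a \code{prior_spec} list.
#' @export
prior_spec <- function(family = c("cauchy_on_delta", "stretched_beta_on_rho"),
                       scale = NULL,
                       truncation = c("none", "positive", "negative")) {
  family <- match.arg(family)
  truncation <- match.arg(truncation)
  if (is.null(scale)) scale <- if (family == "cauchy_on_delta") sqrt(2) / 2 else 1
  stopifnot(scale > 0)
  structure(list(family = family, scale = scale, truncation = truncation),
            class = "prior_spec")
}

bf_result <- function(orientation, value, posterior_median, ci95, prior) {
  stopifnot(value > 0)
  structure(list(orientation = orientation, value = value,
                 posterior_median = posterior_median, ci95 = ci95,
                 prior = prior),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("%s = %.3f  (posterior median %.3f, 95%% CI [%.3f, %.3f])\n",
              sub("_", "", x$orientation), x$value,
              x$posterior_median, x$ci95[1], x$ci95[2]))
  invisible(x)
}

## t statistics from printed summaries -----------------------------------------

#' t statistic from a paired-design summary
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff SD of the differences (> 0).
#' @param n number of pairs (>= 2).
#' @return list \code{t}, \code{df}, \code{n_eff}.
#' @export
t_from_paired_summary <- function(mean_diff, sd_diff, n) {
  stopifnot(n >= 2)
  if (!isTRUE(sd_diff > 0)) stop("sd_diff must be > 0")
  list(t = mean_diff / (sd_diff / sqrt(n)), df = n - 1L, n_eff = n)
}

#' t statistic from a two-sample summary (pooled variance)
#'
#' @param m1,s1,n1 mean, SD, size of sample 1.
#' @param m2,s2,n2 mean, SD, size of sample 2.
#' @return list \code{t}, \code{df}, \code{n_eff} (= n1 n2 / (n1 + n2)).
#' @export
t_from_two_sample_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (!isTRUE(sp2 > 0)) stop("degenerate: pooled SD is 0")
  list(t = (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2)),
       df = n1 + n2 - 2L, n_eff = n1 * n2 / (n1 + n2))
}

## JZS Bayes factor -----------------------------------------------------------

# marginal likelihood of t under delta ~ (possibly truncated) Cauchy.
# Substituting delta = scale * tan(u) absorbs the prior density into du/pi,
# so the integrand is bounded by the t density for any prior scale.
jzs_marginal <- function(t, df, n_eff, scale, lo, hi, rel_tol = 1e-10) {
  u_lo <- if (is.finite(lo)) atan(lo / scale) else -pi / 2
  u_hi <- if (is.finite(hi)) atan(hi / scale) else pi / 2
  renorm <- pi / (u_hi - u_lo)  # truncated-prior normalization
  g <- function(u) suppressWarnings(
    dt(t, df, ncp = scale * tan(u) * sqrt(n_eff))) / pi * renorm
  integrate(function(u) vapply(u, g, numeric(1)), u_lo, u_hi,
            rel.tol = rel_tol, subdivisions = 400L)$value
}

#' JZS Cauchy-prior Bayes factor for a t design
#'
#' Computes the default Bayes factor from a t statistic, with a Cauchy prior
#' on the standardized effect size, by adaptive quadrature. One-sided
#' variants truncate (and renormalize) the prior on the requested half-line;
#' the identity \code{BF_plus0 + BF_minus0 = 2 BF10} holds by construction.
#' Posterior median and central 95% interval of the effect size are obtained
#' by numerical inversion of the posterior CDF (truncated when one-sided).
#'
#' @param t observed t statistic (finite).
#' @param n sample size for a paired/one-sample design; or give \code{n1},
#'   \code{n2} for a two-sample design.
#' @param n1,n2 group sizes for a two-sample design.
#' @param orientation one of \code{"BF10"}, \code{"BF01"} (two-sided),
#'   \code{"BF_plus0"}, \code{"BF_minus0"} (one-sided).
#' @param scale Cauchy prior scale; default \eqn{\sqrt{2}/2}.
#' @return a \code{bf_result}.
#' @export
jzs_bf_t <- function(t, n = NULL, n1 = NULL, n2 = NULL,
                     orientation = c("BF10", "BF01", "BF_plus0", "BF_minus0"),
                     scale = sqrt(2) / 2) {
  orientation <- match.arg(orientation)
  if (!is.finite(t)) stop("t must be finite")
  if (!is.null(n)) {
    stopifnot(n >= 2); df <- n - 1; n_eff <- n
  } else {
    stopifnot(!is.null(n1), !is.null(n2), n1 >= 2, n2 >= 2)
    df <- n1 + n2 - 2; n_eff <- n1 * n2 / (n1 + n2)
  }
  side <- switch(orientation, BF_plus0 = "positive", BF_minus0 = "negative", "none")
  lo <- if (side == "positive") 0 else -Inf
  hi <- if (side == "negative") 0 else Inf
  m1 <- jzs_marginal(t, df, n_eff, scale, lo, hi)
  m0 <- dt(t, df)
  bf10 <- m1 / m0
  value <- if (orientation == "BF01") 1 / bf10 else bf10

  q <- posterior_delta_quantiles(t, df, n_eff, scale, lo, hi,
                                 probs = c(0.025, 0.5, 0.975))
  prior <- prior_spec("cauchy_on_delta", scale,
                      switch(side, positive = "positive",
                             negative = "negative", "none"))
  bf_result(orientation, value, posterior_median = q[2],
            ci95 = c(q[1], q[3]), prior = prior)
}

# posterior CDF inversion in the same tan-substituted coordinate, where the
# integrand is bounded for any prior scale
posterior_delta_quantiles <- function(t, df, n_eff, scale, lo, hi,
                                      probs = c(0.025, 0.5, 0.975)) {
  u_lo <- if (is.finite(lo)) atan(lo / scale) else -pi / 2
  u_hi <- if (is.finite(hi)) atan(hi / scale) else pi / 2
  g <- function(u) suppressWarnings(
    dt(t, df, ncp = scale * tan(u) * sqrt(n_eff)))
  gv <- function(u) vapply(u, g, numeric(1))
  Z <- integrate(gv, u_lo, u_hi, rel.tol = 1e-10, subdivisions = 400L)$value
  cdf_u <- function(u) integrate(gv, u_lo, u, rel.tol = 1e-9,
                                 subdivisions = 400L)$value / Z
  eps <- 1e-12
  vapply(probs, function(p) {
    u <- uniroot(function(x) cdf_u(x) - p,
                 c(u_lo + eps, u_hi - eps), tol = 1e-10)$root
    scale * tan(u)
  }, numeric(1))
}

## Bayesian Pearson correlation -------------------------------------------------

# exact sampling density of r given rho (Hotelling's integral representation);
# factors free of rho cancel in the Bayes factor and are omitted
lik_r_given_rho <- function(r, rho, n) {
  (1 - rho^2)^((n - 1) / 2) *
    integrate(function(w) (cosh(w) - rho * r)^(-(n - 1)), 0, Inf,
              rel.tol = 1e-10)$value
}

#' Bayes factor for a Pearson correlation
#'
#' Contrasts H0: \eqn{\rho = 0} against a stretched-beta prior on \eqn{\rho}
#' (width \eqn{\kappa}; \eqn{\kappa = 1} is uniform on \eqn{(-1, 1)}, the
#' conventional default). The marginal likelihood integrates the exact
#' sampling density of the observed correlation coefficient over the prior;
#' one-sided variants truncate and renormalize, so
#' \code{BF_minus0(r) = BF_plus0(-r)}.
#'
#' @param r observed Pearson correlation, \code{|r| < 1}.
#' @param n sample size (>= 3).
#' @param orientation \code{"BF10"}, \code{"BF01"}, \code{"BF_plus0"}, or
#'   \code{"BF_minus0"}.
#' @param kappa stretched-beta width (default 1).
#' @return a \code{bf_result} (posterior summaries on the \eqn{\rho} scale).
#' @export
pearson_bf <- function(r, n, orientation = c("BF10", "BF01", "BF_plus0",
                                             "BF_minus0"), kappa = 1) {
  orientation <- match.arg(orientation)
  if (!(abs(r) < 1)) stop("|r| must be < 1")
  stopifnot(n >= 3)
  a <- 1 / kappa
  pri <- function(rho) dbeta((rho + 1) / 2, a, a) / 2
  side <- switch(orientation, BF_plus0 = 1, BF_minus0 = -1, 0)
  lo <- if (side > 0) 0 else -1
  hi <- if (side < 0) 0 else 1
  mass <- integrate(pri, lo, hi, rel.tol = 1e-10)$value
  f <- function(rho) lik_r_given_rho(r, rho, n) * pri(rho) / mass
  fv <- function(rho) vapply(rho, f, numeric(1))
  m1 <- integrate(fv, lo, hi, rel.tol = 1e-8, subdivisions = 400L)$value
  bf10 <- m1 / lik_r_given_rho(r, 0, n)
  value <- if (orientation == "BF01") 1 / bf10 else bf10

  Z <- m1
  cdf <- function(x) integrate(fv, lo, x, rel.tol = 1e-8,
                               subdivisions = 400L)$value / Z
  q <- vapply(c(0.025, 0.5, 0.975), function(p)
    uniroot(function(x) cdf(x) - p, c(lo + 1e-12, hi - 1e-12), tol = 1e-9)$root,
    numeric(1))
  prior <- prior_spec("stretched_beta_on_rho", kappa,
                      switch(orientation, BF_plus0 = "positive",
                             BF_minus0 = "negative", "none"))
  bf_result(orientation, value, posterior_median = q[2], ci95 = c(q[1], q[3]),
            prior = prior)
}

## Nonparametric tests ----------------------------------------------------------

test_result <- function(statistic_name, statistic, p_value, ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(statistic_name = statistic_name, statistic = statistic,
                   p_value = p_value), list(...)),
            class = "np_test_result")
}

#' @export
print.np_test_result <- function(x, ...) {
  cat(sprintf("%s = %.3f, p = %.4f\n", x$statistic_name, x$statistic, x$p_value))
  invisible(x)
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Reports the normalized statistic Z = (U1 - n1 n2 / 2) / sigma with the
#' tie-corrected variance, and the two-sided normal p value. U1 counts the
#' wins of \code{x} over \code{y}.
#'
#' @param x,y numeric samples (each >= 2 observations).
#' @return an \code{np_test_result} with \code{statistic_name = "Z"} and the
#'   raw \code{U} as an extra field.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  z <- if (sigma2 > 0) (U1 - n1 * n2 / 2) / sqrt(sigma2) else 0
  test_result("Z", z, p_value = 2 * pnorm(-abs(z)), U = U1)
}

#' Wilcoxon signed-rank test (normal approximation, tie-corrected)
#'
#' Zero differences are dropped. Alongside Z, the centered S statistic — the
#' sum of positive ranks minus its null expectation n(n+1)/4 — is reported,
#' the scale some statistical packages print for small samples.
#'
#' @param diffs numeric vector of paired differences.
#' @return an \code{np_test_result} with \code{statistic_name = "Z"} and
#'   extra field \code{S}.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  stopifnot(length(diffs) >= 2)
  d <- diffs[diffs != 0]
  if (length(d) == 0L) stop("all differences are zero")
  n <- length(d)
  rk <- rank(abs(d))
  wplus <- sum(rk[d > 0])
  S <- wplus - n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) S / sqrt(sigma2) else 0
  test_result("Z", z, p_value = 2 * pnorm(-abs(z)), S = S)
}

#' Spearman rank-order correlation (normal approximation)
#'
#' rho is the Pearson correlation of the (midrank) ranks; the p value uses
#' the large-sample normal deviate \eqn{Z = \rho \sqrt{n - 1}}.
#'
#' @param x,y paired numeric vectors (>= 3 pairs).
#' @return an \code{np_test_result} with \code{statistic_name = "rho"} and
#'   extra field \code{Z}.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rho <- stats::cor(rank(x), rank(y))
  z <- rho * sqrt(length(x) - 1)
  test_result("rho", rho, p_value = 2 * pnorm(-abs(z)), Z = z)
}
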