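## Engagement with the feedback visualizations ---------------------------------
## A "check" is one interaction record opening either visualization view
## (daily or multi-day); repeated opens in the same minute count separately.

#' Visualization-check metrics
#'
#' Counts interaction records with view \code{daily_vis} or
#' \code{multiday_vis} on the given phase dates, split by access source
#' (notification vs dashboard vs shortcut), with per-participant-day counts
#' and per-participant mean daily checks.
#'
#' @param streams a single \code{event_stream} or a list of them.
#' @param phase_dates local dates over which to count.
#' @return an \code{engagement_summary}: list with \code{per_day_checks}
#'   (data frame participant_id, date, checks), \code{source_counts},
#'   \code{source_fraction} (proportions; \code{NA} and flagged when there
#'   are no checks), \code{source_percent} (rounded to 1 decimal), and
#'   \code{mean_daily_checks} (named by participant; denominator is the
#'   number of phase dates).
#' @export
interaction_metrics <- function(streams, phase_dates) {
  if (inherits(streams, "event_stream")) streams <- list(streams)
  phase_dates <- as.character(phase_dates)
  vis_views <- c("daily_vis", "multiday_vis")
  per_day <- list(); src <- setNames(numeric(length(INTERACTION_SOURCES)),
                                     INTERACTION_SOURCES)
  mean_daily <- numeric(0)
  for (s in streams) {
    rec <- s$records
    ii <- rec$kind == "interaction" & rec$view %in% vis_views
    dates <- format(rec$ts[ii], "%Y-%m-%d", tz = s$tz)
    keep <- dates %in% phase_dates
    dates <- dates[keep]
    sources <- rec$source[ii][keep]
    for (sc in names(src)) src[sc] <- src[sc] + sum(sources == sc)
    counts <- table(factor(dates, levels = phase_dates))
    per_day[[length(per_day) + 1L]] <- data.frame(
      participant_id = s$participant_id,
      date = names(counts), checks = as.integer(counts),
      stringsAsFactors = FALSE)
    mean_daily[s$participant_id] <- length(dates) / length(phase_dates)
  }
  total <- sum(src)
  frac <- if (total > 0) src / total else setNames(rep(NA_real_, length(src)),
                                                   names(src))
  structure(list(
    per_day_checks = do.call(rbind, per_day),
    source_counts = src,
    source_fraction = frac,
    source_percent = round(100 * frac, 1),
    total_checks = total,
    no_checks = total == 0,
    mean_daily_checks = mean_daily
  ), class = "engagement_summary")
}

#' Percent split of checks by access source
#'
#' Convenience for the printed notification-vs-dashboard contrast: given raw
#' counts, returns percentages rounded to one decimal.
#'
#' @param counts named numeric vector of per-source counts.
#' @return named numeric vector of percentages (1 decimal).
#' @export
source_split_percent <- function(counts) {
  total <- sum(counts)
  if (total == 0) stop("no checks: split undefined")
  round(100 * counts / total, 1)
}

#' Association between engagement and sedentary change
#'
#' Correlates each participant's mean daily visualization checks with their
#' change in daily sedentary hours (intervention minus baseline, so negative
#' = reduction). Reports the Spearman rank correlation with its
#' normal-approximation p, the Pearson correlation, and the one-sided
#' (negative-direction) Bayesian correlation Bayes factor: under the sign
#' convention, a negative correlation means more checking went with more
#' reduction.
#'
#' @param mean_daily_checks named numeric vector (participant -> checks/day).
#' @param changes named numeric vector (participant -> hours/day change).
#' @return list \code{spearman_rho}, \code{spearman_p}, \code{pearson_r},
#'   \code{bf_neg} (a \code{bf_result}), \code{n}.
#' @export
engagement_change_assoc <- function(mean_daily_checks, changes) {
  ids <- intersect(names(mean_daily_checks), names(changes))
  if (length(ids) < 3) stop("need at least 3 paired observations")
  x <- mean_daily_checks[ids]; y <- changes[ids]
  sp <- spearman(x, y)
  r <- stats::cor(x, y)
  # at |r| = 1 the marginal likelihood diverges (evidence is unbounded);
  # report no finite Bayes factor rather than a fabricated one
  bf <- if (abs(r) < 1 - 1e-12)
    pearson_bf(r, length(ids), orientation = "BF_minus0") else NULL
  list(spearman_rho = sp$statistic, spearman_p = sp$p_value,
       pearson_r = r, bf_neg = bf, n = length(ids))
}
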