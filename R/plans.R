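## Action plans: storage, specificity coding, quantity and quality summaries ---
##
## An action plan is a when/where/how triple ("13:00, office, take a walk").
## Specificity is coded per slot on a 3-level scale: 1 vague, 2 medium
## specific, 3 highly specific. The coding rules are a lexicon shipped as
## configuration (JSON), because in the original protocol specificity was
## coded by human raters; the defaults encode the published criteria and the
## vocabulary observed in participants' plans.

#' Load a specificity-coding lexicon
#'
#' @param path JSON file; default is the lexicon shipped with the package.
#' @return nested list by slot (\code{when}, \code{where}, \code{how}) with
#'   entries \code{level1}/\code{level2}/\code{level3} (term lists, matched
#'   as whole words) and \code{level2_patterns}/\code{level3_patterns}
#'   (regular expressions).
#' @export
load_lexicon <- function(path = system.file("extdata", "specificity_lexicon.json",
                                            package = "sedkit")) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

norm_text <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

match_terms <- function(text, terms) {
  for (term in terms) {
    pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\.?-])", "\\\\\\1", term), "\\b")
    if (grepl(pat, text, perl = TRUE)) return(term)
  }
  NULL
}

match_patterns <- function(text, patterns) {
  for (pat in patterns) if (grepl(pat, text, perl = TRUE)) return(pat)
  NULL
}

code_slot <- function(text, slot_lex, clock_time_first = FALSE) {
  text <- norm_text(text)
  if (!nzchar(text)) return(list(level = 1L, rule = "empty"))
  # highly specific first (a clock time or a named place/activity dominates)
  hit <- match_patterns(text, slot_lex$level3_patterns)
  if (!is.null(hit)) return(list(level = 3L, rule = paste0("pattern:", hit)))
  hit <- match_terms(text, slot_lex$level3)
  if (!is.null(hit)) return(list(level = 3L, rule = paste0("term:", hit)))
  hit <- match_terms(text, slot_lex$level1)
  if (!is.null(hit)) return(list(level = 1L, rule = paste0("term:", hit)))
  hit <- match_terms(text, slot_lex$level2)
  if (!is.null(hit)) return(list(level = 2L, rule = paste0("term:", hit)))
  hit <- match_patterns(text, slot_lex$level2_patterns)
  if (!is.null(hit)) return(list(level = 2L, rule = paste0("pattern:", hit)))
  list(level = 2L, rule = "fallback")  # unmatched: middle level, flag for review
}

#' Code the specificity of an action plan
#'
#' Deterministic, case-insensitive coding of the when/where/how slots against
#' the lexicon: empty or vague terms are level 1; recurring or event-anchored
#' phrases and large areas level 2; clock times, named places, and named
#' activities level 3. Non-empty text matching nothing is coded 2 with
#' \code{matched_rule = "fallback"} (flagged for manual review) rather than
#' guessing an extreme.
#'
#' @param when_text,where_text,how_text the plan's slot texts (may be empty).
#' @param lexicon a lexicon from [load_lexicon()].
#' @return one-row data frame: \code{when_level}, \code{where_level},
#'   \code{how_level}, \code{when_rule}, \code{where_rule}, \code{how_rule},
#'   \code{needs_review}.
#' @export
code_specificity <- function(when_text, where_text, how_text,
                             lexicon = load_lexicon()) {
  w <- code_slot(when_text, lexicon$when)
  wh <- code_slot(where_text, lexicon$where)
  h <- code_slot(how_text, lexicon$how)
  data.frame(when_level = w$level, where_level = wh$level, how_level = h$level,
             when_rule = w$rule, where_rule = wh$rule, how_rule = h$rule,
             needs_review = any(c(w$rule, wh$rule, h$rule) == "fallback"),
             stringsAsFactors = FALSE)
}

#' Code a table of plans
#'
#' @param plans data frame with columns \code{plan_id}, \code{participant_id},
#'   \code{created_ts}, \code{when_text}, \code{where_text}, \code{how_text}.
#' @param lexicon a lexicon from [load_lexicon()].
#' @return \code{plans} with the coding columns appended.
#' @export
code_plans <- function(plans, lexicon = load_lexicon()) {
  cod <- do.call(rbind, lapply(seq_len(nrow(plans)), function(i)
    code_specificity(plans$when_text[i], plans$where_text[i], plans$how_text[i],
                     lexicon)))
  cbind(plans, cod)
}

normalize_triple <- function(when_text, where_text, how_text) {
  paste(norm_text(when_text), norm_text(where_text), norm_text(how_text),
        sep = "\x1f")
}

#' Count total and unique plans in a phase
#'
#' Participants could repeat a previous day's plan, so the unique count
#' deduplicates normalized (trimmed, casefolded, whitespace-collapsed)
#' when/where/how triples.
#'
#' @param plans plans data frame (see [code_plans()]); \code{created_ts}
#'   POSIXct or ISO strings.
#' @param phase_dates local dates defining the phase.
#' @param tz timezone for converting \code{created_ts} to local dates.
#' @return list \code{total}, \code{unique}.
#' @export
count_plans <- function(plans, phase_dates, tz = "UTC") {
  if (nrow(plans) == 0L) return(list(total = 0L, unique = 0L))
  ts <- as.POSIXct(plans$created_ts, tz = "UTC")
  dates <- format(ts, "%Y-%m-%d", tz = tz)
  sel <- plans[dates %in% as.character(phase_dates), , drop = FALSE]
  keys <- normalize_triple(sel$when_text, sel$where_text, sel$how_text)
  list(total = nrow(sel), unique = length(unique(keys)))
}

#' Average number of plans per participant-day
#'
#' @param total total number of plans (or a plans data frame, whose row count
#'   is used).
#' @param n_participants,n_days positive counts.
#' @return total / (n_participants * n_days), rounded to 2 decimals.
#' @export
plans_per_day <- function(total, n_participants, n_days) {
  if (is.data.frame(total)) total <- nrow(total)
  if (n_participants <= 0 || n_days <= 0)
    stop("n_participants and n_days must be positive")
  round(total / (n_participants * n_days), 2)
}

#' Group summaries of plan quality
#'
#' Aggregates plan-level measures to a per-participant mean first, then to a
#' group mean (SD) across participants — the two-stage structure that keeps
#' prolific planners from dominating a group. Participants with zero plans
#' are excluded with a warning.
#'
#' @param coded coded plans from [code_plans()].
#' @param ratings data frame \code{plan_id}, \code{viability},
#'   \code{instrumentality} (1-4 participant-supplied ratings).
#' @param groups data frame \code{participant_id}, \code{group}.
#' @return data frame: \code{measure}, \code{group}, \code{mean}, \code{sd},
#'   \code{n_participants}. SD over a single participant is reported as 0 and
#'   flagged via the \code{degenerate} column.
#' @export
quality_summary <- function(coded, ratings, groups) {
  m <- merge(coded, ratings, by = "plan_id", all.x = TRUE)
  m <- merge(m, groups, by = "participant_id")
  absent <- setdiff(groups$participant_id, m$participant_id)
  if (length(absent) > 0)
    warning("participants with zero plans excluded: ",
            paste(absent, collapse = ", "))
  measures <- c("viability", "instrumentality", "when_level", "where_level",
                "how_level")
  out <- list()
  for (meas in measures) {
    per <- aggregate(m[[meas]],
                     by = list(participant_id = m$participant_id, group = m$group),
                     FUN = mean, na.rm = TRUE)
    for (g in sort(unique(per$group))) {
      v <- per$x[per$group == g]
      v <- v[!is.na(v)]
      out[[length(out) + 1L]] <- data.frame(
        measure = meas, group = g, mean = mean(v),
        sd = if (length(v) > 1) sd(v) else 0,
        n_participants = length(v),
        degenerate = length(v) < 2 || sd(v) == 0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Append-only plan store
#'
#' Plans are shown chronologically and cannot be deleted; this store enforces
#' that contract.
#'
#' @param plans optional initial plans data frame.
#' @return a \code{plan_store} environment with \code{$add(plan)} and
#'   \code{$all()}; there is no remove operation.
#' @export
plan_store <- function(plans = NULL) {
  env <- new.env(parent = emptyenv())
  env$plans <- if (is.null(plans)) data.frame() else plans
  add <- function(plan) {
    env$plans <- rbind(env$plans, plan)
    invisible(NULL)
  }
  all <- function() env$plans
  structure(list(add = add, all = all), class = "plan_store")
}

#' Read a plans CSV
#'
#' Columns: plan_id, participant_id, created_ts, when_text, where_text,
#' how_text.
#'
#' @param path CSV file.
#' @return plans data frame with \code{created_ts} parsed to POSIXct (UTC).
#' @export
read_plans_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("plan_id", "participant_id", "created_ts", "when_text",
            "where_text", "how_text")
  missing <- setdiff(need, names(p))
  if (length(missing)) stop("plans CSV missing columns: ",
                            paste(missing, collapse = ", "))
  p$created_ts <- parse_ts(p$created_ts)
  p
}
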