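test_that("published coding exemplars map to their levels", {
  lex <- load_lexicon()
  code_when <- function(x) code_specificity(x, "", "", lex)$when_level
  code_where <- function(x) code_specificity("", x, "", lex)$where_level
  code_how <- function(x) code_specificity("", "", x, lex)$how_level

  # when: vague / recurring-or-anchored / clock time
  expect_equal(code_when(""), 1L)
  expect_equal(code_when("Now"), 1L)
  expect_equal(code_when("Anytime"), 1L)
  expect_equal(code_when("Today"), 1L)
  expect_equal(code_when("Every Hour"), 2L)
  expect_equal(code_when("After Lunch"), 2L)
  expect_equal(code_when("13:00"), 3L)
  expect_equal(code_when("4 AM"), 3L)

  # where: vague / large area / named place
  expect_equal(code_where(""), 1L)
  expect_equal(code_where("Out"), 1L)
  expect_equal(code_where("City"), 2L)
  expect_equal(code_where("University"), 2L)
  expect_equal(code_where("Post"), 3L)
  expect_equal(code_where("Lab"), 3L)
  expect_equal(code_where("Office"), 3L)
  expect_equal(code_where("Home"), 3L)
  expect_equal(code_where("Library"), 3L)

  # how: empty / composite outing / named activity
  expect_equal(code_how(""), 1L)
  expect_equal(code_how("Going to the park"), 2L)
  expect_equal(code_how("Walk"), 3L)
  expect_equal(code_how("Yoga"), 3L)
  expect_equal(code_how("Cycle"), 3L)
  expect_equal(code_how("Push-ups"), 3L)
  expect_equal(code_how("Stretch"), 3L)
  expect_equal(code_how("Stand up"), 3L)
})

test_that("coding is pure, case-insensitive, and flags unmatched text", {
  lex <- load_lexicon()
  a <- code_specificity("13:00", "lab", "take a walk in between experiments", lex)
  b <- code_specificity("13:00", "Lab", "Take a WALK in between experiments", lex)
  expect_equal(a[c("when_level", "where_level", "how_level")],
               b[c("when_level", "where_level", "how_level")])
  expect_equal(a$how_level, 3L)  # named activity dominates extra context

  f <- code_specificity("when the moon rises", "", "", lex)
  expect_equal(f$when_level, 2L)
  expect_equal(f$when_rule, "fallback")
  expect_true(f$needs_review)
})

test_that("plan counting dedupes normalized triples within the phase", {
  dates <- as.character(as.Date("2026-03-11") + 0:4)
  plans <- data.frame(
    plan_id = paste0("pl", 1:6),
    participant_id = "a",
    created_ts = utc(paste(c(dates, "2026-02-01"), "10:00:00")),
    when_text = c(rep("13:00", 5), "13:00"),
    where_text = c("Office", "office", " OFFICE ", "office", "office", "office"),
    how_text = rep("walk", 6), stringsAsFactors = FALSE)
  res <- count_plans(plans, phase_dates = dates)
  expect_equal(res$total, 5L)   # the out-of-phase plan is not counted
  expect_equal(res$unique, 1L)  # case/whitespace variants collapse
  expect_lte(res$unique, res$total)

  zero <- count_plans(plans[0, ], dates)
  expect_equal(zero, list(total = 0L, unique = 0L))
})

test_that("plans_per_day divides by participant-days", {
  expect_equal(plans_per_day(0, 16, 14), 0)
  expect_equal(plans_per_day(16, 16, 1), 1)
  expect_error(plans_per_day(5, 0, 14), "positive")
})

test_that("quality summary aggregates per participant before groups", {
  # participant a: 3 plans all coded 3; b: 1 plan coded 3 -> both groups A
  coded <- data.frame(
    plan_id = paste0("pl", 1:4),
    participant_id = c("a", "a", "a", "b"),
    when_level = 3L, where_level = 3L, how_level = 3L)
  ratings <- data.frame(plan_id = paste0("pl", 1:4),
                        viability = c(4, 2, 3, 3), instrumentality = 3)
  groups <- data.frame(participant_id = c("a", "b"), group = "A")
  qs <- quality_summary(coded, ratings, groups)
  how <- qs[qs$measure == "how_level" & qs$group == "A", ]
  expect_equal(how$mean, 3)
  expect_equal(how$sd, 0)
  # viability: per-participant means first (3, 3) -> group mean 3, sd 0
  via <- qs[qs$measure == "viability" & qs$group == "A", ]
  expect_equal(via$mean, 3)
  expect_equal(via$sd, 0)
  expect_equal(via$n_participants, 2L)

  # participant with zero plans excluded with warning
  groups2 <- rbind(groups, data.frame(participant_id = "c", group = "B"))
  expect_warning(quality_summary(coded, ratings, groups2), "zero plans.*c")
})

test_that("the plan store is append-only", {
  st <- plan_store()
  st$add(data.frame(plan_id = "pl1", when_text = "13:00"))
  st$add(data.frame(plan_id = "pl2", when_text = "14:00"))
  expect_equal(nrow(st$all()), 2L)
  expect_null(st$remove)
})

test_that("plans CSV round-trips through read_plans_csv", {
  p <- data.frame(plan_id = "pl1", participant_id = "a",
                  created_ts = "2026-03-11T10:00:00.000+00:00",
                  when_text = "13:00", where_text = "office", how_text = "walk")
  f <- tempfile(fileext = ".csv")
  write.csv(p, f, row.names = FALSE)
  back <- read_plans_csv(f)
  expect_equal(back$when_text, "13:00")
  expect_s3_class(back$created_ts, "POSIXct")
  unlink(f)
})
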