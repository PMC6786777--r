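test_that("GvHD type classification covers the taxonomy", {
  expect_identical(classify_type("both"), "overlap_chronic")
  expect_identical(classify_type("acute_features"), "acute")
  expect_identical(classify_type("acute_features",
                                 concurrent_chronic_diagnosis = TRUE),
                   "overlap_chronic")
  expect_identical(classify_type("chronic_features"), "classic_chronic")
  expect_identical(classify_type("undefined_other"), "undefined_other")
  # a progressive chronic onset is always overlap
  expect_identical(classify_type("chronic_features",
                                 chronic_onset = "progressive"),
                   "overlap_chronic")
  expect_error(classify_type("rash"), class = "gvhd_validation_error")
})

test_that("acute onset classification: classic/late/recurrent/persistent", {
  expect_identical(classify_acute_onset(40), "classic")
  expect_identical(classify_acute_onset(130), "late_onset")
  expect_identical(classify_acute_onset(150, first_episode = FALSE,
                                        prior_settled = TRUE), "recurrent")
  expect_identical(classify_acute_onset(40, query_day = 101,
                                        still_active = TRUE), "persistent")
  # chronic manifestations block the persistent label
  expect_identical(classify_acute_onset(40, query_day = 101,
                                        still_active = TRUE,
                                        chronic_present = TRUE), "classic")
  expect_error(classify_acute_onset(-1), class = "gvhd_validation_error")
})

test_that("day-100 convention: the label flips at exactly one day", {
  labels <- classify_acute_onset(95:105)
  expect_identical(unique(labels[1:6]), "classic")   # days 95..100
  expect_identical(unique(labels[7:11]), "late_onset") # days 101..105
  expect_identical(sum(labels[-1] != labels[-length(labels)]), 1L)
  # day-by-day simulation across the boundary for a still-active episode
  persist <- classify_acute_onset(rep(60, 11), query_day = 95:105,
                                  still_active = TRUE)
  expect_identical(unique(persist[1:6]), "classic")
  expect_identical(unique(persist[7:11]), "persistent")
})

test_that("chronic onset classification and the overlap implication", {
  expect_identical(classify_chronic_onset(FALSE), "de_novo")
  expect_identical(classify_chronic_onset(TRUE, FALSE), "quiescent")
  expect_identical(classify_chronic_onset(TRUE, TRUE), "progressive")
  onset <- classify_chronic_onset(TRUE, TRUE)
  expect_identical(classify_type("chronic_features", chronic_onset = onset),
                   "overlap_chronic")
})

test_that("activity status follows the manifestation/sequelae/treatment table", {
  expect_identical(activity_status(FALSE, on_immunosuppression = TRUE),
                   "controlled")
  expect_identical(activity_status(FALSE, TRUE, FALSE, 13, "acute"),
                   "inactive")
  expect_identical(activity_status(FALSE, FALSE, FALSE, 25, "chronic"),
                   "resolved")
  expect_identical(activity_status(TRUE, FALSE, FALSE, 30), "active")
  # manifestations dominate even on treatment
  expect_identical(activity_status(TRUE, TRUE, TRUE), "active")
  expect_identical(activity_status(FALSE, FALSE, FALSE, 5, "acute"),
                   "controlled")
  expect_error(activity_status(FALSE), class = "gvhd_validation_error")
})

test_that("off-treatment windows flip at 12 (acute) and 24 (chronic) weeks", {
  acute <- activity_status(FALSE, FALSE, FALSE, 0:30, "acute")
  expect_identical(which(acute != "controlled")[1] - 1L, 12L)
  expect_identical(sum(acute[-1] != acute[-31]), 1L)
  chronic <- activity_status(FALSE, FALSE, FALSE, 0:30, "chronic")
  expect_identical(which(chronic != "controlled")[1] - 1L, 24L)
  # configurable window
  expect_identical(activity_status(FALSE, FALSE, FALSE, 10, "acute",
                                   window_weeks = 8), "resolved")
})

test_that("a simulated trajectory passes through consistent activity labels", {
  onset <- as.Date("2024-02-01")
  end <- as.Date("2024-03-01")
  stop <- as.Date("2024-03-10")
  days <- seq(onset, stop + 7 * 14, by = "day")
  labels <- vapply(days, function(d)
    activity_status_at(d, onset, end, sequelae_present = FALSE,
                       is_stop_date = if (d >= stop) stop else NA,
                       gvhd_kind = "acute"),
    character(1))
  expect_identical(unique(labels),
                   c("active", "controlled", "resolved"))
  runs <- rle(labels)$values
  expect_identical(runs, c("active", "controlled", "resolved"))
  expect_error(activity_status_at(onset - 1, onset),
               class = "gvhd_validation_error")
})

test_that("acute steroid refractoriness fires on its three clauses", {
  doses <- data.frame(day = 0, dose_mg_kg_day = 2.5)
  # (1) early progression on >= 2 mg/kg/day
  r <- steroid_response(doses, data.frame(day = 4, label = "progression"),
                        "acute", variant = steroid_variant("refractory_4d"))
  expect_identical(r$category, "refractory")
  expect_match(r$rationale, "progression_within_4d", all = FALSE)
  # same progression below the dose threshold does not fire
  low <- steroid_response(data.frame(day = 0, dose_mg_kg_day = 1.5),
                          data.frame(day = 4, label = "progression"),
                          "acute")
  expect_false(low$category == "refractory")
  # day 5 progression misses a 4-day variant but hits the 5-day consensus
  d5 <- data.frame(day = 5, label = "progression")
  expect_false(steroid_response(doses, d5, "acute",
                                variant = steroid_variant("refractory_4d")
                                )$category == "refractory")
  expect_identical(steroid_response(doses, d5, "acute")$category,
                   "refractory")
  # (2) no improvement by day 7
  r <- steroid_response(doses, data.frame(day = c(3, 8),
                                          label = c("stable", "stable")),
                        "acute")
  expect_identical(r$category, "refractory")
  expect_match(r$rationale, "no_improvement_by_d7", all = FALSE)
  # (3) incomplete response beyond 28 days
  r <- steroid_response(doses, data.frame(day = c(5, 29),
                                          label = c("improvement",
                                                    "improvement")),
                        "acute")
  expect_identical(r$category, "refractory")
  expect_match(r$rationale, "incomplete_beyond_d28", all = FALSE)
  # CR beyond 28 days is fine
  r <- steroid_response(doses, data.frame(day = c(5, 29),
                                          label = c("improvement", "CR")),
                        "acute")
  expect_identical(r$category, "responsive")
})

test_that("acute steroid dependence: recurrence during taper, taper floor", {
  doses <- data.frame(day = c(0, 10), dose_mg_kg_day = c(2.5, 1.5))
  r <- steroid_response(doses,
                        data.frame(day = c(5, 8, 15),
                                   label = c("improvement", "CR",
                                             "progression")),
                        "acute")
  expect_identical(r$category, "dependent")
  expect_match(r$rationale, "recurrence_during_taper", all = FALSE)
  # "flare" is accepted as an input alias of progression
  r2 <- steroid_response(doses,
                         data.frame(day = c(5, 8, 15),
                                    label = c("improvement", "CR", "flare")),
                         "acute")
  expect_identical(r2$category, "dependent")
  # inability to taper below 2 mg/kg/day after >= 7 days of success
  r3 <- steroid_response(
    data.frame(day = 0, dose_mg_kg_day = 2.5),
    data.frame(day = 5, label = "improvement"),
    "acute",
    taper_attempts = data.frame(day = 12, dose = 1.8, control_lost = TRUE))
  expect_identical(r3$category, "dependent")
})

test_that("chronic steroid refractoriness: progression and stable clauses", {
  r <- steroid_response(data.frame(day = 0, dose_mg_kg_day = 1.2),
                        data.frame(day = 20, label = "progression"),
                        "chronic")
  expect_identical(r$category, "refractory")
  # progression on >= 1 mg/kg/day held for less than the window: no fire
  r2 <- steroid_response(data.frame(day = 0, dose_mg_kg_day = 1.2),
                         data.frame(day = 8, label = "progression"),
                         "chronic")
  expect_false(r2$category == "refractory")
  # stable disease on 0.6 mg/kg/day for 7 weeks: refractory only under the
  # 1-month stable window, not the 2-month one
  doses <- data.frame(day = 0, dose_mg_kg_day = 0.6)
  stab <- data.frame(day = 49, label = "stable")
  expect_false(steroid_response(doses, stab, "chronic",
                                variant = steroid_variant("chronic_2mo")
                                )$category == "refractory")
  expect_identical(steroid_response(doses, stab, "chronic",
                                    variant = steroid_variant("chronic_1mo")
                                    )$category, "refractory")
})

test_that("chronic steroid dependence needs two taper failures 8+ weeks apart", {
  doses <- data.frame(day = 0, dose_mg_kg_day = 1)
  improve <- data.frame(day = 10, label = "improvement")
  dep <- function(tapers) steroid_response(doses, improve, "chronic",
                                           taper_attempts = tapers)$category
  expect_identical(dep(data.frame(day = c(100, 163), dose = 0.2,
                                  control_lost = TRUE)), "dependent")
  # a single failed attempt is not dependence
  expect_identical(dep(data.frame(day = 100, dose = 0.2,
                                  control_lost = TRUE)), "responsive")
  # attempts too close together (< 8 weeks)
  expect_identical(dep(data.frame(day = c(100, 140), dose = 0.2,
                                  control_lost = TRUE)), "responsive")
  # failures above the 0.25 floor are not dependence
  expect_identical(dep(data.frame(day = c(100, 163), dose = 0.4,
                                  control_lost = TRUE)), "responsive")
})

test_that("steroid intolerance and evaluability", {
  r <- steroid_response(data.frame(day = 0, dose_mg_kg_day = 2),
                        data.frame(day = 5, label = "improvement"),
                        "acute", steroid_toxicity = TRUE)
  expect_identical(r$category, "intolerant")
  r <- steroid_response(NULL, NULL, "acute")
  expect_identical(r$category, "not_evaluable")
  expect_match(r$rationale, "missing steroid dose history")
})

test_that("prednisone equivalents and variant presets load from config", {
  expect_equal(prednisone_equivalent(2, "prednisone"), 2)
  expect_equal(prednisone_equivalent(2, "methylprednisolone"), 2.5)
  expect_error(prednisone_equivalent(2, "dexamethasone"),
               class = "gvhd_validation_error")
  v <- steroid_variant("refractory_28d")
  expect_identical(v$active_clauses, "late_incomplete")
  expect_identical(steroid_variant("trial_14d")$acute_late_assessment_days,
                   14L)
  expect_error(steroid_variant("nope"), class = "gvhd_validation_error")
  # overrides
  expect_identical(
    steroid_variant("consensus",
                    acute_progression_window_days = 3
                    )$acute_progression_window_days, 3)
})
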