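# Seeded synthetic-cohort generator with constructive ground-truth labels.
# Records are built label-first: each patient's dates, findings, doses and
# response series are constructed so that the classifiers provably return
# the assigned labels, which are emitted alongside the record.

#' Configuration for the synthetic cohort generator
#'
#' Label mixes must each sum to 1. Defaults are an even spread over the
#' taxonomy so every classifier branch is exercised; organ-stage
#' distributions put most mass on the low stages, as in clinic-level
#' cohorts.
#'
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param n_patients Number of patients.
#' @param acute_onset_mix,activity_mix,steroid_mix,chronic_onset_mix Named
#'   probability vectors over the respective label sets.
#' @param chronic_fraction Fraction of patients with a chronic episode.
#' @param pediatric_fraction Fraction of patients under 50 kg graded with
#'   the per-kg GI bands.
#' @param stage_probs List of per-organ acute stage distributions
#'   (`skin`/`liver` over 0-4, `upper_gi` over 0-1, `lower_gi` over 0-4).
#' @return List of class `gvhd_cohort_config`.
#' @export
cohort_config <- function(seed = 1L, n_patients = 100L,
                          acute_onset_mix = c(classic = 0.4, late_onset = 0.2,
                                              recurrent = 0.2, persistent = 0.2),
                          activity_mix = c(active = 0.25, controlled = 0.25,
                                           inactive = 0.25, resolved = 0.25),
                          steroid_mix = c(responsive = 0.4, refractory = 0.25,
                                          dependent = 0.25, intolerant = 0.1),
                          chronic_onset_mix = c(de_novo = 1 / 3,
                                                quiescent = 1 / 3,
                                                progressive = 1 / 3),
                          chronic_fraction = 0.4,
                          pediatric_fraction = 0.15,
                          stage_probs = list(
                            skin = c(0.3, 0.2, 0.2, 0.2, 0.1),
                            liver = c(0.4, 0.2, 0.2, 0.1, 0.1),
                            upper_gi = c(0.6, 0.4),
                            lower_gi = c(0.35, 0.2, 0.2, 0.15, 0.1))) {
  check_mix <- function(mix, labels, what) {
    if (!setequal(names(mix), labels) || abs(sum(mix) - 1) > 1e-8 ||
        any(mix < 0)) {
      abort(sprintf("`%s` must be a probability mix over {%s} summing to 1.",
                    what, paste(labels, collapse = ", ")),
            class = "gvhd_validation_error")
    }
  }
  check_mix(acute_onset_mix, ACUTE_ONSETS, "acute_onset_mix")
  check_mix(activity_mix, ACTIVITY_LEVELS, "activity_mix")
  check_mix(steroid_mix, c("responsive", "refractory", "dependent",
                           "intolerant"), "steroid_mix")
  check_mix(chronic_onset_mix, CHRONIC_ONSETS, "chronic_onset_mix")
  stopifnot(n_patients >= 1, chronic_fraction >= 0, chronic_fraction <= 1,
            pediatric_fraction >= 0, pediatric_fraction <= 1)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 acute_onset_mix = acute_onset_mix,
                 activity_mix = activity_mix, steroid_mix = steroid_mix,
                 chronic_onset_mix = chronic_onset_mix,
                 chronic_fraction = chronic_fraction,
                 pediatric_fraction = pediatric_fraction,
                 stage_probs = stage_probs),
            class = "gvhd_cohort_config")
}

draw_feasible <- function(mix, feasible) {
  w <- mix[intersect(names(mix), feasible)]
  if (sum(w) <= 0) {
    abort(paste("Infeasible label mix: no probability mass on any label",
                "compatible with the patient's other assigned labels",
                sprintf("(feasible: %s).", paste(feasible, collapse = ", "))),
          class = "gvhd_infeasible_mix")
  }
  sample(names(w), 1L, prob = w)
}

# Representative findings producing a target MAGIC stage vector.
stage_to_findings <- function(skin, liver, upper_gi, lower_gi,
                              pediatric = FALSE, biopsy = TRUE) {
  wt <- if (pediatric) 20 else 70
  vol_adult <- c(200, 700, 1200, 1600, 800)[lower_gi + 1]
  vol_ped <- wt * c(5, 15, 25, 35, 15)[lower_gi + 1]
  list(
    rash_bsa_pct = c(0, 10, 30, 60, 80)[skin + 1],
    bullae_desquamation_bsa_pct = if (skin == 4) 10 else 0,
    generalized_erythroderma = skin == 4,
    bilirubin_mg_dl = c(0.8, 2.5, 4, 8, 20)[liver + 1],
    anorexia_with_weight_loss = FALSE,
    nausea_days = if (upper_gi == 1) 4L else 0L,
    vomiting_episodes_per_day = 0L, vomiting_days = 0L,
    upper_gi_biopsy_positive = if (upper_gi == 1) biopsy else NA,
    stool_volume_ml_per_day = if (pediatric) vol_ped else vol_adult,
    stool_episodes_per_day = NULL,
    severe_abdominal_pain = lower_gi == 4,
    ileus = FALSE, grossly_bloody_stools = FALSE,
    is_pediatric = pediatric,
    patient_weight_kg = wt)
}

# Steroid course/response series realizing a target category.
steroid_plan <- function(category, kind) {
  if (kind == "acute") {
    switch(category,
      responsive = list(
        doses = data.frame(day = 0, dose_mg_kg_day = 2),
        responses = data.frame(day = c(5, 20), label = c("improvement", "CR")),
        tapers = NULL, toxicity = FALSE),
      refractory = list(
        doses = data.frame(day = 0, dose_mg_kg_day = 2.5),
        responses = data.frame(day = 4, label = "progression"),
        tapers = NULL, toxicity = FALSE),
      dependent = list(
        doses = data.frame(day = c(0, 10), dose_mg_kg_day = c(2.5, 1.5)),
        responses = data.frame(day = c(5, 8, 15),
                               label = c("improvement", "CR", "progression")),
        tapers = NULL, toxicity = FALSE),
      intolerant = list(
        doses = data.frame(day = 0, dose_mg_kg_day = 2),
        responses = data.frame(day = 5, label = "improvement"),
        tapers = NULL, toxicity = TRUE))
  } else {
    switch(category,
      responsive = list(
        doses = data.frame(day = 0, dose_mg_kg_day = 1),
        responses = data.frame(day = c(10, 40), label = c("improvement", "CR")),
        tapers = NULL, toxicity = FALSE),
      refractory = list(
        doses = data.frame(day = 0, dose_mg_kg_day = 1.2),
        responses = data.frame(day = 20, label = "progression"),
        tapers = NULL, toxicity = FALSE),
      dependent = list(
        doses = data.frame(day = 0, dose_mg_kg_day = 1),
        responses = data.frame(day = 10, label = "improvement"),
        tapers = data.frame(day = c(100, 160), dose = c(0.2, 0.2),
                            control_lost = c(TRUE, TRUE)),
        toxicity = FALSE),
      intolerant = list(
        doses = data.frame(day = 0, dose_mg_kg_day = 1),
        responses = data.frame(day = 10, label = "improvement"),
        tapers = NULL, toxicity = TRUE))
  }
}

#' Generate a synthetic GvHD cohort with ground-truth labels
#'
#' Each patient record is constructed so that the package's classifiers
#' provably recover the assigned labels: e.g. a quiescent-onset patient's
#' acute activity ends at least one day before the chronic onset, a
#' persistent late-acute patient stays active past day 100 with no chronic
#' manifestations, and organ findings are representative values inside the
#' assigned MAGIC stage bands. Infeasible label combinations (persistent
#' acute with chronic disease; de novo chronic with prior acute) are
#' resolved by redrawing from the renormalized feasible mix, and an error
#' is raised when the requested mix leaves no feasible label.
#'
#' @param config A [cohort_config()].
#' @return Tibble, one row per patient: `patient_id`, list-columns `record`,
#'   `steroid_doses`, `steroid_responses`, `steroid_tapers`, the patient
#'   `query_date`, and ground-truth label columns (`truth_` prefix: stages,
#'   type, acute/chronic onset, activity, steroid category, `gvhd_kind`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1, n_patients = 5))
#' cohort$truth_acute_onset
generate_cohort <- function(config) {
  stopifnot(inherits(config, "gvhd_cohort_config"))
  withr::with_seed(config$seed, {
    rows <- lapply(seq_len(config$n_patients), function(i)
      generate_patient(i, config))
  })
  bind_rows(rows)
}

generate_patient <- function(i, config) {
  hct <- as_date("2023-01-01") + sample(0:364, 1L)
  has_dli <- stats::runif(1) < 0.2
  dli <- if (has_dli) hct + sample(30:120, 1L) else NULL
  ref <- gvhd_reference_date(hct, dli)
  pediatric <- stats::runif(1) < config$pediatric_fraction

  has_chronic <- stats::runif(1) < config$chronic_fraction
  chronic_onset <- if (has_chronic) draw_feasible(config$chronic_onset_mix,
                                                  CHRONIC_ONSETS) else NA_character_
  has_acute <- !has_chronic || chronic_onset != "de_novo"
  acute_onset <- NA_character_
  if (has_acute) {
    feasible <- ACUTE_ONSETS
    if (has_chronic) feasible <- setdiff(feasible, "persistent")
    if (has_chronic && chronic_onset == "progressive") {
      feasible <- intersect(feasible, "classic")
    }
    acute_onset <- draw_feasible(config$acute_onset_mix, feasible)
  }
  activity <- draw_feasible(config$activity_mix, ACTIVITY_LEVELS)
  if (!has_chronic && identical(acute_onset, "persistent")) activity <- "active"
  steroid_kind <- if (has_chronic) "chronic" else "acute"
  steroid <- draw_feasible(config$steroid_mix,
                           c("responsive", "refractory", "dependent",
                             "intolerant"))

  stages <- c(
    skin = sample(0:4, 1L, prob = config$stage_probs$skin),
    liver = sample(0:4, 1L, prob = config$stage_probs$liver),
    upper_gi = sample(0:1, 1L, prob = config$stage_probs$upper_gi),
    lower_gi = sample(0:4, 1L, prob = config$stage_probs$lower_gi))

  episodes <- list()
  courses <- list()
  day <- function(d) as.character(ref + d)
  add_episode <- function(onset, end, class, sequelae = FALSE) {
    episodes[[length(episodes) + 1]] <<- list(
      onset_date = day(onset),
      end_of_activity_date = if (is.na(end)) NULL else day(end),
      manifestation_class = class, organs = list(),
      sequelae_present = sequelae,
      first_episode = length(episodes) == 0)
  }
  add_course <- function(start, stop) {
    courses[[length(courses) + 1]] <<- list(
      drug = "prednisone", start_date = day(start),
      stop_date = if (is.na(stop)) NULL else day(stop),
      doses = list(list(date = day(start), dose_mg_kg_day = 2)))
  }

  # index-episode activity endpoint construction (window: 12 wk acute,
  # 24 wk chronic; resolved/inactive built 1 week beyond the window)
  build_endpoint <- function(onset, kind) {
    win_wk <- if (kind == "acute") 12 else 24
    switch(activity,
      active = list(end = NA, seq = FALSE, stop = NA, q = onset + 5),
      controlled = list(end = onset + 20, seq = FALSE, stop = NA,
                        q = onset + 30),
      inactive = list(end = onset + 20, seq = TRUE, stop = onset + 25,
                      q = onset + 25 + (win_wk + 1) * 7),
      resolved = list(end = onset + 20, seq = FALSE, stop = onset + 25,
                      q = onset + 25 + (win_wk + 1) * 7))
  }

  q_day <- NA_real_
  if (has_acute && !has_chronic) {
    onset <- switch(acute_onset,
      classic = sample(10:70, 1L),
      late_onset = sample(101:200, 1L),
      recurrent = sample(110:200, 1L),
      persistent = sample(40:90, 1L))
    if (acute_onset == "recurrent") {
      add_episode(20, 60, "acute_features")
      add_course(20, 70)
    }
    if (acute_onset == "persistent") {
      add_episode(onset, NA, "acute_features")
      add_course(onset, NA)
      q_day <- sample(101:150, 1L)
    } else {
      ep <- build_endpoint(onset, "acute")
      add_episode(onset, ep$end, "acute_features", ep$seq)
      add_course(onset, ep$stop)
      q_day <- ep$q
      # a classic episode queried past day 100 must not still be active
      if (acute_onset == "classic" && activity == "active") {
        q_day <- min(q_day, 100)
      }
    }
  } else if (has_chronic) {
    if (chronic_onset == "de_novo") {
      co <- sample(120:250, 1L)
    } else if (chronic_onset == "quiescent") {
      ao <- sample(20:40, 1L)
      add_episode(ao, ao + 30, "acute_features")
      co <- ao + 30 + sample(40:120, 1L)
      acute_onset <- "classic"
    } else { # progressive: acute still active at chronic onset
      ao <- sample(20:50, 1L)
      co <- ao + 40
      add_episode(ao, co + 20, "acute_features")
      acute_onset <- "classic"
    }
    ep <- build_endpoint(co, "chronic")
    end <- ep$end
    if (chronic_onset == "progressive" && !is.na(end)) {
      end <- max(end, co + 21) # after the acute episode's end
    }
    add_episode(co, end, "chronic_features", ep$seq)
    add_course(co, ep$stop)
    q_day <- max(ep$q, co + 21 + 1)
    if (activity == "active") q_day <- ep$q
  }

  visits <- list()
  if (has_acute) {
    f <- stage_to_findings(stages[["skin"]], stages[["liver"]],
                           stages[["upper_gi"]], stages[["lower_gi"]],
                           pediatric = pediatric)
    f <- Filter(Negate(is.null), f)
    visit_day <- if (length(episodes)) {
      as.numeric(as_date(episodes[[length(episodes)]]$onset_date) - ref)
    } else 30
    acute_ep_idx <- which(vapply(episodes, function(e)
      e$manifestation_class == "acute_features", logical(1)))
    if (length(acute_ep_idx)) {
      visit_day <- as.numeric(
        as_date(episodes[[max(acute_ep_idx)]]$onset_date) - ref)
    }
    visits[[length(visits) + 1]] <- list(date = day(visit_day),
                                         type = "acute", findings = f)
  }
  if (has_chronic) {
    co_date <- episodes[[length(episodes)]]$onset_date
    visits[[length(visits) + 1]] <- list(
      date = co_date, type = "chronic",
      scores = list(skin = 1L, mouth = sample(0:2, 1L)))
  }

  plan <- steroid_plan(steroid, steroid_kind)
  record <- structure(list(
    schema_version = "1.0",
    patient_id = sprintf("SYN%04d", i),
    timeline = list(
      hct_date = as.character(hct),
      dli_dates = as.list(as.character(dli %||% character())),
      episodes = episodes,
      immunosuppression = courses),
    visits = visits,
    notes = "synthetic record (label-first construction)"),
    class = "patient_record")

  type_truth <- if (has_chronic) {
    if (chronic_onset == "progressive") "overlap_chronic" else "classic_chronic"
  } else if (has_acute) "acute" else NA_character_

  tibble(
    patient_id = record$patient_id,
    record = list(record),
    query_date = day(q_day),
    steroid_doses = list(plan$doses),
    steroid_responses = list(plan$responses),
    steroid_tapers = list(plan$tapers),
    steroid_toxicity = plan$toxicity,
    gvhd_kind = steroid_kind,
    is_pediatric = pediatric,
    truth_skin = unname(stages[["skin"]]) * has_acute,
    truth_liver = unname(stages[["liver"]]) * has_acute,
    truth_upper_gi = unname(stages[["upper_gi"]]) * has_acute,
    truth_lower_gi = unname(stages[["lower_gi"]]) * has_acute,
    truth_type = type_truth,
    truth_acute_onset = acute_onset,
    truth_chronic_onset = chronic_onset,
    truth_activity = activity,
    truth_steroid = steroid)
}

#' Re-classify a synthetic cohort and return recovered labels
#'
#' Applies the package's classifiers to each generated record (and steroid
#' series) and returns the recovered labels in `truth_`-aligned columns,
#' for direct comparison with the generator's ground truth.
#'
#' @param cohort Output of [generate_cohort()].
#' @return Tibble of recovered labels, one row per patient.
#' @export
recover_labels <- function(cohort) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- cohort$record[[i]]
    res <- assess_record(rec, systems = "magic",
                         query_date = cohort$query_date[i])
    course <- res$course
    idx <- if (nrow(course)) nrow(course) else NA_integer_
    acute_rows <- which(!is.na(course$acute_onset))
    stages <- if (nrow(res$acute)) {
      res$acute[1, c("skin_stage", "liver_stage", "upper_gi_stage",
                     "lower_gi_stage")]
    } else tibble(skin_stage = 0L, liver_stage = 0L, upper_gi_stage = 0L,
                  lower_gi_stage = 0L)
    sr <- steroid_response(cohort$steroid_doses[[i]],
                           cohort$steroid_responses[[i]],
                           gvhd_kind = cohort$gvhd_kind[i],
                           taper_attempts = cohort$steroid_tapers[[i]],
                           steroid_toxicity = cohort$steroid_toxicity[i])
    tibble(
      patient_id = cohort$patient_id[i],
      skin = stages$skin_stage, liver = stages$liver_stage,
      upper_gi = stages$upper_gi_stage, lower_gi = stages$lower_gi_stage,
      type = if (!is.na(idx)) course$type[idx] else NA_character_,
      acute_onset = if (length(acute_rows))
        course$acute_onset[max(acute_rows)] else NA_character_,
      chronic_onset = if (!is.na(idx)) course$chronic_onset[idx] else NA_character_,
      activity = if (!is.na(idx)) course$activity[idx] else NA_character_,
      steroid = sr$category)
  })
  bind_rows(rows)
}

#' All 250 acute stage tuples
#'
#' The full grid skin 0-4 x liver 0-4 x upper GI 0-1 x lower GI 0-4, each
#' tuple exactly once; the enumeration surface for grading-system
#' comparisons.
#'
#' @return Tibble with 250 rows and columns `skin_stage`, `liver_stage`,
#'   `upper_gi_stage`, `lower_gi_stage`.
#' @export
stage_grid <- function() {
  as_tibble(expand.grid(skin_stage = 0:4, liver_stage = 0:4,
                        upper_gi_stage = 0:1, lower_gi_stage = 0:4,
                        KEEP.OUT.ATTRS = FALSE))
}

#' Boundary fixtures at every printed rule threshold
#'
#' A fixed fixture set probing each printed threshold one unit either side:
#' MAGIC bullae 4.9/5.0/5.1% BSA, lower-GI 1500/1501 mL, bilirubin 255/256
#' μmol/L and 15/15.1 mg/dL, nausea 2/3 days, onset day 99/100/101, 11/12/13
#' weeks off immunosuppression (acute) and 23/24 (chronic), the chronic
#' taper floor 0.24/0.25/0.26 mg/kg/day, and the 28/29-day late acute
#' steroid assessment. Cases straddling a threshold carry different
#' expected labels.
#'
#' @return Tibble with columns `case_id`, `check`, `value`, `expected`.
#' @export
boundary_cases <- function() {
  tribble_rows <- list(
    list("skin_bullae_4.9", "magic_skin_stage4_bullae", 4.9, "3"),
    list("skin_bullae_5.0", "magic_skin_stage4_bullae", 5.0, "4"),
    list("skin_bullae_5.1", "magic_skin_stage4_bullae", 5.1, "4"),
    list("lower_gi_vol_1500", "magic_lower_gi_volume", 1500, "2"),
    list("lower_gi_vol_1501", "magic_lower_gi_volume", 1501, "3"),
    list("bili_umol_255", "liver_umol", 255, "3"),
    list("bili_umol_256", "liver_umol", 256, "4"),
    list("bili_mgdl_15.0", "liver_mgdl", 15.0, "3"),
    list("bili_mgdl_15.1", "liver_mgdl", 15.1, "4"),
    list("nausea_2d", "magic_upper_gi_nausea", 2, "0"),
    list("nausea_3d", "magic_upper_gi_nausea", 3, "1"),
    list("onset_day_99", "acute_onset_day", 99, "classic"),
    list("onset_day_100", "acute_onset_day", 100, "classic"),
    list("onset_day_101", "acute_onset_day", 101, "late_onset"),
    list("weeks_off_11_acute", "acute_weeks_off_is", 11, "controlled"),
    list("weeks_off_12_acute", "acute_weeks_off_is", 12, "resolved"),
    list("weeks_off_13_acute", "acute_weeks_off_is", 13, "resolved"),
    list("weeks_off_23_chronic", "chronic_weeks_off_is", 23, "controlled"),
    list("weeks_off_24_chronic", "chronic_weeks_off_is", 24, "resolved"),
    list("taper_dose_0.24", "chronic_taper_floor", 0.24, "dependent"),
    list("taper_dose_0.25", "chronic_taper_floor", 0.25, "dependent"),
    list("taper_dose_0.26", "chronic_taper_floor", 0.26, "responsive"),
    list("late_day_28", "acute_late_assessment", 28, "responsive"),
    list("late_day_29", "acute_late_assessment", 29, "refractory"))
  bind_rows(lapply(tribble_rows, function(r)
    tibble(case_id = r[[1]], check = r[[2]], value = r[[3]],
           expected = r[[4]])))
}
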