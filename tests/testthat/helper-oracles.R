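# Independent oracles, written straight from the printed grading tables and
# kept separate from the engine's code path: scalar top-down row lookups
# (the engine assigns grades bottom-up and vectorized).

# Overall acute grade, one system, one stage tuple, by checking the printed
# rows from the highest grade down.
oracle_acute_grade <- function(S, L, U, G, system, kps = NA) {
  if (system == "magic") {
    if (S == 4 || L == 4 || G == 4) return("IV")
    if (L %in% c(2, 3) || G %in% c(2, 3)) return("III")
    if (S == 3 || L == 1 || U == 1 || G == 1) return("II")
    if (S %in% c(1, 2)) return("I")
    return("0")
  }
  if (system == "keystone") {
    if (S == 4 || L == 4) return("IV")
    if (L %in% c(2, 3) || G %in% c(2, 3, 4)) return("III")
    if (S == 3 || L == 1 || U == 1 || G == 1) return("II")
    if (S %in% c(1, 2)) return("I")
    return("0")
  }
  if (system == "minnesota") {
    if (S == 4 || G == 4) return("IV")
    if (L %in% c(2, 3, 4) || G %in% c(2, 3)) return("III")
    if (S == 3 || L == 1 || U == 1 || G == 1) return("II")
    if (S %in% c(1, 2)) return("I")
    return("0")
  }
  if (system == "ibmtr") { # upper GI not graded
    if (S == 4 || L == 4 || G == 4) return("D")
    if (S == 3 || L == 3 || G == 3) return("C")
    if (S == 2 || L %in% c(1, 2) || G %in% c(1, 2)) return("B")
    if (S == 1) return("A")
    return("0")
  }
  if (system == "glucksberg_original") { # upper GI not staged; Karnofsky rules
    any2 <- S >= 2 || L >= 2 || G >= 2
    if (any2 && !is.na(kps) && kps < 30) return("IV")
    if (any2 && !is.na(kps) && kps < 70) return("III")
    if (S %in% c(1, 2) && (L %in% c(1, 2) || G %in% c(1, 2)) &&
        !is.na(kps) && kps < 90) return("II")
    if (S >= 1 || L >= 1 || G >= 1) return("I")
    return("0")
  }
  stop("unknown system")
}

# NIH global severity, scalar closed-form predicate over a named length-8
# score vector.
oracle_nih_severity <- function(s) {
  if (max(s) == 3 || s[["lungs"]] >= 2) return("severe")
  if (s[["lungs"]] == 1 || max(s) == 2 || sum(s == 1) >= 3) return("moderate")
  if (sum(s == 1) >= 1) return("mild")
  "none"
}

# rank on the common 0..4 scale (A-D aligned with I-IV)
oracle_grade_rank <- function(g) {
  rk <- match(g, c("0", "I", "II", "III", "IV"))
  if (is.na(rk)) rk <- match(g, c("0", "A", "B", "C", "D"))
  rk - 1L
}

# Evaluate one boundary_cases() row with the relevant classifier.
evaluate_boundary_case <- function(check, value) {
  switch(check,
    magic_skin_stage4_bullae = as.character(
      stage_skin(80, value, TRUE, "magic")),
    magic_lower_gi_volume = as.character(stage_lower_gi(value)),
    liver_umol = as.character(stage_liver(value, unit = "umol_l")),
    liver_mgdl = as.character(stage_liver(value)),
    magic_upper_gi_nausea = as.character(
      stage_upper_gi(nausea_days = value)),
    acute_onset_day = classify_acute_onset(value),
    acute_weeks_off_is = activity_status(FALSE, FALSE, FALSE, value, "acute"),
    chronic_weeks_off_is = activity_status(FALSE, FALSE, FALSE, value,
                                           "chronic"),
    chronic_taper_floor = steroid_response(
      data.frame(day = 0, dose_mg_kg_day = 1),
      data.frame(day = 10, label = "improvement"),
      gvhd_kind = "chronic",
      taper_attempts = data.frame(day = c(100, 160), dose = value,
                                  control_lost = TRUE))$category,
    acute_late_assessment = steroid_response(
      data.frame(day = 0, dose_mg_kg_day = 2),
      data.frame(day = c(5, value), label = c("improvement", "improvement")),
      gvhd_kind = "acute")$category,
    stop("unknown boundary check: ", check))
}

# Minimal valid patient record for records-io tests.
minimal_record <- function() {
  list(
    schema_version = "1.0",
    patient_id = "P001",
    timeline = list(
      hct_date = "2024-01-10",
      dli_dates = list(),
      episodes = list(list(onset_date = "2024-02-20",
                           end_of_activity_date = "2024-03-20",
                           manifestation_class = "acute_features",
                           organs = list("skin"),
                           sequelae_present = FALSE,
                           first_episode = TRUE)),
      immunosuppression = list(list(drug = "prednisone",
                                    start_date = "2024-02-21",
                                    stop_date = "2024-03-25",
                                    doses = list(list(
                                      date = "2024-02-21",
                                      dose_mg_kg_day = 2))))),
    visits = list(list(date = "2024-02-20", type = "acute",
                       findings = list(rash_bsa_pct = 30,
                                       bilirubin_mg_dl = 4))),
    notes = "")
}
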