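# Per-organ acute GvHD staging (skin, liver, upper GI, lower GI).
# All staging functions are vectorized over findings; `system` is scalar.

#' Stage acute skin GvHD
#'
#' Stages 1-3 are banded on the percent body surface area (BSA) with a
#' maculopapular rash: <25% is stage 1, 25-50% stage 2, >50% stage 3.
#' Stage 4 differs by system: MAGIC requires generalized erythroderma (>50%
#' BSA) together with bullae/ulceration/desquamation on at least 5% of the
#' BSA; the Glucksberg-family systems (Keystone, Minnesota, IBMTR, original
#' Glucksberg) require generalized erythroderma with any bullous formation.
#'
#' @param rash_bsa_pct Percent BSA with maculopapular rash, 0-100.
#' @param bullae_desquamation_bsa_pct Percent BSA with bullae, ulceration or
#'   desquamation, 0-100.
#' @param generalized_erythroderma Logical; erythroderma of >50% BSA.
#' @param system One of [acute_systems()].
#' @return Integer vector of stages 0-4.
#' @export
#' @examples
#' stage_skin(30)                       # stage 2
#' stage_skin(80, 6, TRUE, "magic")     # stage 4
#' stage_skin(80, 4, TRUE, "magic")     # stage 3: bullae below 5% BSA
stage_skin <- function(rash_bsa_pct,
                       bullae_desquamation_bsa_pct = 0,
                       generalized_erythroderma = FALSE,
                       system = "magic") {
  system <- match_system(system)
  a <- recycle_args(rash = rash_bsa_pct,
                    bullae = bullae_desquamation_bsa_pct,
                    eryth = generalized_erythroderma)
  check_range(a$rash, "rash_bsa_pct")
  check_range(a$bullae, "bullae_desquamation_bsa_pct")

  stage <- integer(length(a$rash))
  stage[a$rash > 0] <- 1L
  stage[a$rash >= 25] <- 2L
  stage[a$rash > 50 | a$eryth] <- 3L
  if (system == "magic") {
    stage[a$eryth & a$bullae >= 5] <- 4L
  } else {
    stage[a$eryth & a$bullae > 0] <- 4L
  }
  stage
}

#' Stage acute liver GvHD from total serum bilirubin
#'
#' Banded on total serum bilirubin, identically in all grading systems:
#' <2 mg/dL stage 0, 2-3 stage 1, 3.1-6 stage 2, 6.1-15 stage 3,
#' and above 15 mg/dL (255 μmol/L) stage 4. Values between bands (e.g. 3.05)
#' are assigned to the lower band below the next printed lower bound.
#' μmol/L input is converted with [convert_bilirubin()] before banding.
#'
#' @param bilirubin Total serum bilirubin.
#' @param unit `"mg_dl"` (canonical) or `"umol_l"`.
#' @param system Accepted for interface symmetry; liver bands are shared.
#' @return Integer vector of stages 0-4.
#' @export
#' @examples
#' stage_liver(4.0)                 # stage 2
#' stage_liver(300, unit = "umol_l") # stage 4
stage_liver <- function(bilirubin, unit = c("mg_dl", "umol_l"),
                        system = "magic") {
  unit <- match.arg(unit)
  match_system(system)
  check_nonneg(bilirubin, "bilirubin", allow_na = FALSE)
  x <- if (unit == "umol_l") convert_bilirubin(bilirubin, "umol_l", "mg_dl") else bilirubin
  stage <- integer(length(x))
  stage[x >= 2] <- 1L
  stage[x >= 3.1] <- 2L
  stage[x >= 6.1] <- 3L
  stage[x > 15] <- 4L
  stage
}

#' Stage acute upper-GI GvHD
#'
#' A single-threshold organ (stage 0 or 1). Symptoms qualify as persistent
#' when anorexia is accompanied by weight loss, nausea lasts at least 3
#' consecutive days, or vomiting reaches at least 2 episodes/day for at least
#' 2 days. Under MAGIC, qualifying symptoms alone give stage 1. Under the
#' Keystone/Minnesota/IBMTR systems, stage 1 additionally requires histologic
#' evidence of GvHD in the stomach or duodenum (`upper_gi_biopsy_positive`
#' must be `TRUE`; the tri-state `NA` means unknown and does not qualify).
#' The original Glucksberg system does not stage the upper GI tract.
#'
#' @param anorexia_with_weight_loss Logical.
#' @param nausea_days Consecutive days of nausea (integer >= 0).
#' @param vomiting_episodes_per_day,vomiting_days Integers >= 0.
#' @param upper_gi_biopsy_positive Logical or `NA` (unknown).
#' @param system One of [acute_systems()].
#' @return Integer vector of stages 0-1.
#' @export
#' @examples
#' stage_upper_gi(nausea_days = 4, system = "magic")    # 1
#' stage_upper_gi(nausea_days = 4, system = "keystone") # 0: biopsy unknown
stage_upper_gi <- function(anorexia_with_weight_loss = FALSE,
                           nausea_days = 0,
                           vomiting_episodes_per_day = 0,
                           vomiting_days = 0,
                           upper_gi_biopsy_positive = NA,
                           system = "magic") {
  system <- match_system(system)
  a <- recycle_args(anorexia = anorexia_with_weight_loss,
                    nausea = nausea_days,
                    vep = vomiting_episodes_per_day,
                    vd = vomiting_days,
                    biopsy = upper_gi_biopsy_positive)
  check_nonneg(a$nausea, "nausea_days", allow_na = FALSE)
  check_nonneg(a$vep, "vomiting_episodes_per_day", allow_na = FALSE)
  check_nonneg(a$vd, "vomiting_days", allow_na = FALSE)

  persistent <- a$anorexia | a$nausea >= 3 | (a$vep >= 2 & a$vd >= 2)
  stage <- switch(system,
    magic = persistent,
    glucksberg_original = rep(FALSE, length(persistent)),
    # Keystone, Minnesota and IBMTR require histology
    persistent & !is.na(a$biopsy) & a$biopsy
  )
  as.integer(stage)
}

#' Stage acute lower-GI GvHD
#'
#' MAGIC bands adults on daily stool volume (<500 / 500-999 / 1000-1500 /
#' over 1500 mL/day) or liquid stool episodes (<3 / 3-4 / 5-7 / over 7);
#' children under 50 kg are banded per kg (<10 / 10-19.9 / 20-30 / >30
#' mL/kg/day; <4 / 4-6 / 7-10 / >10 episodes/day). When both volume and
#' episode counts are supplied the stage is the maximum of the two
#' sub-stages (the table's criteria are disjunctive). MAGIC stage 4 is
#' severe abdominal pain with or without ileus, or grossly bloody stools,
#' regardless of stool volume. Keystone/Minnesota/IBMTR band volume only
#' (<500 / >500 / >1000 / >1500) with stage 4 = severe abdominal pain with
#' or without ileus; the original Glucksberg system stages 4 at >2000 mL/day.
#'
#' @param stool_volume_ml_per_day Daily stool volume in mL (may be `NA`).
#' @param stool_episodes_per_day Liquid stool episodes per day (may be `NA`).
#' @param severe_abdominal_pain,ileus,grossly_bloody_stools Logical flags.
#' @param is_pediatric Logical; per-kg bands apply when `TRUE` and weight
#'   < 50 kg.
#' @param patient_weight_kg Required for the pediatric volume path.
#' @param system One of [acute_systems()].
#' @return Integer vector of stages 0-4.
#' @export
#' @examples
#' stage_lower_gi(1200, system = "magic")                      # 2
#' stage_lower_gi(600, 8, system = "magic")                    # 3 (max rule)
#' stage_lower_gi(500, is_pediatric = TRUE, patient_weight_kg = 20) # 2
stage_lower_gi <- function(stool_volume_ml_per_day = NA_real_,
                           stool_episodes_per_day = NA_real_,
                           severe_abdominal_pain = FALSE,
                           ileus = FALSE,
                           grossly_bloody_stools = FALSE,
                           is_pediatric = FALSE,
                           patient_weight_kg = NA_real_,
                           system = "magic") {
  system <- match_system(system)
  a <- recycle_args(vol = stool_volume_ml_per_day,
                    epi = stool_episodes_per_day,
                    pain = severe_abdominal_pain,
                    ileus = ileus,
                    bloody = grossly_bloody_stools,
                    ped = is_pediatric,
                    wt = patient_weight_kg)
  check_nonneg(a$vol, "stool_volume_ml_per_day")
  check_nonneg(a$epi, "stool_episodes_per_day")
  check_nonneg(a$wt, "patient_weight_kg")

  no_input <- is.na(a$vol) & is.na(a$epi) &
    !(a$pain | a$ileus | a$bloody)
  if (any(no_input)) {
    abort(paste("Lower-GI staging needs a stool volume, an episode count,",
                "or a qualitative stage-4 flag."),
          class = "gvhd_validation_error")
  }
  pediatric <- a$ped & (!is.na(a$wt) & a$wt < 50)
  if (any(a$ped & is.na(a$wt) & !is.na(a$vol))) {
    abort("Pediatric volume staging (mL/kg) requires `patient_weight_kg`.",
          class = "gvhd_validation_error")
  }

  band <- function(x, cuts, upper_inclusive) {
    # cuts = c(b1, b2, b3): stage 0 below b1; stage 3 above b3.
    # upper_inclusive: whether b2/b3 themselves belong to the lower stage.
    s <- integer(length(x))
    s[x >= cuts[1]] <- 1L
    if (upper_inclusive) {
      s[x > cuts[2]] <- 2L
      s[x > cuts[3]] <- 3L
    } else {
      s[x >= cuts[2]] <- 2L
      s[x > cuts[3]] <- 3L
    }
    s[is.na(x)] <- NA_integer_
    s
  }

  if (system == "magic") {
    vol_sub <- integer(length(a$vol))
    vol_sub[!pediatric] <- band(a$vol[!pediatric], c(500, 1000, 1500), FALSE)
    vol_sub[pediatric] <- band(a$vol[pediatric] / a$wt[pediatric],
                               c(10, 20, 30), FALSE)
    epi_sub <- integer(length(a$epi))
    # adult episode bands <3 / 3-4 / 5-7 / >7; pediatric <4 / 4-6 / 7-10 / >10
    epi_sub[!pediatric] <- band(a$epi[!pediatric], c(3, 4, 7), TRUE)
    epi_sub[pediatric] <- band(a$epi[pediatric], c(4, 6, 10), TRUE)
    stage <- pmax(vol_sub, epi_sub, na.rm = TRUE)
    stage[a$pain | a$bloody] <- 4L
  } else {
    # volume-only systems; printed rows "<500 / >500 / >1000 / >1500"
    stage <- band(a$vol, c(500, 1000, 1500), TRUE)
    stage[is.na(stage)] <- 0L
    if (system == "glucksberg_original") {
      stage[!is.na(a$vol) & a$vol > 2000] <- 4L
    } else {
      stage[a$pain] <- 4L
    }
  }
  stage[is.na(stage)] <- 0L
  as.integer(stage)
}

#' Convert liquid stool episode counts to an approximate daily volume
#'
#' One episode of diarrhea is considered to be about 200 mL for an adult and
#' 3 mL/kg for a child under 50 kg. The conversion is exposed as a utility and
#' is never applied silently when both raw inputs are recorded.
#'
#' @param episodes_per_day Episode count.
#' @param is_pediatric Logical.
#' @param patient_weight_kg Required when `is_pediatric` and weight < 50 kg.
#' @return Estimated stool volume, mL/day.
#' @export
episodes_to_volume <- function(episodes_per_day, is_pediatric = FALSE,
                               patient_weight_kg = NA_real_) {
  a <- recycle_args(epi = episodes_per_day, ped = is_pediatric,
                    wt = patient_weight_kg)
  check_nonneg(a$epi, "episodes_per_day", allow_na = FALSE)
  ped <- a$ped & (!is.na(a$wt) & a$wt < 50)
  if (any(a$ped & is.na(a$wt))) {
    abort("Pediatric episode conversion requires `patient_weight_kg`.",
          class = "gvhd_validation_error")
  }
  ifelse(ped, a$epi * 3 * a$wt, a$epi * 200)
}

#' Stage all acute target organs for a table of visits
#'
#' Data-frame verb over per-visit findings columns (named as the staging
#' function arguments, e.g. `rash_bsa_pct`, `bilirubin_mg_dl`,
#' `nausea_days`, `stool_volume_ml_per_day`). Missing columns fall back to
#' the staging defaults (absent findings). Per-organ attribution columns
#' (`skin_attribution`, `liver_attribution`, `upper_gi_attribution`,
#' `lower_gi_attribution` with values `"gvhd"`, `"mixed"` or
#' `"non_gvhd_only"`) are carried through for [grade_acute()]; organs whose
#' manifestation is solely due to a non-GvHD cause are excluded from the
#' overall grade (mixed etiology is graded fully, with no downgrade).
#'
#' @param data A data frame of visits.
#' @param system One of [acute_systems()].
#' @return The input tibble with integer columns `skin_stage`, `liver_stage`,
#'   `upper_gi_stage`, `lower_gi_stage` appended.
#' @export
#' @examples
#' stage_acute(tibble::tibble(rash_bsa_pct = 30, bilirubin_mg_dl = 4,
#'                            stool_volume_ml_per_day = 1200))
stage_acute <- function(data, system = "magic") {
  system <- match_system(system)
  data <- as_tibble(data)
  col <- function(nm, default) {
    if (nm %in% names(data)) data[[nm]] else rep(default, nrow(data))
  }
  bili <- col("bilirubin_mg_dl", NA_real_)
  bili_umol <- col("bilirubin_umol_l", NA_real_)
  bili <- ifelse(is.na(bili) & !is.na(bili_umol),
                 convert_bilirubin(ifelse(is.na(bili_umol), 0, bili_umol),
                                   "umol_l", "mg_dl"),
                 bili)
  bili[is.na(bili)] <- 0

  data$skin_stage <- stage_skin(
    col("rash_bsa_pct", 0),
    col("bullae_desquamation_bsa_pct", 0),
    col("generalized_erythroderma", FALSE),
    system = system)
  data$liver_stage <- stage_liver(bili, unit = "mg_dl", system = system)
  data$upper_gi_stage <- stage_upper_gi(
    col("anorexia_with_weight_loss", FALSE),
    col("nausea_days", 0),
    col("vomiting_episodes_per_day", 0),
    col("vomiting_days", 0),
    col("upper_gi_biopsy_positive", NA),
    system = system)
  data$lower_gi_stage <- stage_lower_gi(
    col("stool_volume_ml_per_day", 0),
    col("stool_episodes_per_day", NA_real_),
    col("severe_abdominal_pain", FALSE),
    col("ileus", FALSE),
    col("grossly_bloody_stools", FALSE),
    col("is_pediatric", FALSE),
    col("patient_weight_kg", NA_real_),
    system = system)
  data
}
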