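# Longitudinal course classification: GvHD type, onset, activity status and
# steroid-response categories over dated timelines.

GVHD_TYPES <- c("acute", "classic_chronic", "overlap_chronic", "undefined_other")
ACUTE_ONSETS <- c("classic", "late_onset", "recurrent", "persistent")
CHRONIC_ONSETS <- c("de_novo", "quiescent", "progressive")
ACTIVITY_LEVELS <- c("active", "controlled", "inactive", "resolved")
STEROID_CATEGORIES <- c("refractory", "dependent", "intolerant",
                        "responsive", "not_evaluable")

#' Reference date anchoring day 100: transplant or last DLI
#'
#' @param hct_date Transplant date.
#' @param dli_dates Optional vector of donor lymphocyte infusion dates.
#' @return The later of the transplant and the last DLI ("whichever happened
#'   last").
#' @export
gvhd_reference_date <- function(hct_date, dli_dates = NULL) {
  d <- as_date(hct_date)
  if (length(dli_dates)) d <- max(c(d, as_date(dli_dates)))
  d
}

#' Classify GvHD type: acute, classic chronic, overlap chronic or undefined
#'
#' Episodes presenting acute features only (maculopapular rash,
#' hyperbilirubinemia, and/or the acute GI set) are acute GvHD unless a
#' chronic GvHD diagnosis is concurrently present, in which case the acute
#' manifestations make the syndrome overlap chronic GvHD. Episodes with
#' simultaneous acute and chronic features are overlap; chronic features
#' alone are classic chronic; atypical alloimmune manifestations treated as
#' GvHD without meeting NIH criteria are "undefined other". A progressive
#' chronic onset always forces overlap.
#'
#' @param manifestation_class One of `"acute_features"`, `"chronic_features"`,
#'   `"both"`, `"undefined_other"` (vectorized).
#' @param concurrent_chronic_diagnosis Logical.
#' @param chronic_onset Optional chronic onset label; `"progressive"` forces
#'   overlap.
#' @return One of `"acute"`, `"classic_chronic"`, `"overlap_chronic"`,
#'   `"undefined_other"`.
#' @export
#' @examples
#' classify_type("both")                                # "overlap_chronic"
#' classify_type("acute_features")                      # "acute"
#' classify_type("acute_features", concurrent_chronic_diagnosis = TRUE)
classify_type <- function(manifestation_class,
                          concurrent_chronic_diagnosis = FALSE,
                          chronic_onset = NULL) {
  a <- recycle_args(mc = manifestation_class,
                    cc = concurrent_chronic_diagnosis,
                    on = chronic_onset %||% NA_character_)
  ok <- c("acute_features", "chronic_features", "both", "undefined_other")
  if (!all(a$mc %in% ok)) {
    abort(sprintf("`manifestation_class` must be one of %s.",
                  paste(ok, collapse = ", ")),
          class = "gvhd_validation_error")
  }
  out <- character(length(a$mc))
  out[a$mc == "undefined_other"] <- "undefined_other"
  out[a$mc == "chronic_features"] <- "classic_chronic"
  out[a$mc == "both"] <- "overlap_chronic"
  out[a$mc == "acute_features"] <-
    ifelse(a$cc[a$mc == "acute_features"], "overlap_chronic", "acute")
  out[!is.na(a$on) & a$on == "progressive"] <- "overlap_chronic"
  out
}

#' Classify acute GvHD onset: classic, late, recurrent or persistent
#'
#' Day counts are whole days from the reference date (transplant or last
#' DLI, whichever happened last). The first acute episode within day 100 is
#' classic; a first episode beyond day 100 is late onset; a recurrence
#' beyond day 100 after a period of control, inactivity or resolution is
#' recurrent; and a classic episode whose activity continues beyond day 100
#' without chronic manifestations is persistent (strict uninterrupted
#' activity).
#'
#' @param onset_day Whole days from the reference date to episode onset
#'   (must be >= 0).
#' @param first_episode Is this the patient's first acute episode?
#' @param prior_settled Was the prior acute episode controlled, inactive or
#'   resolved before this onset?
#' @param query_day Day at which the classification is asked (defaults to
#'   the onset day).
#' @param still_active Is the episode still active at `query_day`?
#' @param chronic_present Chronic GvHD manifestations present?
#' @return One of `"classic"`, `"late_onset"`, `"recurrent"`, `"persistent"`.
#' @export
#' @examples
#' classify_acute_onset(40)                              # "classic"
#' classify_acute_onset(130)                             # "late_onset"
#' classify_acute_onset(150, first_episode = FALSE, prior_settled = TRUE)
#' classify_acute_onset(40, query_day = 101, still_active = TRUE)
classify_acute_onset <- function(onset_day, first_episode = TRUE,
                                 prior_settled = FALSE,
                                 query_day = onset_day,
                                 still_active = TRUE,
                                 chronic_present = FALSE) {
  a <- recycle_args(onset = onset_day, first = first_episode,
                    settled = prior_settled, q = query_day,
                    act = still_active, cg = chronic_present)
  if (any(a$onset < 0)) {
    abort("Episode onset precedes the transplant/DLI reference date.",
          class = "gvhd_validation_error")
  }
  out <- character(length(a$onset))
  late <- a$onset > 100
  out[late & a$first] <- "late_onset"
  out[late & !a$first & a$settled] <- "recurrent"
  # a "new" late onset while the prior episode never settled is a
  # continuation of uninterrupted activity
  out[late & !a$first & !a$settled] <- "persistent"
  out[!late] <- "classic"
  persists <- !late & a$q > 100 & a$act & !a$cg
  out[persists] <- "persistent"
  out
}

#' Classify chronic GvHD onset: de novo, quiescent or progressive
#'
#' De novo when the patient never had acute GvHD; quiescent when all acute
#' manifestations were controlled, inactive or resolved before the first
#' chronic diagnosis; progressive when chronic GvHD first presents while
#' acute symptoms are still active. A progressive onset is always a form of
#' overlap chronic GvHD (see [classify_type()]).
#'
#' @param prior_acute Did the patient have acute GvHD before the chronic
#'   diagnosis?
#' @param acute_active_at_onset Were acute symptoms still active at the
#'   chronic onset?
#' @return One of `"de_novo"`, `"quiescent"`, `"progressive"`.
#' @export
#' @examples
#' classify_chronic_onset(FALSE)        # "de_novo"
#' classify_chronic_onset(TRUE, TRUE)   # "progressive"
classify_chronic_onset <- function(prior_acute = FALSE,
                                   acute_active_at_onset = FALSE) {
  a <- recycle_args(prior = prior_acute, act = acute_active_at_onset)
  out <- rep("de_novo", length(a$prior))
  out[a$prior & !a$act] <- "quiescent"
  out[a$prior & a$act] <- "progressive"
  out
}

#' GvHD activity status: active, controlled, inactive or resolved
#'
#' GvHD is active while inflammatory or worsening manifestations are present,
#' regardless of immunosuppression. Once manifestations have disappeared it
#' is controlled while systemic immunosuppression is ongoing or has been
#' stopped for less than the window (12 weeks for acute, 24 for chronic
#' GvHD). Off immunosuppression beyond the window, it is inactive when fixed
#' sequelae (irreversible scars) persist and resolved when none remain.
#' Equality at the window boundary leaves "controlled" (the printed rule
#' reads "less than" for controlled).
#'
#' @param manifestations_present Logical (vectorized).
#' @param sequelae_present Logical.
#' @param on_immunosuppression Logical.
#' @param weeks_off_is Weeks since all systemic immunosuppression stopped
#'   (may be fractional); required when off immunosuppression and not
#'   active.
#' @param gvhd_kind `"acute"` or `"chronic"` (selects the default window).
#' @param window_weeks Override for the off-immunosuppression window.
#' @return One of `"active"`, `"controlled"`, `"inactive"`, `"resolved"`.
#' @export
#' @examples
#' activity_status(FALSE, on_immunosuppression = TRUE)            # controlled
#' activity_status(FALSE, TRUE, FALSE, 13, "acute")               # inactive
#' activity_status(FALSE, FALSE, FALSE, 25, "chronic")            # resolved
activity_status <- function(manifestations_present,
                            sequelae_present = FALSE,
                            on_immunosuppression = FALSE,
                            weeks_off_is = NA_real_,
                            gvhd_kind = c("acute", "chronic"),
                            window_weeks = NULL) {
  gvhd_kind <- match.arg(gvhd_kind)
  window <- window_weeks %||% if (gvhd_kind == "acute") 12 else 24
  a <- recycle_args(man = manifestations_present, seq = sequelae_present,
                    is = on_immunosuppression, off = weeks_off_is)
  need_off <- !a$man & !a$is & is.na(a$off)
  if (any(need_off)) {
    abort(paste("`weeks_off_is` is required when manifestations are absent",
                "and immunosuppression has stopped."),
          class = "gvhd_validation_error")
  }
  out <- rep("resolved", length(a$man))
  out[a$seq] <- "inactive"
  out[a$is | (!is.na(a$off) & a$off < window)] <- "controlled"
  out[a$man] <- "active"
  out
}

#' Activity status at a query date from episode and treatment dates
#'
#' Date-level convenience over [activity_status()]: manifestations are
#' present until the episode's end-of-activity date (an `NA` end date means
#' still active), and weeks off immunosuppression are counted from the stop
#' date of the last systemic course.
#'
#' @param query_date Date of the status query (must not precede onset).
#' @param onset_date Episode onset.
#' @param end_of_activity_date Date manifestations disappeared, or `NA`.
#' @param sequelae_present Logical.
#' @param is_stop_date Date immunosuppression stopped, or `NA` while ongoing
#'   (if a course exists).
#' @param any_is_course Was systemic immunosuppression ever given? When
#'   `FALSE`, time off treatment is counted from the end of activity
#'   (resolution without treatment).
#' @inheritParams activity_status
#' @return One of `"active"`, `"controlled"`, `"inactive"`, `"resolved"`.
#' @export
activity_status_at <- function(query_date, onset_date,
                               end_of_activity_date = NA,
                               sequelae_present = FALSE,
                               is_stop_date = NA, any_is_course = TRUE,
                               gvhd_kind = c("acute", "chronic"),
                               window_weeks = NULL) {
  q <- as_date(query_date)
  if (q < as_date(onset_date)) {
    abort("`query_date` precedes the episode onset.",
          class = "gvhd_validation_error")
  }
  manifest <- is.na(end_of_activity_date) || q < as_date(end_of_activity_date)
  on_is <- any_is_course && is.na(is_stop_date)
  anchor <- if (any_is_course) is_stop_date else end_of_activity_date
  weeks_off <- if (!is.na(anchor) && !manifest) {
    as.numeric(q - as_date(anchor)) / 7
  } else NA_real_
  activity_status(manifest, sequelae_present, on_is, weeks_off,
                  gvhd_kind = gvhd_kind, window_weeks = window_weeks)
}

# ---------------------------------------------------------------------------
# Steroid response

steroid_variant_presets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("config", "steroid_variants.yaml",
                          package = "gvhdgrade")
      cache <<- yaml::read_yaml(path)
    }
    cache
  }
})

#' Steroid-response definition variants
#'
#' The published failure criteria come in cited variants (progression within
#' 3, 4 or 5 days; failure to improve within 5 to 7 days; trial-specific
#' 14-day windows). Each variant ships as a named preset in
#' `inst/config/steroid_variants.yaml` with citation metadata; `"consensus"`
#' is the default (progression within 5 days on >= 2 mg/kg/day, no
#' improvement within 7 days, incomplete response beyond 28 days; chronic
#' progression on >= 1 mg/kg/day over 2 weeks or stable disease on
#' 0.5 mg/kg/day or more over 2 months; dependence floors 2 and 0.25).
#' The 14-day trial definition is shipped but excluded from the consensus
#' default.
#'
#' @param name Preset name; see `names(steroid_variant_presets())` in the
#'   shipped YAML (`consensus`, `refractory_3d`, `refractory_4d`,
#'   `refractory_5_7d`, `refractory_28d`, `trial_14d`, `chronic_1mo`,
#'   `chronic_2mo`).
#' @param ... Named overrides of individual parameters.
#' @return A list of class `gvhd_steroid_variant`.
#' @export
#' @examples
#' steroid_variant("refractory_4d")$acute_progression_window_days  # 4
steroid_variant <- function(name = "consensus", ...) {
  presets <- steroid_variant_presets()
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown steroid variant `%s`; shipped presets: %s.",
                  name, paste(names(presets), collapse = ", ")),
          class = "gvhd_validation_error")
  }
  v <- utils::modifyList(presets[["consensus"]], presets[[name]])
  dots <- list(...)
  if (length(dots)) v <- utils::modifyList(v, dots)
  v$name <- name
  structure(v, class = "gvhd_steroid_variant")
}

#' Prednisone-equivalent dose conversion
#'
#' Converts a systemic corticosteroid dose to prednisone equivalents using
#' the shipped conversion table (`inst/config/steroid_equivalents.yaml`).
#' The methylprednisolone factor (1.25) is an extrapolation from common
#' potency tables, marked as such in the config.
#'
#' @param dose_mg_kg_day Numeric dose.
#' @param drug Drug name present in the conversion table.
#' @return Dose in prednisone mg/kg/day equivalents.
#' @export
prednisone_equivalent <- function(dose_mg_kg_day, drug = "prednisone") {
  path <- system.file("config", "steroid_equivalents.yaml",
                      package = "gvhdgrade")
  tab <- yaml::read_yaml(path)$factors
  a <- recycle_args(dose = dose_mg_kg_day, drug = drug)
  check_nonneg(a$dose, "dose_mg_kg_day", allow_na = FALSE)
  unknown <- setdiff(unique(a$drug), names(tab))
  if (length(unknown)) {
    abort(sprintf("No prednisone-equivalence factor for: %s.",
                  paste(unknown, collapse = ", ")),
          class = "gvhd_validation_error")
  }
  unname(a$dose * unlist(tab)[a$drug])
}

# step-function dose lookup; doses: tibble(day, dose) sorted by day
dose_at <- function(doses, t) {
  idx <- findInterval(t, doses$day)
  ifelse(idx == 0, 0, doses$dose[pmax(idx, 1L)])
}

# length of the contiguous spell ending at t during which dose >= min_dose
sustained_days <- function(doses, t, min_dose) {
  if (dose_at(doses, t) < min_dose) return(0)
  bp <- doses$day[doses$day <= t]
  dv <- doses$dose[doses$day <= t]
  start <- t
  for (i in rev(seq_along(bp))) {
    if (dv[i] >= min_dose) start <- bp[i] else break
  }
  t - start
}

normalize_days <- function(x, origin = NULL) {
  if (is.numeric(x)) return(x)
  as.numeric(as_date(x) - as_date(origin %||% "1970-01-01"))
}

#' Steroid-response category for a treated GvHD episode
#'
#' Classifies the response to systemic corticosteroids as refractory,
#' dependent, intolerant, responsive, or not evaluable, under a named
#' definition variant (see [steroid_variant()]). For acute GvHD the
#' refractoriness clauses are: progression within the variant's window
#' (3-5 days) of therapy onset on at least 2 mg/kg/day prednisone
#' equivalent; failure to improve within 5-7 days; or an incomplete
#' response (anything short of CR) after more than 28 days of
#' immunosuppressive treatment including steroids. Acute dependence is the
#' inability to taper below 2 mg/kg/day after at least 7 days of initially
#' successful treatment, or recurrence of activity during the steroid
#' taper. For chronic GvHD, refractoriness is progression on
#' at least 1 mg/kg/day sustained for the variant window (1-2 weeks) or stable
#' disease on >= 0.5 mg/kg/day for 1-2 months; dependence is loss of
#' control at or below the 0.25 mg/kg/day taper floor in at least two
#' attempts separated by at least 8 weeks. Steroid intolerance is a
#' clinician-flagged unacceptable toxicity.
#'
#' @param doses Data frame with columns `day` (or `date`) and
#'   `dose_mg_kg_day`: a dated step function of the prednisone-equivalent
#'   dose.
#' @param responses Data frame with columns `day` (or `date`) and `label`
#'   in `progression`, `stable`, `improvement`, `CR` (`flare` and
#'   `recurrence` are accepted as aliases of `progression`).
#' @param gvhd_kind `"acute"` or `"chronic"`.
#' @param variant A [steroid_variant()].
#' @param taper_attempts Optional data frame with columns `day` (or
#'   `date`), `dose` (the trial dose reached) and `control_lost` (logical).
#' @param steroid_toxicity Clinician flag for unacceptable steroid toxicity.
#' @return List of class `gvhd_steroid_response`: `category`, `rationale`
#'   (fired clauses), `variant`.
#' @export
#' @examples
#' steroid_response(
#'   doses = data.frame(day = 0, dose_mg_kg_day = 2.5),
#'   responses = data.frame(day = 4, label = "progression"),
#'   gvhd_kind = "acute")$category  # "refractory"
steroid_response <- function(doses, responses = NULL,
                             gvhd_kind = c("acute", "chronic"),
                             variant = steroid_variant(),
                             taper_attempts = NULL,
                             steroid_toxicity = FALSE) {
  gvhd_kind <- match.arg(gvhd_kind)
  out <- function(category, rationale) {
    structure(list(category = category, rationale = rationale,
                   variant = variant$name, gvhd_kind = gvhd_kind),
              class = "gvhd_steroid_response")
  }
  if (is.null(doses) || !nrow(as.data.frame(doses)) ||
      all(is.na(doses$dose_mg_kg_day))) {
    return(out("not_evaluable", "missing steroid dose history"))
  }
  doses <- as_tibble(doses)
  origin <- if (!is.numeric(doses$day %||% doses$date)) {
    min(as_date(doses$date))
  } else NULL
  day_col <- function(df) normalize_days(df$day %||% df$date, origin)
  doses$day <- day_col(doses)
  doses <- arrange(doses, .data$day)
  doses$dose <- doses$dose_mg_kg_day
  started <- doses$day[doses$dose > 0]
  if (!length(started)) return(out("not_evaluable", "no non-zero steroid dose"))
  start <- min(started)

  resp <- if (!is.null(responses) && nrow(as.data.frame(responses))) {
    r <- as_tibble(responses)
    r$day <- day_col(r)
    r$label <- as.character(r$label)
    r$label[r$label %in% c("flare", "recurrence")] <- "progression"
    bad <- setdiff(r$label, c("progression", "stable", "improvement", "CR"))
    if (length(bad)) {
      abort(sprintf("Unknown response label(s): %s.",
                    paste(bad, collapse = ", ")),
            class = "gvhd_validation_error")
    }
    arrange(r, .data$day)
  } else tibble(day = numeric(), label = character())
  resp$t <- resp$day - start

  taper <- if (!is.null(taper_attempts) && nrow(as.data.frame(taper_attempts))) {
    ta <- as_tibble(taper_attempts)
    ta$day <- day_col(ta)
    ta
  } else NULL

  fired <- character()
  clauses <- variant$active_clauses

  if (gvhd_kind == "acute") {
    prog <- resp[resp$label == "progression", ]
    if ("progression" %in% clauses && nrow(prog)) {
      hit <- prog$t >= 0 & prog$t <= variant$acute_progression_window_days &
        dose_at(doses, prog$day) >= variant$acute_progression_min_dose
      if (any(hit)) {
        fired <- c(fired, sprintf(
          "acute.refractory.progression_within_%dd_on_ge%.3gmgkg",
          variant$acute_progression_window_days,
          variant$acute_progression_min_dose))
      }
    }
    if ("no_improvement" %in% clauses && nrow(resp)) {
      w <- variant$acute_improvement_window_days
      improved <- any(resp$label %in% c("improvement", "CR") & resp$t <= w)
      observed <- any(resp$t >= w)
      if (observed && !improved) {
        fired <- c(fired, sprintf("acute.refractory.no_improvement_by_d%d", w))
      }
    }
    if ("late_incomplete" %in% clauses && nrow(resp)) {
      d <- variant$acute_late_assessment_days
      hit <- resp$t > d & resp$label != "CR" & dose_at(doses, resp$day) > 0
      if (any(hit)) {
        fired <- c(fired,
                   sprintf("acute.refractory.incomplete_beyond_d%d", d))
      }
    }
    if (length(fired)) return(out("refractory", fired))

    # dependence: recurrence during taper
    succ <- resp[resp$label %in% c("improvement", "CR"), ]
    if (nrow(succ) && nrow(prog)) {
      for (i in seq_len(nrow(prog))) {
        before <- doses$dose[doses$day < prog$day[i]]
        if (any(succ$day < prog$day[i]) && length(before) &&
            dose_at(doses, prog$day[i]) < max(before)) {
          fired <- c(fired, "acute.dependent.recurrence_during_taper")
          break
        }
      }
    }
    # dependence: taper floor after >= 7 days of successful treatment
    if (!is.null(taper) && nrow(succ)) {
      hit <- taper$control_lost &
        taper$dose < variant$acute_dependence_taper_floor &
        (taper$day - start) >= variant$acute_dependence_min_success_days &
        vapply(taper$day, function(d) any(succ$day < d), logical(1))
      if (any(hit)) {
        fired <- c(fired, sprintf(
          "acute.dependent.cannot_taper_below_%.3gmgkg",
          variant$acute_dependence_taper_floor))
      }
    }
    if (length(fired)) return(out("dependent", fired))
  } else {
    prog <- resp[resp$label == "progression", ]
    if (nrow(prog)) {
      hit <- vapply(prog$day, function(d)
        sustained_days(doses, d, variant$chronic_progression_min_dose) >=
          variant$chronic_progression_window_days, logical(1))
      if (any(hit)) {
        fired <- c(fired, sprintf(
          "chronic.refractory.progression_on_ge%.3gmgkg_%dd",
          variant$chronic_progression_min_dose,
          variant$chronic_progression_window_days))
      }
    }
    stab <- resp[resp$label == "stable", ]
    if (nrow(stab)) {
      hit <- vapply(stab$day, function(d)
        sustained_days(doses, d, variant$chronic_stable_min_dose) >=
          variant$chronic_stable_window_days, logical(1))
      if (any(hit)) {
        fired <- c(fired, sprintf(
          "chronic.refractory.stable_on_ge%.3gmgkg_%dd",
          variant$chronic_stable_min_dose,
          variant$chronic_stable_window_days))
      }
    }
    if (length(fired)) return(out("refractory", fired))

    if (!is.null(taper)) {
      qual <- taper[taper$control_lost &
                      taper$dose <= variant$chronic_dependence_floor, ]
      if (nrow(qual) >= variant$chronic_dependence_min_attempts &&
          diff(range(qual$day)) >= variant$chronic_dependence_separation_days) {
        fired <- c(fired, sprintf(
          "chronic.dependent.control_lost_at_le%.3gmgkg_x%d_ge%dd_apart",
          variant$chronic_dependence_floor,
          variant$chronic_dependence_min_attempts,
          variant$chronic_dependence_separation_days))
      }
    }
    if (length(fired)) return(out("dependent", fired))
  }

  if (isTRUE(steroid_toxicity)) {
    return(out("intolerant", "clinician-flagged unacceptable steroid toxicity"))
  }
  if (any(resp$label %in% c("improvement", "CR"))) {
    return(out("responsive", "improvement or complete response recorded"))
  }
  out("not_evaluable", "no failure clause met and no improvement recorded")
}

#' @export
print.gvhd_steroid_response <- function(x, ...) {
  cat(sprintf("Steroid response (%s GvHD, variant %s): %s\n",
              x$gvhd_kind, x$variant, x$category))
  cat("  rationale:", paste(x$rationale, collapse = "; "), "\n")
  invisible(x)
}
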