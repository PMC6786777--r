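# Versioned patient-record JSON I/O, validation, assessment and reporting.
# JSON is the canonical on-disk form; CSV is a lossy flat view for cohorts.
# The normative schema ships at inst/schema/patient-record-v1.json.

RECORD_SCHEMA_VERSIONS <- "1.0"

iso_date_ok <- function(x) {
  !is.null(x) && length(x) == 1 && !is.na(suppressWarnings(
    as_date(x, format = "%Y-%m-%d")))
}

#' Validate a GvHD patient record
#'
#' Field-level validation against the shipped record schema
#' (`inst/schema/patient-record-v1.json`). Each violation names the
#' offending field and the rule it breaks.
#'
#' @param record A record list (as parsed from JSON).
#' @return A tibble with columns `field`, `rule`, `message`; zero rows when
#'   the record is valid.
#' @export
validate_patient_record <- function(record) {
  errs <- list()
  err <- function(field, rule, message) {
    errs[[length(errs) + 1]] <<- tibble(field = field, rule = rule,
                                        message = message)
  }
  if (is.null(record$schema_version) ||
      !record$schema_version %in% RECORD_SCHEMA_VERSIONS) {
    err("schema_version", "recognized_version",
        sprintf("schema_version must be one of: %s",
                paste(RECORD_SCHEMA_VERSIONS, collapse = ", ")))
  }
  if (is.null(record$patient_id) || !nzchar(record$patient_id %||% "")) {
    err("patient_id", "required", "patient_id is required")
  }
  tl <- record$timeline
  if (is.null(tl)) {
    err("timeline", "required", "timeline is required")
  } else {
    if (!iso_date_ok(tl$hct_date)) {
      err("timeline.hct_date", "required_iso_date",
          "hct_date is required and must be an ISO-8601 date")
    }
    for (d in tl$dli_dates %||% list()) {
      if (!iso_date_ok(d)) {
        err("timeline.dli_dates", "iso_date",
            sprintf("DLI date `%s` is not an ISO-8601 date", d))
      }
    }
    for (i in seq_along(tl$episodes %||% list())) {
      ep <- tl$episodes[[i]]
      fld <- sprintf("timeline.episodes[%d]", i)
      if (!iso_date_ok(ep$onset_date)) {
        err(paste0(fld, ".onset_date"), "required_iso_date",
            "episode onset_date is required and must be an ISO-8601 date")
      }
      mc <- ep$manifestation_class
      if (is.null(mc) || !mc %in% c("acute_features", "chronic_features",
                                    "both", "undefined_other")) {
        err(paste0(fld, ".manifestation_class"), "enum",
            "manifestation_class must be acute_features/chronic_features/both/undefined_other")
      }
      if (iso_date_ok(tl$hct_date) && iso_date_ok(ep$onset_date) &&
          as_date(ep$onset_date) < as_date(tl$hct_date)) {
        err(paste0(fld, ".onset_date"), "dates_ordered",
            "episode onset precedes the transplant date")
      }
    }
  }
  for (i in seq_along(record$visits %||% list())) {
    v <- record$visits[[i]]
    fld <- sprintf("visits[%d]", i)
    if (!iso_date_ok(v$date)) {
      err(paste0(fld, ".date"), "required_iso_date",
          "visit date is required and must be an ISO-8601 date")
    }
    if (is.null(v$type) || !v$type %in% c("acute", "chronic")) {
      err(paste0(fld, ".type"), "enum", "visit type must be acute or chronic")
    }
    f <- v$findings
    rng <- function(nm, lo, hi) {
      x <- f[[nm]]
      if (!is.null(x) && !is.na(x) && (x < lo || x > hi)) {
        err(paste0(fld, ".findings.", nm), "range",
            sprintf("%s must be in [%s, %s]", nm, lo, hi))
      }
    }
    if (!is.null(f)) {
      rng("rash_bsa_pct", 0, 100)
      rng("bullae_desquamation_bsa_pct", 0, 100)
      rng("karnofsky_pct", 0, 100)
      for (nm in c("bilirubin_mg_dl", "bilirubin_umol_l", "nausea_days",
                   "vomiting_episodes_per_day", "vomiting_days",
                   "stool_volume_ml_per_day", "stool_episodes_per_day")) {
        rng(nm, 0, Inf)
      }
      for (org in names(f$attribution %||% list())) {
        if (!f$attribution[[org]] %in% ATTRIBUTION_LEVELS) {
          err(paste0(fld, ".findings.attribution.", org), "enum",
              "attribution must be gvhd/mixed/non_gvhd_only")
        }
      }
    }
    for (org in names(v$scores %||% list())) {
      s <- v$scores[[org]]
      if (!org %in% nih_organs()) {
        err(paste0(fld, ".scores.", org), "known_organ",
            sprintf("unknown NIH organ `%s`", org))
      } else if (!s %in% 0:3) {
        err(paste0(fld, ".scores.", org), "range",
            "NIH organ scores must be integers in 0..3")
      }
    }
  }
  if (length(errs)) bind_rows(errs) else
    tibble(field = character(), rule = character(), message = character())
}

#' Read a GvHD patient record from JSON
#'
#' Parses, validates and normalizes a record. Bilirubin recorded in μmol/L
#' is normalized to mg/dL (via [convert_bilirubin()]) with the original
#' value preserved; unknown fields are preserved on round-trip.
#'
#' @param path Path to a JSON record file.
#' @param validate Throw on validation errors (default `TRUE`).
#' @return A list of class `patient_record`.
#' @export
read_patient_record <- function(path, validate = TRUE) {
  record <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  problems <- validate_patient_record(record)
  if (validate && nrow(problems)) {
    abort(paste0("Invalid patient record:\n", paste(
      sprintf("- %s [%s]: %s", problems$field, problems$rule,
              problems$message), collapse = "\n")),
      class = "gvhd_record_error")
  }
  for (i in seq_along(record$visits)) {
    f <- record$visits[[i]]$findings
    if (!is.null(f$bilirubin_umol_l) && is.null(f$bilirubin_mg_dl)) {
      record$visits[[i]]$findings$bilirubin_mg_dl <-
        convert_bilirubin(f$bilirubin_umol_l, "umol_l", "mg_dl")
    }
  }
  structure(record, class = "patient_record", problems = problems)
}

#' Write a GvHD patient record to JSON
#'
#' Serialization is key-order preserving, so write-read-write round trips
#' are byte-stable on valid records.
#'
#' @param record A `patient_record` (or compatible list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_record <- function(record, path) {
  json <- jsonlite::toJSON(unclass(record), auto_unbox = TRUE, null = "null",
                           pretty = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

# Findings list -> one-row tibble with staging columns, for stage_acute().
findings_to_row <- function(f) {
  g <- function(nm, default) f[[nm]] %||% default
  tibble(
    rash_bsa_pct = g("rash_bsa_pct", 0),
    bullae_desquamation_bsa_pct = g("bullae_desquamation_bsa_pct", 0),
    generalized_erythroderma = isTRUE(f$generalized_erythroderma),
    bilirubin_mg_dl = g("bilirubin_mg_dl", 0),
    anorexia_with_weight_loss = isTRUE(f$anorexia_with_weight_loss),
    nausea_days = g("nausea_days", 0),
    vomiting_episodes_per_day = g("vomiting_episodes_per_day", 0),
    vomiting_days = g("vomiting_days", 0),
    upper_gi_biopsy_positive = f$upper_gi_biopsy_positive %||% NA,
    stool_volume_ml_per_day = g("stool_volume_ml_per_day", 0),
    stool_episodes_per_day = f$stool_episodes_per_day %||% NA_real_,
    severe_abdominal_pain = isTRUE(f$severe_abdominal_pain),
    ileus = isTRUE(f$ileus),
    grossly_bloody_stools = isTRUE(f$grossly_bloody_stools),
    is_pediatric = isTRUE(f$is_pediatric),
    patient_weight_kg = f$patient_weight_kg %||% NA_real_,
    karnofsky_pct = f$karnofsky_pct %||% NA_real_,
    skin_attribution = f$attribution$skin %||% "gvhd",
    liver_attribution = f$attribution$liver %||% "gvhd",
    upper_gi_attribution = f$attribution$upper_gi %||% "gvhd",
    lower_gi_attribution = f$attribution$lower_gi %||% "gvhd")
}

#' Assess a patient record: grades, severity and course labels
#'
#' Runs the full rule engine over a record: stages and grades every acute
#' visit under the requested systems, computes the NIH global severity for
#' every chronic visit (resolving the lung-score source), and classifies
#' each episode's type, onset and activity at the latest visit date.
#'
#' @param record A `patient_record`.
#' @param systems Acute systems to grade under (default all except the
#'   original Glucksberg system, which additionally needs a Karnofsky
#'   input); `"all"` for every system.
#' @param query_date Date for activity classification (default: last visit
#'   or episode date).
#' @return List of class `gvhd_assessment` with tibbles `acute`, `chronic`
#'   and `course`.
#' @export
assess_record <- function(record,
                          systems = c("magic", "keystone", "minnesota",
                                      "ibmtr"),
                          query_date = NULL) {
  if (identical(systems, "all")) systems <- acute_systems()
  visits <- record$visits %||% list()
  tl <- record$timeline
  ref <- gvhd_reference_date(tl$hct_date, unlist(tl$dli_dates))

  acute_rows <- list()
  chronic_rows <- list()
  for (v in visits) {
    if (identical(v$type, "acute")) {
      row <- findings_to_row(v$findings %||% list())
      for (sys in systems) {
        staged <- stage_acute(row, system = sys)
        graded <- grade_acute(staged, system = sys)
        graded$date <- v$date
        acute_rows[[length(acute_rows) + 1]] <- graded
      }
    } else if (identical(v$type, "chronic")) {
      scores <- lapply(v$scores %||% list(), as.integer)
      lung_source <- NA_character_
      if (!is.null(v$lung)) {
        ls <- select_lung_score(v$lung$pft_score %||% NA_integer_,
                                v$lung$pft_date,
                                v$lung$dyspnea_score %||% NA_integer_,
                                v$date)
        scores$lungs <- ls$score
        lung_source <- ls$source
      }
      sev <- nih_global_severity(
        scores, attribution = v$attribution,
        karnofsky_pct = v$karnofsky_pct %||% NA_real_,
        undefined_other = unlist(v$undefined_other) %||% character())
      chronic_rows[[length(chronic_rows) + 1]] <- tibble(
        date = v$date, nih_severity = sev$severity,
        lung_score_source = lung_source,
        excluded_organs = paste(sev$excluded_organs, collapse = ";"),
        undefined_other = paste(sev$undefined_other, collapse = ";"),
        rule_trace = paste(sev$rule_trace, collapse = ";"))
    }
  }

  episodes <- tl$episodes %||% list()
  eps_dates <- unlist(lapply(episodes, function(e) e$onset_date))
  all_dates <- c(unlist(lapply(visits, function(v) v$date)), eps_dates)
  qd <- as_date(query_date %||% (if (length(all_dates)) max(all_dates) else ref))

  course_rows <- list()
  chronic_onsets <- which(vapply(episodes, function(e)
    e$manifestation_class %in% c("chronic_features", "both"), logical(1)))
  first_chronic_date <- if (length(chronic_onsets)) {
    as_date(episodes[[chronic_onsets[1]]]$onset_date)
  } else as_date(NA)

  for (i in seq_along(episodes)) {
    ep <- episodes[[i]]
    onset <- as_date(ep$onset_date)
    is_acute <- ep$manifestation_class %in% c("acute_features", "both")
    prior_acute_idx <- which(vapply(episodes, function(e)
      e$manifestation_class %in% c("acute_features", "both") &&
        as_date(e$onset_date) < onset, logical(1)))
    prior_settled <- length(prior_acute_idx) > 0 &&
      all(vapply(prior_acute_idx, function(j) {
        end <- episodes[[j]]$end_of_activity_date
        !is.null(end) && !is.na(end) && as_date(end) <= onset
      }, logical(1)))
    qd_ep <- max(qd, onset)
    still_active <- is.null(ep$end_of_activity_date) ||
      is.na(ep$end_of_activity_date %||% NA) ||
      qd_ep < as_date(ep$end_of_activity_date)

    chronic_onset <- NA_character_
    acute_onset <- NA_character_
    if (ep$manifestation_class %in% c("chronic_features", "both") &&
        !is.na(first_chronic_date) && onset == first_chronic_date) {
      prior_acute <- length(prior_acute_idx) > 0
      chronic_onset <- classify_chronic_onset(prior_acute,
                                              prior_acute && !prior_settled)
    }
    if (is_acute) {
      acute_onset <- classify_acute_onset(
        as.numeric(onset - ref),
        first_episode = length(prior_acute_idx) == 0,
        prior_settled = prior_settled,
        query_day = as.numeric(qd_ep - ref),
        still_active = still_active,
        chronic_present = !is.na(first_chronic_date) &&
          first_chronic_date <= qd_ep)
    }
    type <- classify_type(ep$manifestation_class,
                          concurrent_chronic_diagnosis =
                            !is.na(first_chronic_date) &&
                            first_chronic_date <= onset,
                          chronic_onset = chronic_onset)

    courses <- tl$immunosuppression %||% list()
    any_is <- length(courses) > 0
    stop_dates <- lapply(courses, function(cs) cs$stop_date %||% NA)
    on_going <- any(vapply(stop_dates, function(s) is.na(s %||% NA), logical(1)))
    last_stop <- if (any_is && !on_going) {
      max(as_date(unlist(stop_dates)))
    } else as_date(NA)
    activity <- activity_status_at(
      qd_ep, onset,
      end_of_activity_date = ep$end_of_activity_date %||% NA,
      sequelae_present = isTRUE(ep$sequelae_present),
      is_stop_date = if (on_going) NA else last_stop,
      any_is_course = any_is,
      gvhd_kind = if (is_acute) "acute" else "chronic")

    course_rows[[length(course_rows) + 1]] <- tibble(
      episode = i, onset_date = as.character(onset),
      onset_day = as.numeric(onset - ref), type = type,
      acute_onset = acute_onset, chronic_onset = chronic_onset,
      activity = activity, query_date = as.character(qd_ep))
  }

  structure(list(
    patient_id = record$patient_id,
    reference_date = ref,
    acute = if (length(acute_rows)) bind_rows(acute_rows) else tibble(),
    chronic = if (length(chronic_rows)) bind_rows(chronic_rows) else tibble(),
    course = if (length(course_rows)) bind_rows(course_rows) else tibble()),
    class = "gvhd_assessment")
}

#' Render a human- and machine-readable assessment report
#'
#' The report always carries the fired rule ids for every label, lists
#' every organ excluded for a non-GvHD cause together with the exclusion
#' reason, the lung-score source, and any "undefined other" manifestations
#' (recorded, never scored).
#'
#' @param record A `patient_record`.
#' @param results Optional precomputed [assess_record()] output.
#' @param ... Passed to [assess_record()] when `results` is `NULL`.
#' @return List of class `gvhd_report` with elements `text` (character
#'   lines) and `results`.
#' @export
render_report <- function(record, results = NULL, ...) {
  results <- results %||% assess_record(record, ...)
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("GvHD assessment report - patient %s", record$patient_id)
  add("Reference date (HCT/last DLI): %s", as.character(results$reference_date))
  if (nrow(results$acute)) {
    add("== Acute grading ==")
    for (i in seq_len(nrow(results$acute))) {
      r <- results$acute[i, ]
      add("  %s [%s]: grade %s (skin %d, liver %d, upper GI %d, lower GI %d)",
          r$date, r$system, r$grade, r$skin_stage, r$liver_stage,
          r$upper_gi_stage, r$lower_gi_stage)
      excl <- grep("^exclude\\.", strsplit(r$rule_trace, ";")[[1]], value = TRUE)
      for (e in excl) {
        add("    excluded organ (manifestation solely non-GvHD): %s", e)
      }
      add("    rules: %s", r$rule_trace)
    }
  }
  if (nrow(results$chronic)) {
    add("== NIH chronic severity ==")
    for (i in seq_len(nrow(results$chronic))) {
      r <- results$chronic[i, ]
      add("  %s: %s (lung score source: %s)", r$date, r$nih_severity,
          r$lung_score_source %||% "n/a")
      if (nzchar(r$excluded_organs)) {
        add("    excluded organs (non-GvHD cause): %s", r$excluded_organs)
      }
      if (nzchar(r$undefined_other)) {
        add("    undefined other manifestations (recorded, not scored): %s",
            r$undefined_other)
      }
      add("    rules: %s", r$rule_trace)
    }
  }
  if (nrow(results$course)) {
    add("== Course classification ==")
    for (i in seq_len(nrow(results$course))) {
      r <- results$course[i, ]
      add("  episode %d (day %g): type %s%s%s, activity at %s: %s",
          r$episode, r$onset_day, r$type,
          if (!is.na(r$acute_onset)) paste0(", acute onset ", r$acute_onset) else "",
          if (!is.na(r$chronic_onset)) paste0(", chronic onset ", r$chronic_onset) else "",
          r$query_date, r$activity)
    }
  }
  structure(list(text = ln, results = results), class = "gvhd_report")
}

#' @export
print.gvhd_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}

#' Export / import a cohort of acute visits as flat CSV
#'
#' A lossy flat view (one row per visit) that preserves all gradeable
#' fields; JSON remains the canonical record form.
#'
#' @param data Tibble of acute visit rows (findings columns).
#' @param path CSV path.
#' @return `cohort_to_csv()` returns `path` invisibly; `cohort_from_csv()`
#'   returns the tibble.
#' @export
cohort_to_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_to_csv
#' @export
cohort_from_csv <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
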