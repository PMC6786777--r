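# NIH 2014 chronic GvHD global severity, lung-score source selection,
# weight-loss window, and legacy Seattle categories.

NIH_SEVERITY_LEVELS <- c("none", "mild", "moderate", "severe")

# Vectorized severity from an n x 8 score matrix (columns nih_organs()).
nih_severity_label <- function(scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- colnames(scores) %||% nih_organs()
  if (anyNA(scores) || !all(scores %in% 0:3)) {
    abort("NIH organ scores must be integers in 0..3.",
          class = "gvhd_validation_error")
  }
  lungs <- scores[, "lungs"]
  any3 <- apply(scores == 3, 1, any)
  any2 <- apply(scores == 2, 1, any)
  n1 <- rowSums(scores == 1)
  out <- rep("none", nrow(scores))
  out[n1 >= 1] <- "mild"
  out[any2 | n1 >= 3 | lungs >= 1] <- "moderate"
  out[any3 | lungs >= 2] <- "severe"
  out
}

#' NIH 2014 global severity of chronic GvHD
#'
#' Aggregates the eight NIH organ scores (each 0-3) into a global severity:
#' severe if any organ scores 3 or the lung scores 2 or 3; moderate if the
#' lung scores 1, any organ scores 2, or three or more organs score 1; mild
#' if one or two non-lung organs score 1 and nothing scores higher; none if
#' all scores are 0. Organs whose dysfunction is unequivocally caused by an
#' alternative etiology (`attribution = "non_gvhd_only"`) are eliminated
#' from the severity score; mixed etiology is scored fully. The Karnofsky
#' score and "undefined other" manifestations are recorded but never alter
#' the global score.
#'
#' @param scores Named numeric vector or list with entries for
#'   [nih_organs()] (missing organs default to 0).
#' @param attribution Optional named character vector over the same organs
#'   with values `"gvhd"`, `"mixed"` or `"non_gvhd_only"`.
#' @param karnofsky_pct Optional; recorded only.
#' @param undefined_other Optional character vector of "undefined other"
#'   chronic GvHD manifestations; recorded only, never scored.
#' @return Object of class `gvhd_nih_severity`: list with `severity`,
#'   `scores`, `excluded_organs`, `karnofsky_pct`, `undefined_other`,
#'   `rule_trace`.
#' @export
#' @examples
#' nih_global_severity(c(mouth = 1, eyes = 1))$severity  # "mild"
#' nih_global_severity(c(lungs = 2))$severity            # "severe"
nih_global_severity <- function(scores, attribution = NULL,
                                karnofsky_pct = NA_real_,
                                undefined_other = character()) {
  full <- stats::setNames(rep(0L, 8L), nih_organs())
  scores <- unlist(scores)
  bad <- setdiff(names(scores), nih_organs())
  if (length(bad)) {
    abort(sprintf("Unknown NIH organ(s): %s.", paste(bad, collapse = ", ")),
          class = "gvhd_validation_error")
  }
  if (length(scores) && any(!scores %in% 0:3)) {
    abort("NIH organ scores must be integers in 0..3.",
          class = "gvhd_validation_error")
  }
  full[names(scores)] <- as.integer(scores)

  excluded <- character()
  if (!is.null(attribution)) {
    bad_attr <- setdiff(unlist(attribution), ATTRIBUTION_LEVELS)
    if (length(bad_attr)) {
      abort(sprintf("Unknown attribution level(s): %s.",
                    paste(bad_attr, collapse = ", ")),
            class = "gvhd_validation_error")
    }
    excluded <- names(attribution)[unlist(attribution) == "non_gvhd_only"]
    excluded <- intersect(excluded, nih_organs())
  }
  graded <- full
  graded[excluded] <- 0L

  severity <- nih_severity_label(matrix(graded, nrow = 1,
                                        dimnames = list(NULL, nih_organs())))
  trace <- character()
  if (length(excluded)) {
    trace <- paste0("exclude.", excluded, ".non_gvhd_only")
  }
  lungs <- graded[["lungs"]]
  n1 <- sum(graded == 1)
  trace <- c(trace, switch(severity,
    severe = if (lungs >= 2) "nih.severe.lung_ge2" else "nih.severe.any_organ_3",
    moderate = if (lungs == 1) "nih.moderate.lung_1"
               else if (any(graded == 2)) "nih.moderate.any_organ_2"
               else "nih.moderate.ge3_organs_score1",
    mild = "nih.mild.le2_organs_score1",
    none = "nih.none.all_scores_0"))
  structure(
    list(severity = severity, scores = full, excluded_organs = excluded,
         karnofsky_pct = karnofsky_pct,
         undefined_other = undefined_other, rule_trace = trace),
    class = "gvhd_nih_severity")
}

#' @export
print.gvhd_nih_severity <- function(x, ...) {
  cat(sprintf("NIH 2014 chronic GvHD global severity: %s\n", x$severity))
  inv <- x$scores[x$scores > 0]
  cat("  organ scores:",
      if (length(inv)) paste(names(inv), inv, collapse = ", ") else "none",
      "\n")
  if (length(x$excluded_organs))
    cat("  excluded (non-GvHD cause):",
        paste(x$excluded_organs, collapse = ", "), "\n")
  if (length(x$undefined_other))
    cat("  undefined other (recorded, not scored):",
        paste(x$undefined_other, collapse = "; "), "\n")
  cat("  rules:", paste(x$rule_trace, collapse = "; "), "\n")
  invisible(x)
}

#' NIH global severity for a table of chronic visits
#'
#' Data-frame verb: expects one column per NIH organ ([nih_organs()]);
#' missing organ columns default to score 0. Optional
#' `<organ>_attribution` columns exclude `"non_gvhd_only"` organs row-wise.
#' `karnofsky_pct` and `undefined_other` columns are carried through
#' unchanged and never affect the severity.
#'
#' @param data Data frame of chronic visits.
#' @return Input tibble with `nih_severity` and `rule_trace` appended.
#' @export
grade_chronic <- function(data) {
  data <- as_tibble(data)
  mat <- sapply(nih_organs(), function(o)
    if (o %in% names(data)) as.integer(data[[o]]) else rep(0L, nrow(data)))
  if (nrow(data) == 1L) mat <- matrix(mat, nrow = 1,
                                      dimnames = list(NULL, nih_organs()))
  for (o in nih_organs()) {
    cl <- paste0(o, "_attribution")
    if (cl %in% names(data)) {
      mat[data[[cl]] == "non_gvhd_only" & !is.na(data[[cl]]), o] <- 0L
    }
  }
  data$nih_severity <- nih_severity_label(mat)
  data
}

#' Choose the NIH lung score source: recent PFT or symptomatic dyspnea
#'
#' Pulmonary function tests are the preferred source for the lung score but
#' only while recent (3-6 months; default staleness window 183 days). When
#' the PFT score is missing or older than the window, the symptomatic
#' dyspnea score is used instead, and the source is recorded so later
#' assessments can trace which information was used.
#'
#' @param pft_score Optional 0-3 lung score from PFTs.
#' @param pft_date Date of the PFT.
#' @param dyspnea_score Optional 0-3 symptomatic dyspnea score.
#' @param assessment_date Date of the GvHD assessment.
#' @param staleness_window_days Maximum PFT age in days (default 183;
#'   92-183 spans the recommended 3-6 months).
#' @return List with `score`, `source` (`"pft"` or `"dyspnea"`) and
#'   `pft_age_days`.
#' @export
#' @examples
#' select_lung_score(pft_score = 2, pft_date = "2026-01-01",
#'                   dyspnea_score = 1, assessment_date = "2026-01-31")
select_lung_score <- function(pft_score = NA_integer_, pft_date = NULL,
                              dyspnea_score = NA_integer_,
                              assessment_date,
                              staleness_window_days = 183) {
  if (!is.na(pft_score)) check_stage(pft_score, "pft_score", 3L)
  if (!is.na(dyspnea_score)) check_stage(dyspnea_score, "dyspnea_score", 3L)
  check_nonneg(staleness_window_days, "staleness_window_days", allow_na = FALSE)
  age <- NA_real_
  if (!is.na(pft_score) && !is.null(pft_date)) {
    age <- as.numeric(as_date(assessment_date) - as_date(pft_date))
  }
  pft_ok <- !is.na(age) && age >= 0 && age <= staleness_window_days
  if (pft_ok) {
    return(list(score = as.integer(pft_score), source = "pft",
                pft_age_days = age))
  }
  if (is.na(dyspnea_score)) {
    abort(paste("No usable lung score: PFT score absent or stale and no",
                "dyspnea score recorded."),
          class = "gvhd_validation_error")
  }
  list(score = as.integer(dyspnea_score), source = "dyspnea",
       pft_age_days = age)
}

#' Percent weight loss over the trailing three months
#'
#' The impact of weight loss on chronic GvHD severity scoring is limited to
#' the three months preceding the assessment: the baseline is the nearest
#' measurement at or before the window start (no interpolation) and the
#' result is floored at zero, so a patient whose loss occurred entirely
#' earlier and has since stabilized scores 0%. With no measurement at or
#' before the window start the quantity is not evaluable (`NA`, with a
#' reason), never silently 0.
#'
#' @param weights Data frame with columns `date` and `weight_kg`.
#' @param assessment_date Date of assessment; the current weight is the
#'   latest measurement at or before it.
#' @param window_months Width of the trailing window (default 3).
#' @return One-row tibble: `pct_loss`, `baseline_date`, `baseline_kg`,
#'   `current_date`, `current_kg`, `evaluable`, `reason`.
#' @export
weight_loss_window_pct <- function(weights, assessment_date,
                                   window_months = 3) {
  weights <- as_tibble(weights)
  stopifnot(all(c("date", "weight_kg") %in% names(weights)))
  check_nonneg(weights$weight_kg, "weight_kg", allow_na = FALSE)
  weights$date <- as_date(weights$date)
  weights <- arrange(weights, .data$date)
  ad <- as_date(assessment_date)
  start <- ad %m-% months(window_months)

  not_eval <- function(reason) tibble(
    pct_loss = NA_real_, baseline_date = as_date(NA), baseline_kg = NA_real_,
    current_date = as_date(NA), current_kg = NA_real_,
    evaluable = FALSE, reason = reason)

  cur <- filter(weights, .data$date <= ad)
  if (nrow(cur) == 0) return(not_eval("no current weight at or before assessment"))
  cur <- cur[nrow(cur), ]
  base <- filter(weights, .data$date <= start)
  if (nrow(base) == 0) {
    return(not_eval("no baseline weight at or before the window start"))
  }
  base <- base[nrow(base), ]
  pct <- max(0, 100 * (base$weight_kg - cur$weight_kg) / base$weight_kg)
  tibble(pct_loss = pct, baseline_date = base$date,
         baseline_kg = base$weight_kg, current_date = cur$date,
         current_kg = cur$weight_kg, evaluable = TRUE, reason = NA_character_)
}

#' Legacy Seattle category for chronic GvHD
#'
#' The original Seattle criteria call chronic GvHD "limited" for localized
#' skin and/or limited hepatic involvement and "extensive" for generalized
#' skin involvement, major hepatic complications, an isolated sicca syndrome
#' or any other organ involvement. The revised criteria move single-organ
#' sicca to "limited" and add extensive triggers: more than two organs
#' involved, skin sclerosis/serositis/fasciitis, bronchiolitis obliterans,
#' Karnofsky-Lansky below 60%, or weight loss above 15%.
#'
#' @param skin_extent `"none"`, `"localized"` or `"generalized"`.
#' @param hepatic `"none"`, `"limited"` or `"major"`.
#' @param single_organ_sicca Logical; isolated sicca (eyes, mouth, vagina).
#' @param organs_involved_count Total organs involved.
#' @param sclerosis_serositis_fasciitis,bronchiolitis_obliterans Logical.
#' @param karnofsky_pct,weight_loss_pct Optional numerics (revised triggers).
#' @param revision `"original"` or `"revised"`.
#' @return Character vector, `"limited"` or `"extensive"`.
#' @export
#' @examples
#' seattle_category(single_organ_sicca = TRUE, organs_involved_count = 1,
#'                  revision = "original")  # "extensive"
#' seattle_category(single_organ_sicca = TRUE, organs_involved_count = 1,
#'                  revision = "revised")   # "limited"
seattle_category <- function(skin_extent = "none", hepatic = "none",
                             single_organ_sicca = FALSE,
                             organs_involved_count = 0,
                             sclerosis_serositis_fasciitis = FALSE,
                             bronchiolitis_obliterans = FALSE,
                             karnofsky_pct = NA_real_,
                             weight_loss_pct = NA_real_,
                             revision = c("revised", "original")) {
  revision <- match.arg(revision)
  a <- recycle_args(skin = skin_extent, hep = hepatic,
                    sicca = single_organ_sicca, n = organs_involved_count,
                    scl = sclerosis_serositis_fasciitis,
                    bo = bronchiolitis_obliterans,
                    kps = karnofsky_pct, wl = weight_loss_pct)
  if (!all(a$skin %in% c("none", "localized", "generalized"))) {
    abort("`skin_extent` must be none/localized/generalized.",
          class = "gvhd_validation_error")
  }
  if (!all(a$hep %in% c("none", "limited", "major"))) {
    abort("`hepatic` must be none/limited/major.",
          class = "gvhd_validation_error")
  }
  check_nonneg(a$n, "organs_involved_count", allow_na = FALSE)
  check_range(a$wl, "weight_loss_pct", allow_na = TRUE)
  check_range(a$kps, "karnofsky_pct", allow_na = TRUE)

  if (revision == "original") {
    other_organ <- a$n > ((a$skin != "none") + (a$hep != "none"))
    extensive <- a$skin == "generalized" | a$hep == "major" |
      a$sicca | other_organ
  } else {
    extensive <- a$skin == "generalized" | a$hep == "major" |
      a$n > 2 | a$scl | a$bo |
      (!is.na(a$kps) & a$kps < 60) |
      (!is.na(a$wl) & a$wl > 15)
  }
  ifelse(extensive, "extensive", "limited")
}
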