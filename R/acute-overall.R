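# Overall acute GvHD grade under the five published systems, with rule
# tracing against the shipped YAML rules file (inst/rules/acute_overall.yaml).

# Vectorized grade labels from stage vectors. kps may be NA.
acute_grade_label <- function(skin, liver, upper_gi, lower_gi, system,
                              kps = NA_real_,
                              karnofsky_bands = c(mild = 90, marked = 70,
                                                  grade_iv = 30)) {
  S <- check_stage(skin, "skin")
  L <- check_stage(liver, "liver")
  U <- check_stage(upper_gi, "upper_gi", max_stage = 1L)
  G <- check_stage(lower_gi, "lower_gi")
  n <- max(length(S), length(L), length(U), length(G))
  S <- rep_len(S, n); L <- rep_len(L, n)
  U <- rep_len(U, n); G <- rep_len(G, n)
  kps <- rep_len(kps, n)

  grade <- rep("0", n)
  if (system == "magic") {
    grade[S %in% 1:2] <- "I"
    grade[S == 3 | L == 1 | U == 1 | G == 1] <- "II"
    grade[L %in% 2:3 | G %in% 2:3] <- "III"
    grade[S == 4 | L == 4 | G == 4] <- "IV"
  } else if (system == "keystone") {
    grade[S %in% 1:2] <- "I"
    grade[S == 3 | L == 1 | U == 1 | G == 1] <- "II"
    grade[L %in% 2:3 | G %in% 2:4] <- "III"
    grade[S == 4 | L == 4] <- "IV"
  } else if (system == "minnesota") {
    grade[S %in% 1:2] <- "I"
    grade[S == 3 | L == 1 | U == 1 | G == 1] <- "II"
    grade[L %in% 2:4 | G %in% 2:3] <- "III"
    grade[S == 4 | G == 4] <- "IV"
  } else if (system == "ibmtr") {
    # IBMTR letter grades; upper-GI stage does not enter (lower-GI only rows)
    grade[S == 1] <- "A"
    grade[S == 2 | L %in% 1:2 | G %in% 1:2] <- "B"
    grade[S == 3 | L == 3 | G == 3] <- "C"
    grade[S == 4 | L == 4 | G == 4] <- "D"
  } else { # glucksberg_original (upper GI not staged in this system)
    involved <- S >= 1 | L >= 1 | G >= 1
    any2 <- S >= 2 | L >= 2 | G >= 2
    if (any(any2 & is.na(kps))) {
      abort(paste("The original Glucksberg overall grade requires",
                  "`karnofsky_pct` when any organ stage is >= 2",
                  "(performance status is a rule input)."),
            class = "gvhd_validation_error")
    }
    mild <- !is.na(kps) & kps < karnofsky_bands[["mild"]]
    marked <- !is.na(kps) & kps < karnofsky_bands[["marked"]]
    kiv <- !is.na(kps) & kps < karnofsky_bands[["grade_iv"]]
    grade[involved] <- "I"
    grade[S %in% 1:2 & (L %in% 1:2 | G %in% 1:2) & mild] <- "II"
    grade[any2 & marked] <- "III"
    grade[any2 & kiv] <- "IV"
  }
  grade
}

# Which organ clauses fired for a single graded case (trace ids match the
# YAML rules file: <system>.<grade>.<clause>).
acute_grade_trace <- function(S, L, U, G, system, grade, kps = NA_real_) {
  tr <- character()
  add <- function(tr, cond, id) if (isTRUE(cond)) c(tr, id) else tr
  p <- function(...) paste0(system, ".", ...)
  if (grade == "0") return(p("0.all_organs_0"))
  if (system %in% c("magic", "keystone", "minnesota")) {
    if (grade == "I") tr <- add(tr, S %in% 1:2, p("I.skin1-2"))
    if (grade == "II") {
      tr <- add(tr, S == 3, p("II.skin3"))
      tr <- add(tr, L == 1, p("II.liver1"))
      tr <- add(tr, U == 1, p("II.upper_gi1"))
      tr <- add(tr, G == 1, p("II.lower_gi1"))
    }
    if (grade == "III") {
      liv3 <- if (system == "minnesota") L %in% 2:4 else L %in% 2:3
      gi3 <- if (system == "keystone") G %in% 2:4 else G %in% 2:3
      tr <- add(tr, liv3, p("III.liver"))
      tr <- add(tr, gi3, p("III.lower_gi"))
    }
    if (grade == "IV") {
      tr <- add(tr, S == 4, p("IV.skin4"))
      tr <- add(tr, system != "minnesota" && L == 4, p("IV.liver4"))
      tr <- add(tr, system %in% c("magic", "minnesota") && G == 4,
                p("IV.lower_gi4"))
    }
  } else if (system == "ibmtr") {
    if (grade == "A") tr <- add(tr, S == 1, p("A.skin1"))
    if (grade == "B") {
      tr <- add(tr, S == 2, p("B.skin2"))
      tr <- add(tr, L %in% 1:2, p("B.liver1-2"))
      tr <- add(tr, G %in% 1:2, p("B.lower_gi1-2"))
    }
    if (grade == "C") {
      tr <- add(tr, S == 3, p("C.skin3"))
      tr <- add(tr, L == 3, p("C.liver3"))
      tr <- add(tr, G == 3, p("C.lower_gi3"))
    }
    if (grade == "D") {
      tr <- add(tr, S == 4, p("D.skin4"))
      tr <- add(tr, L == 4, p("D.liver4"))
      tr <- add(tr, G == 4, p("D.lower_gi4"))
    }
  } else { # glucksberg_original: Karnofsky mapping is an extrapolation
    tr <- c(tr, p("karnofsky_bands.extrapolated"))
    if (grade == "I") tr <- c(tr, p("I.any_involvement_floor"))
    if (grade == "II") tr <- c(tr, p("II.skin_plus_visceral_mild_ps"))
    if (grade == "III") tr <- c(tr, p("III.stage2plus_marked_ps"))
    if (grade == "IV") tr <- c(tr, p("IV.stage2plus_karnofsky_lt30"))
  }
  tr
}

#' Overall acute GvHD grade for one stage vector
#'
#' Applies one grading system's overall-grade table to a staged organ vector
#' (skin 0-4, liver 0-4, upper GI 0-1, lower GI 0-4). Organs listed in
#' `excluded_organs` (manifestation solely due to a non-GvHD cause) are set
#' to stage 0 before grading and reported in the rule trace. The Karnofsky
#' performance status enters only the original Glucksberg system; all other
#' systems record it without letting it contribute to the overall grade.
#'
#' @param skin,liver,upper_gi,lower_gi Integer organ stages.
#' @param system One of [acute_systems()].
#' @param karnofsky_pct Optional 0-100; required by `glucksberg_original`
#'   when any organ stage is >= 2.
#' @param excluded_organs Character subset of
#'   `c("skin", "liver", "upper_gi", "lower_gi")`.
#' @param karnofsky_bands Named cutoffs mapping the original Glucksberg
#'   "mild"/"marked" performance-status decreases (an extrapolation,
#'   flagged in the trace).
#' @return An object of class `gvhd_grade`: list with `grade`, `system`,
#'   `stages`, `excluded_organs` and `rule_trace`.
#' @export
#' @examples
#' overall_acute_grade(0, 0, 0, 4, system = "magic")$grade     # "IV"
#' overall_acute_grade(0, 4, 0, 0, system = "minnesota")$grade # "III"
overall_acute_grade <- function(skin, liver, upper_gi, lower_gi,
                                system = "magic",
                                karnofsky_pct = NA_real_,
                                excluded_organs = character(),
                                karnofsky_bands = c(mild = 90, marked = 70,
                                                    grade_iv = 30)) {
  system <- match_system(system)
  stopifnot(length(skin) == 1L)
  bad <- setdiff(excluded_organs, c("skin", "liver", "upper_gi", "lower_gi"))
  if (length(bad)) {
    abort(sprintf("Unknown organ(s) in `excluded_organs`: %s.",
                  paste(bad, collapse = ", ")),
          class = "gvhd_validation_error")
  }
  stages <- c(skin = as.integer(skin), liver = as.integer(liver),
              upper_gi = as.integer(upper_gi),
              lower_gi = as.integer(lower_gi))
  graded <- stages
  graded[excluded_organs] <- 0L
  if (!is.na(karnofsky_pct)) check_range(karnofsky_pct, "karnofsky_pct")

  grade <- acute_grade_label(graded[["skin"]], graded[["liver"]],
                             graded[["upper_gi"]], graded[["lower_gi"]],
                             system, kps = karnofsky_pct,
                             karnofsky_bands = karnofsky_bands)
  trace <- acute_grade_trace(graded[["skin"]], graded[["liver"]],
                             graded[["upper_gi"]], graded[["lower_gi"]],
                             system, grade, kps = karnofsky_pct)
  if (length(excluded_organs)) {
    trace <- c(paste0("exclude.", excluded_organs, ".non_gvhd_only"), trace)
  }
  structure(
    list(grade = grade, system = system, stages = stages,
         excluded_organs = excluded_organs, rule_trace = trace),
    class = "gvhd_grade")
}

#' @export
print.gvhd_grade <- function(x, ...) {
  cat(sprintf("Acute GvHD overall grade %s [%s]\n", x$grade, x$system))
  cat(sprintf("  stages: skin %d, liver %d, upper GI %d, lower GI %d\n",
              x$stages[["skin"]], x$stages[["liver"]],
              x$stages[["upper_gi"]], x$stages[["lower_gi"]]))
  if (length(x$excluded_organs)) {
    cat("  excluded (non-GvHD cause):",
        paste(x$excluded_organs, collapse = ", "), "\n")
  }
  cat("  rules:", paste(x$rule_trace, collapse = "; "), "\n")
  invisible(x)
}

#' Grade a table of staged visits under one or all acute systems
#'
#' Data-frame verb: takes visit rows carrying `skin_stage`, `liver_stage`,
#' `upper_gi_stage` and `lower_gi_stage` columns (e.g. from [stage_acute()])
#' and appends the overall grade. Attribution columns
#' (`<organ>_attribution == "non_gvhd_only"`) exclude that organ row-wise.
#'
#' @param data Data frame with stage columns.
#' @param system One of [acute_systems()], or `"all"` for a long table with
#'   one row per visit x system.
#' @param karnofsky_col Name of an optional Karnofsky column (used only by
#'   `glucksberg_original`).
#' @return Tibble with `system`, `grade` and `rule_trace` columns appended.
#' @export
grade_acute <- function(data, system = "magic", karnofsky_col = "karnofsky_pct") {
  data <- as_tibble(data)
  systems <- if (identical(system, "all")) acute_systems() else match_system(system)
  kps <- if (karnofsky_col %in% names(data)) data[[karnofsky_col]] else
    rep(NA_real_, nrow(data))
  excl <- lapply(seq_len(nrow(data)), function(i) {
    organs <- c("skin", "liver", "upper_gi", "lower_gi")
    cols <- paste0(organs, "_attribution")
    organs[vapply(cols, function(cl)
      cl %in% names(data) && identical(data[[cl]][i], "non_gvhd_only"),
      logical(1))]
  })
  one_system <- function(sys) {
    res <- lapply(seq_len(nrow(data)), function(i) {
      g <- overall_acute_grade(data$skin_stage[i], data$liver_stage[i],
                               data$upper_gi_stage[i], data$lower_gi_stage[i],
                               system = sys, karnofsky_pct = kps[i],
                               excluded_organs = excl[[i]])
      tibble(system = sys, grade = g$grade,
             rule_trace = paste(g$rule_trace, collapse = ";"))
    })
    dplyr::bind_cols(data, dplyr::bind_rows(res))
  }
  dplyr::bind_rows(lapply(systems, one_system))
}

#' MAGIC diagnostic-confidence level for acute GvHD
#'
#' Maps the four MAGIC criteria to a confidence level: a definitive
#' alternative histologic diagnosis gives `"negative"`, histological
#' confirmation `"confirmed"`, initiation of GvHD treatment `"probable"`,
#' and resolution without therapeutic intervention `"possible"`, with
#' precedence negative > confirmed > probable > possible.
#'
#' @param histology_confirmed,treated,resolved_without_treatment,alternative_histology
#'   Logical flags; `resolved_without_treatment` contradicts `treated`.
#' @return One of `"confirmed"`, `"probable"`, `"possible"`, `"negative"`.
#' @export
#' @examples
#' confidence_level(histology_confirmed = TRUE, treated = TRUE)  # "confirmed"
confidence_level <- function(histology_confirmed = FALSE,
                             treated = FALSE,
                             resolved_without_treatment = FALSE,
                             alternative_histology = FALSE) {
  a <- recycle_args(h = histology_confirmed, t = treated,
                    r = resolved_without_treatment,
                    alt = alternative_histology)
  if (any(a$r & a$t)) {
    abort("`resolved_without_treatment` contradicts `treated`.",
          class = "gvhd_validation_error")
  }
  if (any(!(a$h | a$t | a$r | a$alt))) {
    abort(paste("No confidence criterion set: need at least one of histology,",
                "treatment, resolution without treatment, or alternative",
                "histologic diagnosis."),
          class = "gvhd_validation_error")
  }
  out <- rep("possible", length(a$h))
  out[a$t] <- "probable"
  out[a$h] <- "confirmed"
  out[a$alt] <- "negative"
  out
}
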