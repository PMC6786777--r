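# Cross-system comparison of overall acute grades on a cohort of staged
# patients: exact and grade-III/IV-pooled agreement, a disagreement census
# by driving organ, and descriptive unweighted Cohen's kappa.

# letter <-> roman alignment for cross-system comparison
grade_rank <- function(grade) {
  r <- match(grade, ROMAN_GRADES)
  r[is.na(r)] <- match(grade[is.na(r)], IBMTR_GRADES)
  r - 1L
}

pool_grades <- function(grade, pool = c("III", "IV")) {
  rk <- grade_rank(grade)
  pool_rk <- sort(grade_rank(pool))
  ifelse(rk %in% pool_rk, paste(pool, collapse = "+"), as.character(rk))
}

cohen_kappa <- function(a, b) {
  tab <- table(factor(a, levels = union(a, b)), factor(b, levels = union(a, b)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

# organ driving a grade, extracted from the rule-trace ids
driving_organ <- function(rule_trace) {
  ids <- strsplit(rule_trace, ";")[[1]]
  ids <- ids[!grepl("^exclude\\.|karnofsky_bands|all_organs_0", ids)]
  organ <- sub("^[^.]+\\.[^.]+\\.", "", ids)
  organ <- sub("[0-9].*$|-.*$|_floor$|_plus.*$|plus.*$", "", organ)
  organ <- unique(organ[nzchar(organ)])
  if (!length(organ)) "none" else paste(sort(organ), collapse = "+")
}

#' Compare acute grading systems on a staged cohort
#'
#' Grades every patient under each requested system from identical staging
#' inputs and summarises pairwise agreement: exact, and with grades III and
#' IV pooled (the comparison under which MAGIC and the modified Glucksberg
#' criteria are anticipated to coincide). IBMTR letter grades are aligned
#' positionally (A-D with I-IV). Disagreements are annotated with the organ
#' whose staging drives the higher grade. Unweighted Cohen's kappa is
#' included as a descriptive statistic only.
#'
#' @param data Data frame with `skin_stage`, `liver_stage`,
#'   `upper_gi_stage`, `lower_gi_stage` columns (e.g. [stage_grid()] or
#'   [stage_acute()] output).
#' @param systems Systems to compare (default all except the original
#'   Glucksberg system, which needs `karnofsky_pct`).
#' @param pool Grades pooled for the pooled-agreement figure.
#' @param karnofsky_pct Optional vector for `glucksberg_original`.
#' @return Object of class `gvhd_concordance`: `grades` (wide tibble),
#'   `agreement` (pairwise tibble), `disagreements` (census tibble), `n`,
#'   `pool`.
#' @export
#' @examples
#' cc <- compare_systems(stage_grid())
#' tidy(cc)
compare_systems <- function(data,
                            systems = c("magic", "keystone", "minnesota",
                                        "ibmtr"),
                            pool = c("III", "IV"),
                            karnofsky_pct = NULL) {
  data <- as_tibble(data)
  systems <- vapply(systems, match_system, character(1), USE.NAMES = FALSE)
  if ("glucksberg_original" %in% systems && is.null(karnofsky_pct)) {
    abort("`karnofsky_pct` is required to grade under glucksberg_original.",
          class = "gvhd_validation_error")
  }
  if (!is.null(karnofsky_pct)) data$karnofsky_pct <- karnofsky_pct
  grades <- data
  traces <- list()
  for (sys in systems) {
    g <- grade_acute(data, system = sys)
    grades[[paste0("grade_", sys)]] <- g$grade
    traces[[sys]] <- g$rule_trace
  }

  pairs <- utils::combn(systems, 2, simplify = FALSE)
  agreement <- bind_rows(lapply(pairs, function(p) {
    a <- grades[[paste0("grade_", p[1])]]
    b <- grades[[paste0("grade_", p[2])]]
    exact <- grade_rank(a) == grade_rank(b)
    pa <- pool_grades(a, pool)
    pb <- pool_grades(b, pool)
    tibble(system_a = p[1], system_b = p[2],
           n = length(a),
           exact_agreement = mean(exact),
           pooled_agreement = mean(pa == pb),
           kappa = cohen_kappa(grade_rank(a), grade_rank(b)))
  }))

  disagreements <- bind_rows(lapply(pairs, function(p) {
    a <- grades[[paste0("grade_", p[1])]]
    b <- grades[[paste0("grade_", p[2])]]
    idx <- which(grade_rank(a) != grade_rank(b))
    if (!length(idx)) return(NULL)
    organ <- vapply(idx, function(i) {
      hi <- if (grade_rank(a[i]) > grade_rank(b[i])) p[1] else p[2]
      driving_organ(traces[[hi]][i])
    }, character(1))
    tibble(system_a = p[1], system_b = p[2], row = idx,
           grade_a = a[idx], grade_b = b[idx], driving_organ = organ)
  }))
  if (is.null(disagreements)) {
    disagreements <- tibble(system_a = character(), system_b = character(),
                            row = integer(), grade_a = character(),
                            grade_b = character(),
                            driving_organ = character())
  }

  structure(list(grades = grades, agreement = agreement,
                 disagreements = disagreements, n = nrow(data),
                 pool = pool, systems = systems),
            class = "gvhd_concordance")
}

#' @export
print.gvhd_concordance <- function(x, ...) {
  cat(sprintf("Acute GvHD grading concordance: %d patients, systems %s\n",
              x$n, paste(x$systems, collapse = ", ")))
  cat(sprintf("(pooled agreement merges grades %s)\n",
              paste(x$pool, collapse = "+")))
  print(x$agreement)
  invisible(x)
}

#' @describeIn compare_systems Pairwise agreement as a tidy tibble.
#' @param x A `gvhd_concordance` object.
#' @param ... Unused.
#' @export
tidy.gvhd_concordance <- function(x, ...) {
  x$agreement
}

#' @describeIn compare_systems One-row cohort summary.
#' @export
glance.gvhd_concordance <- function(x, ...) {
  tibble(n = x$n, n_systems = length(x$systems),
         n_pairs = nrow(x$agreement),
         mean_exact_agreement = mean(x$agreement$exact_agreement),
         mean_pooled_agreement = mean(x$agreement$pooled_agreement),
         n_disagreements = nrow(x$disagreements))
}

#' @describeIn compare_systems Heatmap of pairwise agreement.
#' @param object A `gvhd_concordance` object.
#' @export
autoplot.gvhd_concordance <- function(object, ...) {
  long <- tidyr::pivot_longer(object$agreement,
                              c("exact_agreement", "pooled_agreement"),
                              names_to = "measure", values_to = "agreement")
  long$pair <- paste(long$system_a, "vs", long$system_b)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$measure, y = .data$pair,
                                     fill = .data$agreement)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$agreement)), color = "white") +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "#762a83",
                                 high = "#1b7837") +
    ggplot2::labs(x = NULL, y = NULL, fill = "agreement",
                  title = "Acute GvHD grading-system concordance",
                  subtitle = sprintf("grades %s pooled for the pooled measure",
                                     paste(object$pool, collapse = "+")))
}
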