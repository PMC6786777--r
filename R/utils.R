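# Internal validation helpers and shared constants.

# Ratio between the printed umol/L and mg/dL bilirubin staging thresholds
# (34/2, 51/3, 102/6, 255/15). The laboratory molar factor is 17.1; the
# staging tables embody 17, and the engine reproduces the printed thresholds.
BILI_UMOL_PER_MGDL <- 17

ATTRIBUTION_LEVELS <- c("gvhd", "mixed", "non_gvhd_only")
ROMAN_GRADES <- c("0", "I", "II", "III", "IV")
IBMTR_GRADES <- c("0", "A", "B", "C", "D")

check_range <- function(x, field, lo = 0, hi = 100, allow_na = FALSE) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    abort(sprintf("`%s` must be in [%s, %s]; got %s.",
                  field, lo, hi, paste(unique(x[bad]), collapse = ", ")),
          class = "gvhd_validation_error")
  }
  if (!allow_na && anyNA(x)) {
    abort(sprintf("`%s` must not contain missing values.", field),
          class = "gvhd_validation_error")
  }
  invisible(x)
}

check_nonneg <- function(x, field, allow_na = TRUE) {
  bad <- !is.na(x) & x < 0
  if (any(bad)) {
    abort(sprintf("`%s` must be non-negative.", field),
          class = "gvhd_validation_error")
  }
  if (!allow_na && anyNA(x)) {
    abort(sprintf("`%s` must not contain missing values.", field),
          class = "gvhd_validation_error")
  }
  invisible(x)
}

check_stage <- function(x, field, max_stage = 4L) {
  if (anyNA(x) || !all(x %in% 0:max_stage)) {
    abort(sprintf("`%s` must be an integer stage in 0..%d.", field, max_stage),
          class = "gvhd_validation_error")
  }
  invisible(as.integer(x))
}

match_system <- function(system) {
  system <- match.arg(system, acute_systems())
  system
}

# Recycle scalar arguments against a common length, tibble-style.
recycle_args <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  bad <- lengths(args) != 1L & lengths(args) != n
  if (any(bad)) {
    abort(sprintf("Arguments must have length 1 or %d: %s.", n,
                  paste(names(args)[bad], collapse = ", ")),
          class = "gvhd_validation_error")
  }
  lapply(args, rep_len, n)
}

#' Convert bilirubin between mg/dL and the staging table's μmol/L scale
#'
#' The acute liver stage is banded on total serum bilirubin in mg/dL; inputs
#' in μmol/L are divided by the ratio the printed band pairs embody (17, e.g.
#' 255 μmol/L paired with 15 mg/dL) so that every printed μmol/L threshold is
#' reproduced exactly.
#'
#' @param x Numeric vector of bilirubin values.
#' @param from,to Units, `"mg_dl"` or `"umol_l"`.
#' @return Numeric vector in the `to` unit.
#' @export
#' @examples
#' convert_bilirubin(255, from = "umol_l", to = "mg_dl")
convert_bilirubin <- function(x, from = c("umol_l", "mg_dl"),
                              to = c("mg_dl", "umol_l")) {
  from <- match.arg(from)
  to <- match.arg(to)
  check_nonneg(x, "bilirubin")
  if (from == to) return(x)
  if (from == "umol_l") x / BILI_UMOL_PER_MGDL else x * BILI_UMOL_PER_MGDL
}
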