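test_that("worked NIH severity mappings hold", {
  expect_identical(nih_global_severity(c(mouth = 1, eyes = 1))$severity,
                   "mild")
  expect_identical(nih_global_severity(c(lungs = 2))$severity, "severe")
  expect_identical(nih_global_severity(c(lungs = 1))$severity, "moderate")
  expect_identical(nih_global_severity(c(lungs = 3))$severity, "severe")
  expect_identical(nih_global_severity(c(skin = 2))$severity, "moderate")
  expect_identical(
    nih_global_severity(c(skin = 1, mouth = 1, eyes = 1))$severity,
    "moderate")
  expect_identical(nih_global_severity(c())$severity, "none")
  expect_error(nih_global_severity(c(skin = 4)),
               class = "gvhd_validation_error")
  expect_error(nih_global_severity(c(spleen = 1)),
               class = "gvhd_validation_error")
})

test_that("all 65,536 score vectors match the closed-form predicate oracle", {
  grid <- as.matrix(expand.grid(rep(list(0:3), 8)))
  colnames(grid) <- nih_organs()
  got <- nih_severity_label(grid)
  want <- apply(grid, 1, oracle_nih_severity)
  expect_identical(got, unname(want))
})

test_that("NIH severity is monotone non-decreasing in every organ score", {
  grid <- as.matrix(expand.grid(rep(list(0:3), 8)))
  colnames(grid) <- nih_organs()
  rank <- function(lab) match(lab, c("none", "mild", "moderate", "severe"))
  base <- rank(nih_severity_label(grid))
  for (org in nih_organs()) {
    bump <- grid
    bump[, org] <- pmin(bump[, org] + 1L, 3L)
    expect_true(all(rank(nih_severity_label(bump)) >= base),
                label = sprintf("monotone in %s", org))
  }
})

test_that("non-GvHD attribution equals zeroing; Karnofsky and undefined-other never matter", {
  set.seed(42)
  for (i in 1:50) {
    s <- stats::setNames(sample(0:3, 8, replace = TRUE), nih_organs())
    org <- sample(nih_organs(), 1)
    excl <- nih_global_severity(s, attribution =
                                  stats::setNames("non_gvhd_only", org))
    zeroed <- s
    zeroed[org] <- 0
    expect_identical(excl$severity, nih_global_severity(zeroed)$severity)
    # metamorphic: karnofsky and undefined-other leave the label unchanged
    a <- nih_global_severity(s, karnofsky_pct = 100)
    b <- nih_global_severity(s, karnofsky_pct = 40,
                             undefined_other = c("eosinophilia", "serositis"))
    expect_identical(a$severity, b$severity)
  }
})

test_that("lung score comes from a recent PFT, else the dyspnea score", {
  r <- select_lung_score(pft_score = 2, pft_date = "2026-01-01",
                         dyspnea_score = 1, assessment_date = "2026-01-31")
  expect_identical(r[c("score", "source")], list(score = 2L, source = "pft"))
  r <- select_lung_score(pft_score = 2, pft_date = "2025-06-01",
                         dyspnea_score = 1, assessment_date = "2026-01-31")
  expect_identical(r[c("score", "source")],
                   list(score = 1L, source = "dyspnea"))
  r <- select_lung_score(dyspnea_score = 0, assessment_date = "2026-01-31")
  expect_identical(r[c("score", "source")],
                   list(score = 0L, source = "dyspnea"))
  # window boundary: 183 days is still recent, 184 is stale
  r <- select_lung_score(2, as.Date("2026-01-31") - 183, 1, "2026-01-31")
  expect_identical(r$source, "pft")
  r <- select_lung_score(2, as.Date("2026-01-31") - 184, 1, "2026-01-31")
  expect_identical(r$source, "dyspnea")
  # tighter configured window
  r <- select_lung_score(2, as.Date("2026-01-31") - 100, 1, "2026-01-31",
                         staleness_window_days = 92)
  expect_identical(r$source, "dyspnea")
  expect_error(select_lung_score(assessment_date = "2026-01-31"),
               class = "gvhd_validation_error")
})

test_that("weight loss is windowed to the trailing three months", {
  w <- tibble::tibble(date = as.Date(c("2025-10-01", "2026-01-01")),
                      weight_kg = c(80, 72))
  out <- weight_loss_window_pct(w, "2026-01-01")
  expect_equal(out$pct_loss, 10)
  # loss entirely more than 3 months ago, stable since -> 0%
  w2 <- tibble::tibble(date = as.Date(c("2025-01-01", "2025-06-01",
                                        "2026-01-01")),
                       weight_kg = c(90, 72, 72))
  expect_equal(weight_loss_window_pct(w2, "2026-01-01")$pct_loss, 0)
  # no baseline at or before the window start -> not evaluable, not 0
  w3 <- tibble::tibble(date = as.Date(c("2025-12-01", "2026-01-01")),
                       weight_kg = c(80, 72))
  out3 <- weight_loss_window_pct(w3, "2026-01-01")
  expect_false(out3$evaluable)
  expect_true(is.na(out3$pct_loss))
  # gains are floored at zero
  w4 <- tibble::tibble(date = as.Date(c("2025-09-01", "2026-01-01")),
                       weight_kg = c(70, 75))
  expect_equal(weight_loss_window_pct(w4, "2026-01-01")$pct_loss, 0)
})

test_that("irregularly sampled weights match brute-force recomputation", {
  set.seed(7)
  for (i in 1:20) {
    dates <- sort(as.Date("2025-01-01") + sample(0:400, 12))
    w <- tibble::tibble(date = dates,
                        weight_kg = round(stats::runif(12, 55, 90), 1))
    ad <- as.Date("2025-01-01") + sample(120:420, 1)
    out <- weight_loss_window_pct(w, ad)
    start <- lubridate::`%m-%`(ad, months(3))
    base_idx <- which(w$date <= start)
    cur_idx <- which(w$date <= ad)
    if (!length(base_idx) || !length(cur_idx)) {
      expect_false(out$evaluable)
    } else {
      b <- w$weight_kg[max(base_idx)]
      cur <- w$weight_kg[max(cur_idx)]
      expect_equal(out$pct_loss, max(0, 100 * (b - cur) / b))
    }
  }
})

test_that("Seattle categories follow the original and revised columns", {
  expect_identical(seattle_category(skin_extent = "localized",
                                    organs_involved_count = 1,
                                    revision = "original"), "limited")
  expect_identical(seattle_category(single_organ_sicca = TRUE,
                                    organs_involved_count = 1,
                                    revision = "original"), "extensive")
  expect_identical(seattle_category(single_organ_sicca = TRUE,
                                    organs_involved_count = 1,
                                    revision = "revised"), "limited")
  expect_identical(seattle_category(weight_loss_pct = 16,
                                    revision = "revised"), "extensive")
  expect_identical(seattle_category(weight_loss_pct = 15,
                                    revision = "revised"), "limited")
  expect_identical(seattle_category(karnofsky_pct = 55,
                                    revision = "revised"), "extensive")
  expect_identical(seattle_category(organs_involved_count = 3,
                                    revision = "revised"), "extensive")
  expect_identical(seattle_category(bronchiolitis_obliterans = TRUE,
                                    revision = "revised"), "extensive")
  expect_identical(seattle_category(skin_extent = "generalized",
                                    revision = "original"), "extensive")
  # any other organ involvement is extensive under the original column
  expect_identical(seattle_category(skin_extent = "localized",
                                    organs_involved_count = 2,
                                    revision = "original"), "extensive")
})

test_that("grade_chronic grades a visit table with attribution columns", {
  df <- tibble::tibble(skin = c(1, 3), mouth = c(1, 0), lungs = c(0, 0),
                       skin_attribution = c("gvhd", "non_gvhd_only"))
  out <- grade_chronic(df)
  expect_identical(out$nih_severity, c("mild", "none"))
})
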