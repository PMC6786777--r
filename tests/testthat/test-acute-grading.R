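test_that("worked overall-grade mappings match the printed tables", {
  expect_identical(overall_acute_grade(0, 0, 0, 4, "magic")$grade, "IV")
  expect_identical(overall_acute_grade(0, 4, 0, 0, "minnesota")$grade, "III")
  expect_identical(overall_acute_grade(0, 0, 1, 0, "keystone")$grade, "II")
  expect_identical(overall_acute_grade(0, 4, 0, 0, "keystone")$grade, "IV")
  expect_identical(overall_acute_grade(4, 0, 0, 0, "minnesota")$grade, "IV")
  expect_identical(overall_acute_grade(0, 0, 0, 4, "keystone")$grade, "III")
  expect_identical(overall_acute_grade(2, 0, 0, 0, "ibmtr")$grade, "B")
  for (sys in acute_systems()) {
    expect_identical(
      overall_acute_grade(0, 0, 0, 0, sys, karnofsky_pct = 100)$grade, "0",
      label = sys)
  }
})

test_that("every stage tuple matches the hand-built table oracle, all systems", {
  grid <- stage_grid()
  for (sys in c("magic", "keystone", "minnesota", "ibmtr")) {
    got <- acute_grade_label(grid$skin_stage, grid$liver_stage,
                             grid$upper_gi_stage, grid$lower_gi_stage, sys)
    want <- mapply(oracle_acute_grade, grid$skin_stage, grid$liver_stage,
                   grid$upper_gi_stage, grid$lower_gi_stage, sys)
    expect_identical(got, unname(want), label = sys)
  }
  for (kps in c(100, 80, 60, 20)) {
    got <- acute_grade_label(grid$skin_stage, grid$liver_stage,
                             grid$upper_gi_stage, grid$lower_gi_stage,
                             "glucksberg_original", kps = kps)
    want <- mapply(oracle_acute_grade, grid$skin_stage, grid$liver_stage,
                   grid$upper_gi_stage, grid$lower_gi_stage,
                   "glucksberg_original", kps)
    expect_identical(got, unname(want),
                     label = sprintf("glucksberg kps=%d", kps))
  }
})

test_that("raising any single organ stage never lowers the overall grade", {
  grid <- stage_grid()
  organs <- c("skin_stage", "liver_stage", "upper_gi_stage", "lower_gi_stage")
  caps <- c(skin_stage = 4L, liver_stage = 4L, upper_gi_stage = 1L,
            lower_gi_stage = 4L)
  for (sys in acute_systems()) {
    kps <- if (sys == "glucksberg_original") 50 else NA_real_
    base <- vapply(acute_grade_label(grid$skin_stage, grid$liver_stage,
                                     grid$upper_gi_stage,
                                     grid$lower_gi_stage, sys, kps),
                   oracle_grade_rank, integer(1))
    for (org in organs) {
      bump <- grid
      bump[[org]] <- pmin(bump[[org]] + 1L, caps[[org]])
      bumped <- vapply(acute_grade_label(bump$skin_stage, bump$liver_stage,
                                         bump$upper_gi_stage,
                                         bump$lower_gi_stage, sys, kps),
                       oracle_grade_rank, integer(1))
      expect_true(all(bumped >= base),
                  label = sprintf("%s monotone in %s", sys, org))
    }
  }
})

test_that("single-organ stage-4 implications hold per system", {
  grid <- stage_grid()
  magic <- acute_grade_label(grid$skin_stage, grid$liver_stage,
                             grid$upper_gi_stage, grid$lower_gi_stage, "magic")
  expect_true(all(magic[grid$lower_gi_stage == 4] == "IV"))
  minn <- acute_grade_label(grid$skin_stage, grid$liver_stage,
                            grid$upper_gi_stage, grid$lower_gi_stage,
                            "minnesota")
  expect_true(all(minn[grid$skin_stage == 4 | grid$lower_gi_stage == 4] == "IV"))
  expect_identical(
    unique(minn[grid$liver_stage == 4 & grid$skin_stage != 4 &
                  grid$lower_gi_stage != 4]), "III")
  key <- acute_grade_label(grid$skin_stage, grid$liver_stage,
                           grid$upper_gi_stage, grid$lower_gi_stage,
                           "keystone")
  expect_true(all(key[grid$skin_stage == 4 | grid$liver_stage == 4] == "IV"))
})

test_that("MAGIC and Keystone agree everywhere once grades III and IV pool", {
  grid <- stage_grid()
  magic <- acute_grade_label(grid$skin_stage, grid$liver_stage,
                             grid$upper_gi_stage, grid$lower_gi_stage, "magic")
  key <- acute_grade_label(grid$skin_stage, grid$liver_stage,
                           grid$upper_gi_stage, grid$lower_gi_stage,
                           "keystone")
  pool <- function(g) ifelse(g %in% c("III", "IV"), "III+IV", g)
  expect_identical(pool(magic), pool(key))
  # disagreements with identical staging inputs sit only on the III/IV split
  dis <- magic != key
  expect_true(all(magic[dis] %in% c("III", "IV") & key[dis] %in% c("III", "IV")))
})

test_that("non-GvHD attribution excludes the organ exactly like stage 0", {
  grid <- stage_grid()
  for (sys in c("magic", "keystone", "minnesota", "ibmtr")) {
    for (i in sample(nrow(grid), 40)) {
      excl <- overall_acute_grade(grid$skin_stage[i], grid$liver_stage[i],
                                  grid$upper_gi_stage[i],
                                  grid$lower_gi_stage[i], sys,
                                  excluded_organs = "liver")
      zeroed <- overall_acute_grade(grid$skin_stage[i], 0,
                                    grid$upper_gi_stage[i],
                                    grid$lower_gi_stage[i], sys)
      expect_identical(excl$grade, zeroed$grade)
      expect_true("exclude.liver.non_gvhd_only" %in% excl$rule_trace)
    }
  }
})

test_that("Karnofsky enters only the original Glucksberg grade", {
  for (sys in c("magic", "keystone", "minnesota", "ibmtr")) {
    g1 <- overall_acute_grade(2, 2, 0, 0, sys, karnofsky_pct = 100)
    g2 <- overall_acute_grade(2, 2, 0, 0, sys, karnofsky_pct = 40)
    expect_identical(g1$grade, g2$grade, label = sys)
  }
  expect_identical(
    overall_acute_grade(2, 2, 0, 0, "glucksberg_original",
                        karnofsky_pct = 100)$grade, "I")
  expect_identical(
    overall_acute_grade(2, 2, 0, 0, "glucksberg_original",
                        karnofsky_pct = 60)$grade, "III")
  expect_identical(
    overall_acute_grade(2, 2, 0, 0, "glucksberg_original",
                        karnofsky_pct = 20)$grade, "IV")
  expect_error(
    overall_acute_grade(2, 2, 0, 0, "glucksberg_original"),
    class = "gvhd_validation_error")
})

test_that("rule-trace ids all resolve to entries in the shipped YAML rules", {
  rules <- yaml::read_yaml(system.file("rules", "acute_overall.yaml",
                                       package = "gvhdgrade"))
  known <- unlist(lapply(rules, function(sys) vapply(sys, `[[`, "", "id")))
  grid <- stage_grid()
  idx <- sample(nrow(grid), 60)
  for (sys in c("magic", "keystone", "minnesota", "ibmtr")) {
    for (i in idx) {
      tr <- overall_acute_grade(grid$skin_stage[i], grid$liver_stage[i],
                                grid$upper_gi_stage[i],
                                grid$lower_gi_stage[i], sys)$rule_trace
      expect_true(all(tr %in% known),
                  label = sprintf("%s trace: %s", sys,
                                  paste(tr, collapse = ",")))
    }
  }
})

test_that("confidence levels map the four MAGIC criteria with precedence", {
  expect_identical(confidence_level(TRUE, TRUE), "confirmed")
  expect_identical(confidence_level(treated = TRUE), "probable")
  expect_identical(confidence_level(resolved_without_treatment = TRUE),
                   "possible")
  expect_identical(confidence_level(alternative_histology = TRUE), "negative")
  # precedence: negative beats histology; histology beats treatment
  expect_identical(confidence_level(TRUE, TRUE, FALSE, TRUE), "negative")
  expect_error(confidence_level(treated = TRUE,
                                resolved_without_treatment = TRUE),
               class = "gvhd_validation_error")
  expect_error(confidence_level(), class = "gvhd_validation_error")
})

test_that("grade_acute grades a staged table under one or all systems", {
  staged <- stage_acute(tibble::tibble(rash_bsa_pct = 30,
                                       bilirubin_mg_dl = 4,
                                       stool_volume_ml_per_day = 1200))
  one <- grade_acute(staged, system = "magic")
  expect_identical(one$grade, "III")
  staged$karnofsky_pct <- 90
  all_sys <- grade_acute(staged, system = "all")
  expect_setequal(all_sys$system, acute_systems())
})
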