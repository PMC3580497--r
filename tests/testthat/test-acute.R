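test_that("phototaxis scores map to motility classes", {
  # untreated cells swim away from the light; toward-light is sign reversal
  expect_equal(score_phototaxis("toward_light"), "sign_reversed")
  expect_equal(score_phototaxis("no_movement"), "motility_inhibited")
  expect_equal(score_phototaxis("lysed"), "motility_inhibited")
  expect_equal(score_phototaxis("away_from_light"), "normal")
  expect_equal(score_phototaxis("missing"), "missing")
  expect_equal(score_phototaxis(NA), "missing")
  # flipped control direction flips the sign call
  expect_equal(score_phototaxis("toward_light",
                                control_direction = "toward_light"), "normal")
  expect_error(score_phototaxis("sideways"), "unknown")
})

test_that("dual-side imaging reconciles by agreement", {
  expect_equal(score_phototaxis("no_movement", "no_movement"),
               "motility_inhibited")
  expect_equal(score_phototaxis("no_movement", "toward_light"), "missing")
  expect_equal(score_phototaxis(c("toward_light", "away_from_light"),
                                c("toward_light", "away_from_light")),
               c("sign_reversed", "normal"))
})

test_that("photosynthesis scoring is a control-relative ratio", {
  r <- score_photosynthesis(1000, 1000, 1.35)
  expect_equal(r$fluorescence_ratio, 1)
  expect_false(r$photosynthesis_hit)
  expect_true(score_photosynthesis(2000, 1000, 1.5)$photosynthesis_hit)
  r0 <- score_photosynthesis(0, 1000)
  expect_equal(r0$fluorescence_ratio, 0)
  expect_false(r0$photosynthesis_hit)
  expect_error(score_photosynthesis(500, 0), "QC")
})

test_that("cytotoxicity classification follows the regrowth definition", {
  expect_equal(classify_cytotoxicity(TRUE, FALSE), "cytocidal")
  expect_equal(classify_cytotoxicity(TRUE, TRUE), "cytostatic")
  expect_equal(classify_cytotoxicity(FALSE, TRUE), "reversible")
  expect_equal(classify_cytotoxicity(TRUE, NA), "missing")
  # classes partition compounds with regrowth data
  inh <- c(TRUE, TRUE, FALSE, TRUE)
  reg <- c(FALSE, TRUE, TRUE, FALSE)
  cls <- classify_cytotoxicity(inh, reg)
  expect_equal(sum(cls == "cytocidal") + sum(cls == "cytostatic"), sum(inh))
})

test_that("acute summaries satisfy inclusion-exclusion", {
  mk_calls <- function(mot_ids, ps_ids, all_ids) {
    data.frame(
      compound_id = all_ids,
      motility_class = ifelse(all_ids %in% mot_ids, "motility_inhibited",
                              "normal"),
      photosynthesis_hit = all_ids %in% ps_ids,
      stringsAsFactors = FALSE
    )
  }
  ids <- sprintf("C%04d", 1:600)
  s <- summarize_acute(mk_calls(ids[1:10], ids[11:15], ids))
  expect_equal(s$n_unique_acute, 15)
  expect_equal(s$n_both, 0)
  s <- summarize_acute(mk_calls(ids[1:7], ids[1:7], ids))
  expect_equal(s$n_unique_acute, 7)
  expect_equal(s$n_both, 7)
  # the identity holds on random overlaps
  set.seed(9)
  for (i in 1:20) {
    mot <- sample(ids, 40)
    ps <- sample(ids, 60)
    s <- summarize_acute(mk_calls(mot, ps, ids))
    expect_equal(s$n_unique_acute + s$n_both,
                 s$n_motility + s$n_photosynthesis)
  }
  expect_error(
    summarize_acute(mk_calls(ids[1], ids[2], c(ids[1:3], ids[1]))),
    "duplicate")
})

test_that("acute plate calls join layout, controls and fitness", {
  ids <- sprintf("C%d", 1:3)
  plates <- simulate_acute(ids, c("photosynthesis", "motility", "none"),
                           seed = 3, fluorescence_cv = 0)
  fitness <- data.frame(compound_id = ids, is_hit = c(TRUE, TRUE, FALSE))
  calls <- call_acute(plates[[1]]$readouts, plates[[1]]$layout,
                      fitness = fitness)
  expect_equal(calls$compound_id, ids)
  expect_equal(calls$motility_class,
               c("normal", "motility_inhibited", "normal"))
  expect_equal(calls$photosynthesis_hit, c(TRUE, FALSE, FALSE))
  expect_equal(calls$fluorescence_ratio[1], 2, tolerance = 1e-12)
  expect_true(all(calls$cytotoxicity %in%
                    c("cytocidal", "cytostatic", "reversible")))
})

test_that("acute readout files parse with optional columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,fluorescence,phototaxis_score_1,phototaxis_score_2,regrew",
               "A1,1200,no_movement,no_movement,TRUE",
               "A2,900,away_from_light,,"), path)
  df <- read_acute_readouts(path)
  expect_equal(df$fluorescence, c(1200, 900))
  expect_true(is.na(df$phototaxis_score_2[2]))
  expect_true(is.na(df$regrew[2]))
})
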