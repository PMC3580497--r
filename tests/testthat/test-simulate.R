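test_that("noiseless plates hit the no-effect and full-kill limits exactly", {
  # phi = 1 for all compounds, sigma = 0: every growth ratio is exactly 1
  phi1 <- setNames(rep(1, 5), sprintf("C%d", 1:5))
  res <- score_plates(simulate_plate(
    plate_sim_config(phi1, sigma = 0, replicates = 2, seed = 1)))
  expect_equal(res$growth_ratio, rep(1, 5))
  expect_equal(res$replicate_sd, rep(0, 5))
  # phi = 0: flat curve, ratio 0 after baseline subtraction
  phi0 <- c(K0 = 0)
  res0 <- score_plates(simulate_plate(
    plate_sim_config(phi0, sigma = 0, replicates = 1, seed = 1)))
  expect_equal(res0$growth_ratio, 0)
  expect_true(res0$is_hit)
})

test_that("noiseless ratios equal the closed-form function of phi", {
  # fine sampling isolates implementation error from grid bias
  phis <- c(A = 0.25, B = 0.5, C = 0.75)
  cfg <- plate_sim_config(phis, sigma = 0, replicates = 1, interval = 0.1,
                          seed = 1)
  res <- score_plates(simulate_plate(cfg))
  expected <- vapply(phis[res$compound_id], closed_form_ratio, numeric(1))
  expect_equal(res$growth_ratio, unname(expected), tolerance = 1e-6)
})

test_that("noisy triplicates recover the planted ratio within 0.1", {
  phis <- setNames(c(0.5, 0.5, 0.5), c("X", "Y", "Z"))
  cfg <- plate_sim_config(phis, sigma = 0.005, replicates = 3, seed = 42)
  res <- score_plates(simulate_plate(cfg))
  target <- closed_form_ratio(0.5)
  expect_true(all(abs(res$growth_ratio - target) < 0.1))
  expect_true(all(res$n_replicates == 3))
})

test_that("simulated plates are bit-identical under one seed", {
  phis <- setNames(runif(10), sprintf("C%d", 1:10))
  cfg <- plate_sim_config(phis, seed = 7)
  p1 <- simulate_plate(cfg)
  p2 <- simulate_plate(cfg)
  expect_identical(p1, p2)
  p3 <- simulate_plate(plate_sim_config(phis, seed = 8))
  expect_false(identical(p1, p3))
})

test_that("library generation is valid, deterministic and label-calibrated", {
  cfg <- library_sim_config(n_compounds = 2000, seed = 31)
  lib <- generate_library(cfg)
  expect_equal(nrow(lib$compounds), 2000)
  # every assembled SMILES parses
  expect_false(anyNA(canonical_smiles(lib$compounds$smiles)))
  # realized hit rate within 3 binomial SDs of 0.3*0.8 + 0.7*0.1 = 0.31
  expect_lt(abs(mean(lib$labels) - 0.31),
            3 * sqrt(0.31 * 0.69 / 2000) + 3 * 0.005)
  expect_identical(lib, generate_library(cfg))
  # degenerate settings
  null_lib <- generate_library(library_sim_config(n_compounds = 100,
                                                  p0 = 0.5, p1 = 0.5,
                                                  seed = 1))
  expect_equal(length(null_lib$labels), 100)
  det <- generate_library(library_sim_config(n_compounds = 100, p0 = 0,
                                             p1 = 1, seed = 1))
  expect_identical(det$labels, det$has_pharmacophore)
})

test_that("acute simulation plants the requested mechanisms", {
  ids <- sprintf("C%d", 1:6)
  mech <- c("none", "general", "photosynthesis", "motility", "sign_reversal",
            "photosynthesis+motility")
  plates <- simulate_acute(ids, mech, seed = 5, fluorescence_cv = 0,
                           cytocidal_fraction = 0)
  calls <- call_acute(plates[[1]]$readouts, plates[[1]]$layout)
  expect_equal(calls$motility_class,
               c("normal", "normal", "normal", "motility_inhibited",
                 "sign_reversed", "motility_inhibited"))
  expect_equal(calls$photosynthesis_hit,
               c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE))
  # all-general plants no acute hits
  plates_g <- simulate_acute(ids, rep("general", 6), seed = 5)
  calls_g <- call_acute(plates_g[[1]]$readouts, plates_g[[1]]$layout)
  s <- summarize_acute(calls_g)
  expect_equal(s$n_unique_acute, 0)
  # cytocidal fraction 0: no well fails to regrow
  expect_true(all(plates[[1]]$readouts$regrew))
  expect_error(simulate_acute(ids, rep("warp_drive", 6)), "unknown")
})

test_that("the planted overlap accounting flows through the acute pipeline", {
  n <- 600
  ids <- sprintf("C%04d", seq_len(n))
  mech <- rep("none", n)
  mech[1:126] <- "motility"       # motility only
  mech[127:144] <- "photosynthesis+motility" # dual actives
  mech[145:476] <- "photosynthesis" # photosynthesis only
  plates <- simulate_acute(ids, mech, seed = 13)
  calls <- do.call(rbind, lapply(plates, function(p) {
    call_acute(p$readouts, p$layout)
  }))
  s <- summarize_acute(calls)
  expect_equal(s$n_motility, 144)
  expect_equal(s$n_photosynthesis, 350)
  expect_equal(s$n_both, 18)
  expect_equal(s$n_unique_acute, 476)
})
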