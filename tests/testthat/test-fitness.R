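test_that("trapezoid AUC reproduces rectangle and triangle areas", {
  flat <- well_series("P", "A1", seq(0, 10, by = 1), rep(0.1, 11))
  expect_equal(trapezoid_auc(flat, baseline = "raw"), 1.0)
  expect_equal(trapezoid_auc(flat, baseline = "subtract"), 0.0)
  tri <- well_series("P", "A1", c(0, 2), c(0, 1))
  expect_equal(trapezoid_auc(tri), 1.0)
})

test_that("trapezoid AUC matches a per-segment midpoint oracle", {
  # midpoint quadrature is exact on linear pieces, and reaches the result by
  # an independent route (interpolation + midpoint sums)
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(4:30, 1)
    t <- sort(runif(n, 0, 80))
    while (any(diff(t) <= 0)) t <- sort(runif(n, 0, 80))
    od <- runif(n, 0, 2)
    s <- well_series("P", "A1", t, od)
    y <- pmax(od - od[1], 0)
    oracle <- 0
    for (i in seq_len(n - 1)) {
      grid <- seq(t[i], t[i + 1], length.out = 51)
      mids <- (head(grid, -1) + tail(grid, -1)) / 2
      oracle <- oracle +
        sum(diff(grid) * approx(t, y, xout = mids)$y)
    }
    expect_equal(trapezoid_auc(s), oracle, tolerance = 1e-9)
  }
})

test_that("integration windows restrict the integral and are validated", {
  s <- well_series("P", "A1", 0:10, c(0, rep(1, 10)))
  expect_equal(trapezoid_auc(s, window = c(2, 6), baseline = "raw"), 4)
  expect_error(trapezoid_auc(s, window = c(-5, 6)), "outside")
  expect_error(trapezoid_auc(s, window = c(2.1, 2.9)), "fewer than 2")
})

test_that("growth ratios behave as compound/control with QC guard", {
  expect_equal(growth_ratio(6.5, 10), 0.65)
  expect_equal(growth_ratio(0, 10), 0)
  expect_equal(growth_ratio(10, 10), 1)
  expect_error(growth_ratio(5, 0), "QC")
  expect_error(growth_ratio(5, -1), "QC")
})

test_that("hit calling is inclusive at the threshold and monotone", {
  expect_true(call_fitness_hit(0.65))
  expect_false(call_fitness_hit(0.651))
  expect_true(call_fitness_hit(0))
  expect_false(call_fitness_hit(0.65, inclusive = FALSE))
  # monotonicity: every ratio below a hit ratio is also a hit
  r <- sort(runif(100, 0, 2))
  hits <- call_fitness_hit(r)
  expect_true(all(diff(as.integer(hits)) <= 0))
})

test_that("replicate aggregation gives sample statistics and hit on mean", {
  a <- aggregate_replicates(c(0.6, 0.6, 0.6))
  expect_equal(a$mean, 0.6)
  expect_equal(a$sd, 0)
  a <- aggregate_replicates(c(0.5, 0.7, 0.9))
  expect_equal(a$mean, 0.7)
  expect_equal(a$sd, 0.2) # hand-computed sample sd of (0.5, 0.7, 0.9)
  single <- aggregate_replicates(0.4)
  expect_equal(single$n, 1)
  expect_true(is.na(single$sd))
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("screen summaries report rounded hit percentages", {
  res <- data.frame(is_hit = c(rep(TRUE, 1), rep(FALSE, 2)))
  expect_equal(summarize_screen(res)$hit_pct, 33)
  expect_equal(summarize_screen(data.frame(is_hit = rep(FALSE, 100)))$hit_pct, 0)
  expect_error(summarize_screen(data.frame(is_hit = logical(0))), "no compounds")
})

test_that("plate scoring is scale-invariant and flags noisy controls", {
  phi <- c(A = 0.3, B = 0.9)
  cfg <- plate_sim_config(phi, sigma = 0, replicates = 1, seed = 7)
  plates <- simulate_plate(cfg)
  res <- score_plates(plates)
  # multiply every OD on the plate by a constant: ratios unchanged
  scaled <- plates
  scaled[[1]]$series <- lapply(scaled[[1]]$series, function(s) {
    well_series(s$plate_id, s$well, s$times, s$od * 3.7)
  })
  res2 <- score_plates(scaled)
  expect_equal(res2$growth_ratio, res$growth_ratio, tolerance = 1e-12)

  # degrade one control well heavily: QC warning
  noisy <- plates
  ctrl_well <- noisy[[1]]$layout$wells$well[
    noisy[[1]]$layout$wells$role == "solvent_control"][1]
  s <- noisy[[1]]$series[[ctrl_well]]
  noisy[[1]]$series[[ctrl_well]] <- well_series(s$plate_id, s$well, s$times,
                                                s$od * 0.05)
  expect_warning(res3 <- score_plates(noisy), "QC bound")
  expect_equal(attr(res3, "qc_flagged"), plates[[1]]$layout$plate_id)
})

test_that("control wells score ratio 1 against their own plate mean", {
  # a plate whose controls are identical noiseless curves: a compound with
  # phi = 1 is indistinguishable from control, ratio exactly 1
  res <- score_plates(simulate_plate(
    plate_sim_config(c(X = 1), sigma = 0, replicates = 1, seed = 1)))
  expect_equal(res$growth_ratio, 1)
})
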