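test_that("well addresses accept padded and unpadded dialects", {
  expect_equal(canonical_well(c("A1", "a01", "H12", "P24")),
               c("A1", "A1", "H12", "P24"))
  expect_error(canonical_well("Z99"), "malformed")
  expect_error(canonical_well("A0"), "malformed")
})

test_that("layouts validate geometry, uniqueness and control count", {
  expect_s3_class(tiny_layout(), "plate_layout")
  # duplicate address (A1 vs A01 are the same well)
  expect_error(plate_layout("P", data.frame(
    well = c("A1", "A01"), role = "solvent_control")), "duplicate")
  # compound plate with too few controls
  expect_error(tiny_layout(n_compounds = 4, n_controls = 3), "at least 4")
  # 384-only well on a 96-well plate
  expect_error(plate_layout("P", data.frame(
    well = c("P24", "A1", "A2", "A3", "A4"),
    role = "solvent_control"), geometry = 96), "geometry")
  # control-only plates need no minimum
  expect_s3_class(plate_layout("P", data.frame(
    well = "A1", role = "solvent_control")), "plate_layout")
})

test_that("growth tables read shape-preservingly and report absences", {
  layout <- tiny_layout(n_compounds = 4, n_controls = 4)
  times <- seq(0, 4, by = 0.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tiny_growth(path, layout, times, function(i) seq_along(times) * 0.01)
  series <- read_growth_table(path, layout)
  expect_length(series, 8)
  expect_true(all(vapply(series, function(s) length(s$times), 1L) ==
                    length(times)))

  # drop one well from the file -> warning naming it
  lines <- readLines(path)
  writeLines(lines[-2], path) # removes well A1
  expect_warning(series <- read_growth_table(path, layout), "A1")
  expect_length(series, 7)

  # a well not in the layout is rejected
  writeLines(c(lines, sub("^A1", "H12", lines[2])), path)
  expect_error(read_growth_table(path, layout), "H12")
})

test_that("malformed growth tables raise specific errors", {
  layout <- tiny_layout(1, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,t0,t0.5,t0.5,t1", "A1,1,2,3,4"), path)
  expect_error(read_growth_table(path, layout), "strictly increasing")
  writeLines(c("well,t0,t1", "A1,0.1,oops",
               paste0(layout$wells$well[-1], ",0.1,0.2")), path)
  err <- tryCatch(read_growth_table(path, layout), error = conditionMessage)
  expect_match(err, "A1")
  expect_match(err, "t1")
})

test_that("minute headers convert to hours", {
  layout <- tiny_layout(1, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("well,t0,t30,t60",
               paste0(layout$wells$well, ",0.1,0.2,0.3")), path)
  s <- read_growth_table(path, layout, time_unit = "minutes")
  expect_equal(s[["A1"]]$times, c(0, 0.5, 1))
})

test_that("growth tables round-trip at full precision", {
  layout <- tiny_layout(2, 4)
  times <- c(0, 1 / 3, sqrt(2), 2.718281828459045)
  series <- lapply(seq_len(6), function(i) {
    well_series("P1", layout$wells$well[i], times,
                abs(sin(i + seq_along(times))) * pi)
  })
  names(series) <- layout$wells$well
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_table(series, path)
  back <- read_growth_table(path, layout)
  for (w in names(series)) {
    expect_identical(back[[w]]$times, series[[w]]$times)
    expect_identical(back[[w]]$od, series[[w]]$od)
  }
})

test_that("well series enforce their invariants", {
  expect_error(well_series("P", "A1", c(0, 1), c(0.1)), ">= 2")
  expect_error(well_series("P", "A1", c(0, 0), c(0.1, 0.2)), "increasing")
  expect_error(well_series("P", "A1", c(0, 1), c(0.1, -0.2)), "finite")
})

test_that("compound libraries read from CSV and SMILES files", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles", "C1,CCO", "C2,not_a_molecule",
               "C3,c1ccccc1", "C4,CC(C)O"), csv)
  expect_warning(lib <- read_compound_library(csv), "C2")
  expect_equal(nrow(lib), 3)
  expect_equal(attr(lib, "rejected"), "C2")
  expect_equal(lib$screen_dose_uM, rep(25, 3))

  smi <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tC1", "c1ccccc1\tC2"), smi)
  lib2 <- read_compound_library(smi)
  expect_equal(lib2$compound_id, c("C1", "C2"))

  writeLines(c("compound_id,smiles", "C1,CCO", "C1,CCO"), csv)
  expect_error(read_compound_library(csv), "duplicate")
})
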