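#!/usr/bin/env Rscript
# Stage 2: score the growth plates against in-plate controls.
#
# Reads the plate layouts and growth tables written by 01_simulate.R, computes
# baseline-subtracted AUCs, forms per-well growth ratios against each plate's
# solvent-control mean, aggregates triplicates, and calls fitness hits at a
# growth ratio of 0.65 or less (35% inhibition).

suppressMessages(library(algscreen))

out <- "results/campaign"
plate_files <- list.files(file.path(out, "plates"), pattern = "_layout\\.csv$",
                          full.names = TRUE)
plates <- lapply(plate_files, function(lf) {
  pid <- sub("_layout\\.csv$", "", basename(lf))
  layout <- read_layout(lf, plate_id = pid)
  series <- read_growth_table(sub("_layout", "", lf), layout)
  list(layout = layout, series = series)
})
message("loaded ", length(plates), " plates")

fit <- score_plates(plates, threshold = 0.65)
write_fitness_results(fit, file.path(out, "fitness_results.csv"))
s <- summarize_screen(fit)
jsonlite::write_json(s, file.path(out, "screen_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf("%d compounds screened, %d fitness hits (%.0f%%)",
                s$n_screened, s$n_hits, s$hit_pct))

truth <- read.csv(file.path(out, "truth.csv"))
agree <- mean(fit$is_hit == truth$true_active[match(fit$compound_id,
                                                    truth$compound_id)])
message(sprintf("agreement with planted truth: %.1f%%", 100 * agree))
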