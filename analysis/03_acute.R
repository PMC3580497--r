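#!/usr/bin/env Rscript
# Stage 3: acute phenotype screens (phototaxis, fluorescence induction,
# regrowth).
#
# Plants acute mechanisms among the screened compounds' true actives,
# simulates readout plates, calls motility/photosynthesis phenotypes and
# cytotoxicity, and reports the overlap accounting between the acute and
# fitness screens.

suppressMessages(library(algscreen))

out <- "results/campaign"
seed <- 20121118
truth <- read.csv(file.path(out, "truth.csv"))
fitness <- read.csv(file.path(out, "fitness_results.csv"))
screened <- truth[truth$compound_id %in% fitness$compound_id, ]

set.seed(seed + 3)
mech <- rep("none", nrow(screened))
act <- which(screened$true_active)
u <- runif(length(act))
mech[act] <- ifelse(u < 0.15, "photosynthesis",
             ifelse(u < 0.21, "motility",
             ifelse(u < 0.24, "sign_reversal",
             ifelse(u < 0.27, "photosynthesis+motility", "general"))))

plates <- simulate_acute(screened$compound_id, mech, seed = seed + 4)
calls <- do.call(rbind, lapply(plates, function(p) {
  call_acute(p$readouts, p$layout, hit_ratio_threshold = 1.35,
             fitness = fitness)
}))
write.csv(calls, file.path(out, "acute_calls.csv"), row.names = FALSE)

s <- summarize_acute(calls, fitness)
jsonlite::write_json(s, file.path(out, "acute_summary.json"),
                     auto_unbox = TRUE, digits = NA)
message(sprintf(
  "acute actives: %d motility/phototaxis, %d photosynthesis, %d in both -> %d unique; %d also fitness hits",
  s$n_motility, s$n_photosynthesis, s$n_both, s$n_unique_acute,
  s$n_also_fitness))
cyt <- table(calls$cytotoxicity)
message("cytotoxicity calls: ",
        paste(names(cyt), cyt, sep = "=", collapse = ", "))
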