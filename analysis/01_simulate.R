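#!/usr/bin/env Rscript
# Stage 1: generate the synthetic screening campaign.
#
# Produces a 2,000-compound SMILES library with a planted structure-activity
# relationship (expected hit rate 0.31) and, for a 300-compound subset kept
# small enough to grow on a handful of plates, triplicate 96-well growth
# plates with planted inhibition tied to the true labels. Everything is
# seeded, so downstream stages are reproducible.

suppressMessages(library(algscreen))

out <- "results/campaign"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20121118

lib <- generate_library(library_sim_config(n_compounds = 2000, seed = seed))
write_smiles_file(lib$compounds, file.path(out, "library.smi"))
write.csv(data.frame(compound_id = lib$compounds$compound_id,
                     true_active = lib$labels,
                     has_pharmacophore = lib$has_pharmacophore),
          file.path(out, "truth.csv"), row.names = FALSE)
message(sprintf("library: %d compounds, %.1f%% active (planted)",
                nrow(lib$compounds), 100 * mean(lib$labels)))

# growth plates for the first 300 compounds: actives get strong inhibition
# (phi 0.15-0.55), inactives mild-to-none (phi 0.8-1.0)
screened <- 1:300
rng_seed <- seed + 1
set.seed(rng_seed)
phi <- ifelse(lib$labels[screened], runif(300, 0.15, 0.55),
              runif(300, 0.8, 1.0))
names(phi) <- lib$compounds$compound_id[screened]
plates <- simulate_plate(plate_sim_config(phi, sigma = 0.005,
                                          replicates = 3, seed = seed + 2))
dir.create(file.path(out, "plates"), showWarnings = FALSE)
for (p in plates) {
  pid <- p$layout$plate_id
  write.csv(p$layout$wells, file.path(out, "plates", paste0(pid, "_layout.csv")),
            row.names = FALSE)
  write_growth_table(p$series, file.path(out, "plates", paste0(pid, ".csv")))
}
message(sprintf("wrote %d plates (%d compounds x 3 replicates) under %s",
                length(plates), length(phi), file.path(out, "plates")))
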