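#!/usr/bin/env Rscript
# Stage 6: prospective ranking of an unscreened library.
#
# Generates a fresh 5,000-compound library from the same chemistry, ranks it
# with the trained model, and measures the realized enrichment of the top 10%
# against the library's planted truth - the synthetic analogue of
# prioritizing a vendor collection before buying plates.

suppressMessages(library(algscreen))

out <- "results/campaign"
seed <- 20121118
model <- read_bayes_model(file.path(out, "model.json"))

ulib <- generate_library(library_sim_config(n_compounds = 5000,
                                            library_name = "unscreened",
                                            seed = seed + 7))
write_smiles_file(ulib$compounds, file.path(out, "unscreened.smi"))
message("fingerprinting ", nrow(ulib$compounds), " unscreened compounds")
ufps <- compute_fingerprints(ulib$compounds$smiles,
                             ulib$compounds$compound_id)

ranked <- rank_library(model, ufps)
ranked$true_active <- ulib$labels[match(ranked$compound_id,
                                        ulib$compounds$compound_id)]
write.csv(ranked, file.path(out, "ranked_unscreened.csv"), row.names = FALSE)

ef <- enrichment_factor(ranked$true_active, 0.10)
curve <- enrichment_curve(ranked$true_active)
write.csv(curve, file.path(out, "enrichment_curve.csv"), row.names = FALSE)
top <- ceiling(0.10 * nrow(ranked))
message(sprintf(
  "top %d of %d ranked compounds contain %d actives (library rate %.1f%%): EF@10%% = %.2f",
  top, nrow(ranked), sum(ranked$true_active[1:top]),
  100 * mean(ranked$true_active), ef))
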