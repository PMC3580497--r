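#!/usr/bin/env Rscript
# Stage 4: chemical similarity network of the active compounds.
#
# Fingerprints every screened active (fitness or acute), connects pairs with
# Tanimoto similarity strictly above 0.5, maps phenotypes onto node color
# (white fitness-only, red photosynthesis, blue motility/phototaxis, green
# both) and shape (circle = fitness hit, diamond = not), and exports SIF,
# GraphML and a per-component phenotype summary.

suppressMessages(library(algscreen))

out <- "results/campaign"
lib <- read_compound_library(file.path(out, "library.smi"), validate = FALSE)
fitness <- read.csv(file.path(out, "fitness_results.csv"))
acute <- read.csv(file.path(out, "acute_calls.csv"))

active_ids <- union(
  fitness$compound_id[fitness$is_hit],
  acute$compound_id[acute$photosynthesis_hit |
                      acute$motility_class %in% c("motility_inhibited",
                                                  "sign_reversed")])
actives <- lib[lib$compound_id %in% active_ids, ]
message("fingerprinting ", nrow(actives), " active compounds")
fps <- compute_fingerprints(actives$smiles, actives$compound_id)

net <- build_network(fps, cutoff = 0.5)
net <- annotate_network(net, fitness, acute)
write_network_sif(net, file.path(out, "network.sif"),
                  file.path(out, "network_attributes.csv"))
write_network_graphml(net, file.path(out, "network.graphml"))
cs <- cluster_summary(net)
write.csv(cs, file.path(out, "cluster_summary.csv"), row.names = FALSE)

n_conn <- sum(cs$size[cs$size > 1])
message(sprintf(
  "network: %d nodes, %d edges; %d compounds cluster together in %d multi-compound components",
  igraph::vcount(net), igraph::ecount(net), n_conn, sum(cs$size > 1)))
print(head(cs, 5))
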