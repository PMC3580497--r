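# End-to-end orchestration of a synthetic screening campaign:
# simulate -> fitness -> acute -> network -> train -> evaluate -> rank.
# Every stage writes its outputs under the run directory; a stage is skipped
# on rerun when its configuration (and its upstream stages') is unchanged,
# tracked by content hashes in stage_state.json. All outputs are plain text
# and carry no timestamps, so identical configurations reproduce
# byte-identical run directories.

#' Default pipeline configuration
#'
#' Sizes are chosen so a full run completes in a couple of minutes on one
#' CPU: a 300-compound screened library on triplicate 96-well plates, and a
#' 300-compound unscreened library for prospective ranking. Thresholds are
#' the screen's operating points: growth-ratio hit threshold 0.65, network
#' similarity cutoff 0.5, enrichment measured at the top 10% under 5-fold
#' stratified holdout.
#'
#' @param seed master seed; stage seeds are derived from it
#' @param n_compounds screened-library size
#' @param n_unscreened unscreened-library size for the ranking stage
#' @param threshold fitness hit threshold on the growth ratio
#' @param cutoff similarity-network edge cutoff
#' @param fraction enrichment-factor screening fraction
#' @param k cross-validation folds
#' @param photosynthesis_threshold fluorescence-ratio hit threshold
#' @param p0,p1,prevalence planted-SAR parameters, see [library_sim_config()]
#' @param sigma growth-curve measurement noise SD (OD units)
#' @param replicates replicate plates per compound
#' @return list of class `run_config`
#' @export
run_config <- function(seed = 20121118, n_compounds = 300,
                       n_unscreened = 300, threshold = 0.65, cutoff = 0.5,
                       fraction = 0.10, k = 5,
                       photosynthesis_threshold = 1.35, p0 = 0.1, p1 = 0.8,
                       prevalence = 0.3, sigma = 0.005, replicates = 3) {
  stopifnot(threshold > 0, threshold < 1, cutoff >= 0, cutoff <= 1,
            fraction > 0, fraction <= 1, k >= 2)
  structure(as.list(environment()), class = "run_config")
}

stage_seed <- function(cfg, offset) (cfg$seed + offset) %% 2147483647L

read_stage_state <- function(dir) {
  f <- file.path(dir, "stage_state.json")
  if (file.exists(f)) jsonlite::read_json(f, simplifyVector = TRUE) else list()
}

write_stage_state <- function(dir, state) {
  jsonlite::write_json(state, file.path(dir, "stage_state.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full screening-analysis pipeline
#'
#' Executes the stages in dependency order under `out_dir`. On rerun with an
#' unchanged configuration, stages whose inputs are unchanged are skipped
#' (content-hash based) and the outputs are byte-identical. Any stage error
#' aborts with the stage name in the message.
#'
#' @param cfg a [run_config()]
#' @param out_dir run directory (created if needed)
#' @param quiet suppress progress messages
#' @return invisibly, a list with the main per-stage results and
#'   `skipped` (stages reused from the previous run)
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- read_stage_state(out_dir)
  new_state <- list()
  skipped <- character(0)
  say <- function(...) if (!quiet) message("[algscreen] ", ...)
  run_stage <- function(name, hash_input, outputs, compute) {
    h <- as.character(config_hash(hash_input))
    outputs_exist <- all(file.exists(file.path(out_dir, outputs)))
    if (identical(state[[name]], h) && outputs_exist) {
      say("stage ", name, ": unchanged, skipped")
      skipped <<- c(skipped, name)
    } else {
      say("stage ", name, ": running")
      tryCatch(compute(), error = function(e) {
        stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
      })
    }
    new_state[[name]] <<- h
    h
  }

  res <- list()

  # -- simulate ---------------------------------------------------------
  lib_cfg <- library_sim_config(n_compounds = cfg$n_compounds, p0 = cfg$p0,
                                p1 = cfg$p1, prevalence = cfg$prevalence,
                                seed = stage_seed(cfg, 1))
  h_sim <- run_stage("simulate", list(lib_cfg = unclass(lib_cfg),
                                      sigma = cfg$sigma,
                                      replicates = cfg$replicates),
                     c("library.smi", "truth.csv"), function() {
    lib <- generate_library(lib_cfg)
    write_smiles_file(lib$compounds, file.path(out_dir, "library.smi"))
    utils::write.csv(
      data.frame(compound_id = lib$compounds$compound_id,
                 true_active = lib$labels,
                 has_pharmacophore = lib$has_pharmacophore),
      file.path(out_dir, "truth.csv"), row.names = FALSE)
  })
  truth <- utils::read.csv(file.path(out_dir, "truth.csv"),
                           stringsAsFactors = FALSE)
  res$library <- utils::read.delim(
    file.path(out_dir, "library.smi"), header = FALSE,
    col.names = c("smiles", "compound_id"), stringsAsFactors = FALSE)

  # -- fitness ----------------------------------------------------------
  run_stage("fitness", list(h_sim, threshold = cfg$threshold,
                            sigma = cfg$sigma, replicates = cfg$replicates,
                            seed = stage_seed(cfg, 2)),
            c("fitness_results.csv", "screen_summary.json"), function() {
    rng <- local_rng(stage_seed(cfg, 2))
    phi <- ifelse(truth$true_active,
                  0.15 + 0.4 * rng$runif(nrow(truth)),
                  0.8 + 0.2 * rng$runif(nrow(truth)))
    names(phi) <- truth$compound_id
    plates <- simulate_plate(plate_sim_config(
      phi, sigma = cfg$sigma, replicates = cfg$replicates,
      seed = stage_seed(cfg, 3)))
    fit <- score_plates(plates, threshold = cfg$threshold)
    write_fitness_results(fit, file.path(out_dir, "fitness_results.csv"))
    jsonlite::write_json(summarize_screen(fit),
                         file.path(out_dir, "screen_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  fitness <- utils::read.csv(file.path(out_dir, "fitness_results.csv"),
                             stringsAsFactors = FALSE)
  class(fitness) <- c("fitness_result", "data.frame")
  h_fit <- new_state$fitness

  # -- acute ------------------------------------------------------------
  run_stage("acute", list(h_fit,
                          ps_thr = cfg$photosynthesis_threshold,
                          seed = stage_seed(cfg, 4)),
            c("acute_calls.csv", "acute_summary.json"), function() {
    rng <- local_rng(stage_seed(cfg, 4))
    mech <- rep("none", nrow(truth))
    act <- which(truth$true_active)
    # planted mechanism mix among true actives: mostly growth-only, with
    # photosynthesis the commonest acute class, as in real screens
    u <- rng$runif(length(act))
    mech[act] <- ifelse(u < 0.15, "photosynthesis",
                 ifelse(u < 0.21, "motility",
                 ifelse(u < 0.24, "sign_reversal",
                 ifelse(u < 0.27, "photosynthesis+motility", "general"))))
    plates <- simulate_acute(truth$compound_id, mech,
                             seed = stage_seed(cfg, 5))
    calls <- do.call(rbind, lapply(plates, function(p) {
      call_acute(p$readouts, p$layout,
                 hit_ratio_threshold = cfg$photosynthesis_threshold,
                 fitness = fitness)
    }))
    utils::write.csv(calls, file.path(out_dir, "acute_calls.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summarize_acute(calls, fitness),
                         file.path(out_dir, "acute_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })
  acute <- utils::read.csv(file.path(out_dir, "acute_calls.csv"),
                           stringsAsFactors = FALSE)
  h_acu <- new_state$acute

  # -- fingerprints + network ------------------------------------------
  fps <- compute_fingerprints(res$library$smiles, res$library$compound_id)
  run_stage("network", list(h_acu, cutoff = cfg$cutoff),
            c("network.sif", "network_attributes.csv", "network.graphml",
              "cluster_summary.csv"), function() {
    active_ids <- union(fitness$compound_id[fitness$is_hit],
                        acute$compound_id[
                          acute$photosynthesis_hit |
                          acute$motility_class %in%
                            c("motility_inhibited", "sign_reversed")])
    net <- build_network(fps[names(fps) %in% active_ids],
                         cutoff = cfg$cutoff)
    net <- annotate_network(net, fitness, acute)
    write_network_sif(net, file.path(out_dir, "network.sif"),
                      file.path(out_dir, "network_attributes.csv"))
    write_network_graphml(net, file.path(out_dir, "network.graphml"))
    utils::write.csv(cluster_summary(net),
                     file.path(out_dir, "cluster_summary.csv"),
                     row.names = FALSE)
  })
  h_net <- new_state$network

  # -- train ------------------------------------------------------------
  run_stage("train", list(h_fit), "model.json", function() {
    labels <- fitness$is_hit[match(names(fps), fitness$compound_id)]
    model <- nb_train(fps, labels)
    write_bayes_model(model, file.path(out_dir, "model.json"))
  })
  model <- read_bayes_model(file.path(out_dir, "model.json"))
  h_train <- new_state$train

  # -- evaluate ---------------------------------------------------------
  run_stage("evaluate", list(h_train, k = cfg$k, fraction = cfg$fraction,
                             seed = stage_seed(cfg, 6)),
            c("crossval_folds.csv", "crossval_summary.json"), function() {
    labels <- fitness$is_hit[match(names(fps), fitness$compound_id)]
    cv <- evaluate_model(fps, labels, k = cfg$k, fraction = cfg$fraction,
                         seed = stage_seed(cfg, 6))
    utils::write.csv(
      data.frame(fold = seq_len(cv$k), ef = cv$fold_ef),
      file.path(out_dir, "crossval_folds.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(mean_ef = cv$mean_ef, se = cv$se, k = cv$k,
           fraction = cv$fraction, seed = cv$seed,
           stratified = cv$stratified, top_cut = cv$top_cut),
      file.path(out_dir, "crossval_summary.json"),
      auto_unbox = TRUE, digits = NA)
  })
  h_eval <- new_state$evaluate

  # -- rank an unscreened library --------------------------------------
  run_stage("rank", list(h_train, n_unscreened = cfg$n_unscreened,
                         seed = stage_seed(cfg, 7)),
            c("unscreened.smi", "ranked.csv"), function() {
    ulib <- generate_library(library_sim_config(
      n_compounds = cfg$n_unscreened, p0 = cfg$p0, p1 = cfg$p1,
      prevalence = cfg$prevalence, library_name = "unscreened",
      seed = stage_seed(cfg, 7)))
    write_smiles_file(ulib$compounds, file.path(out_dir, "unscreened.smi"))
    ufps <- compute_fingerprints(ulib$compounds$smiles,
                                 ulib$compounds$compound_id)
    ranked <- rank_library(model, ufps)
    ranked$true_active <- ulib$labels[match(ranked$compound_id,
                                            ulib$compounds$compound_id)]
    utils::write.csv(ranked, file.path(out_dir, "ranked.csv"),
                     row.names = FALSE)
  })

  # -- summary report and run metadata ---------------------------------
  screen <- jsonlite::read_json(file.path(out_dir, "screen_summary.json"),
                                simplifyVector = TRUE)
  acute_sum <- jsonlite::read_json(file.path(out_dir, "acute_summary.json"),
                                   simplifyVector = TRUE)
  cvs <- jsonlite::read_json(file.path(out_dir, "crossval_summary.json"),
                             simplifyVector = TRUE)
  ranked <- utils::read.csv(file.path(out_dir, "ranked.csv"),
                            stringsAsFactors = FALSE)
  clusters <- utils::read.csv(file.path(out_dir, "cluster_summary.csv"),
                              stringsAsFactors = FALSE)
  ef_unscreened <- enrichment_factor(ranked$true_active, cfg$fraction)
  report <- c(
    "algscreen pipeline summary",
    "==========================",
    "",
    "[simulate]",
    sprintf("  screened library: %d compounds; unscreened: %d",
            cfg$n_compounds, cfg$n_unscreened),
    "",
    "[fitness]",
    sprintf("  %d screened, %d hits (%.0f%%) at growth ratio <= %.2f",
            screen$n_screened, screen$n_hits, screen$hit_pct, cfg$threshold),
    "",
    "[acute]",
    sprintf("  motility/phototaxis %d, photosynthesis %d, both %d, unique %d",
            acute_sum$n_motility, acute_sum$n_photosynthesis,
            acute_sum$n_both, acute_sum$n_unique_acute),
    sprintf("  acute actives also fitness hits: %d", acute_sum$n_also_fitness),
    "",
    "[network]",
    sprintf("  %d components over the active set (largest %d nodes)",
            nrow(clusters), if (nrow(clusters)) max(clusters$size) else 0L),
    "",
    "[model]",
    sprintf("  naive Bayes on %d features, base rate %.3f",
            length(model$feature_id), model$base_rate),
    "",
    "[evaluate]",
    sprintf("  %d-fold EF@%.0f%%: mean %.2f (SE %.2f)",
            cvs$k, 100 * cvs$fraction, cvs$mean_ef, cvs$se),
    "",
    "[rank]",
    sprintf("  unscreened library EF@%.0f%% against planted truth: %.2f",
            100 * cfg$fraction, ef_unscreened)
  )
  writeLines(report, file.path(out_dir, "summary.txt"))
  jsonlite::write_json(
    list(config = unclass(cfg), config_hash = config_hash(unclass(cfg)),
         package_version = as.character(utils::packageVersion("algscreen"))),
    file.path(out_dir, "run_metadata.json"), auto_unbox = TRUE, digits = NA)
  write_stage_state(out_dir, new_state)
  say("run complete: ", out_dir)
  invisible(list(fitness = fitness, acute = acute, screen = screen,
                 acute_summary = acute_sum, crossval = cvs,
                 ef_unscreened = ef_unscreened, skipped = skipped))
}
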