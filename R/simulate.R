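# Synthetic screening campaigns: logistic growth plates with planted
# inhibition, SMILES libraries with a planted structure-activity
# relationship, and acute-assay readouts with planted mechanisms. These
# generators define the study conditions every pipeline stage is tested
# under; all draw their randomness from a seeded generator scoped to the
# call, so outputs are bit-identical for identical seeds.

#' Logistic growth curve
#'
#' `OD(t) = OD0 + K / (1 + exp(-r (t - t_m)))`: a saturating sigmoid over a
#' constant inoculum baseline.
#'
#' @param t times (hours)
#' @param od0 inoculum optical density
#' @param K carrying-capacity increment (OD units)
#' @param r growth rate (per hour)
#' @param tm curve midpoint (hours)
#' @return optical densities
#' @export
logistic_od <- function(t, od0 = 0.1, K = 0.9, r = 0.15, tm = 30) {
  od0 + K / (1 + exp(-r * (t - tm)))
}

#' Configuration for simulated growth plates
#'
#' Defaults emulate an 80-hour microtiter fitness assay read every 30
#' minutes: logistic growth from a 0.1 OD inoculum to saturation near 1.0 OD
#' with midpoint at 30 h, triplicate plates, and 8 in-plate solvent-control
#' wells. Compound inhibition is a fractional carrying-capacity multiplier
#' `phi` in `[0, 1]`; an inhibited well grows to `K * phi` at rate
#' `r * (0.5 + 0.5 phi)`, so partial inhibitors change curve shape as well as
#' plateau.
#'
#' @param inhibition named numeric vector: compound_id -> phi in `[0, 1]`
#' @param geometry 96 or 384
#' @param n_controls solvent-control wells per plate (>= 4)
#' @param od0,K,r,tm logistic parameters, see [logistic_od()]
#' @param sigma measurement noise SD (OD units)
#' @param interval sampling interval (hours)
#' @param duration assay length (hours)
#' @param replicates number of replicate plates
#' @param dose_uM screening dose recorded in the layout
#' @param seed integer seed
#' @return list of class `plate_sim_config`
#' @export
plate_sim_config <- function(inhibition, geometry = 96, n_controls = 8,
                             od0 = 0.1, K = 0.9, r = 0.15, tm = 30,
                             sigma = 0.005, interval = 0.5, duration = 80,
                             replicates = 3, dose_uM = 25, seed = 1) {
  stopifnot(all(inhibition >= 0 & inhibition <= 1), sigma >= 0,
            duration / interval >= 2, n_controls >= 4)
  if (is.null(names(inhibition))) {
    names(inhibition) <- sprintf("CPD%04d", seq_along(inhibition))
  }
  structure(list(inhibition = inhibition, geometry = geometry,
                 n_controls = n_controls, od0 = od0, K = K, r = r, tm = tm,
                 sigma = sigma, interval = interval, duration = duration,
                 replicates = replicates, dose_uM = dose_uM,
                 seed = as.integer(seed)),
            class = "plate_sim_config")
}

#' Simulate replicate growth plates with planted inhibition
#'
#' Compounds fill plates in row-major order; each plate reserves
#' `n_controls` solvent-control wells (the trailing wells of the plate).
#' Compound wells follow the inhibited logistic of their planted `phi`;
#' controls follow the uninhibited curve. Gaussian measurement noise is added
#' and floored so OD stays non-negative.
#'
#' @param cfg a `plate_sim_config`
#' @return list of plates, each a list with `layout` (`plate_layout`) and
#'   `series` (named list of `well_series`); replicate plates carry plate ids
#'   `simplate<p>_r<rep>`
#' @export
simulate_plate <- function(cfg) {
  stopifnot(inherits(cfg, "plate_sim_config"))
  wells_all <- plate_wells(cfg$geometry)
  per_plate <- length(wells_all) - cfg$n_controls
  ids <- names(cfg$inhibition)
  n_plates <- ceiling(length(ids) / per_plate)
  times <- seq(0, cfg$duration, by = cfg$interval)
  rng <- local_rng(cfg$seed)
  curve <- function(phi) {
    cfg$od0 + (cfg$K * phi) /
      (1 + exp(-(cfg$r * (0.5 + 0.5 * phi)) * (times - cfg$tm)))
  }
  plates <- list()
  for (p in seq_len(n_plates)) {
    plate_ids <- ids[((p - 1) * per_plate + 1):min(p * per_plate, length(ids))]
    n_cpd <- length(plate_ids)
    roles <- data.frame(
      well = wells_all[seq_len(n_cpd + cfg$n_controls)],
      role = c(rep("compound", n_cpd),
               rep("solvent_control", cfg$n_controls)),
      compound_id = c(plate_ids, rep(NA_character_, cfg$n_controls)),
      dose_uM = c(rep(cfg$dose_uM, n_cpd), rep(NA_real_, cfg$n_controls)),
      stringsAsFactors = FALSE
    )
    for (rep_i in seq_len(cfg$replicates)) {
      pid <- sprintf("simplate%d_r%d", p, rep_i)
      layout <- plate_layout(pid, roles, geometry = cfg$geometry)
      phis <- c(cfg$inhibition[plate_ids], rep(1, cfg$n_controls))
      series <- vector("list", length(phis))
      for (w in seq_along(phis)) {
        od <- curve(phis[w])
        if (cfg$sigma > 0) {
          od <- pmax(od + rng$rnorm(length(times), 0, cfg$sigma), 0)
        }
        series[[w]] <- well_series(pid, roles$well[w], times, od)
      }
      names(series) <- roles$well
      plates[[length(plates) + 1L]] <- list(layout = layout, series = series)
    }
  }
  plates
}

# Fragment grammar for chemically valid synthetic libraries. Every fragment
# ends in an atom with free valence, so fragments chain by plain SMILES
# concatenation; terminals and pharmacophores close the chain.
SIM_SCAFFOLDS <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1", "C1CCNCC1",
                   "c1ccc2ccccc2c1", "c1ccsc1", "C1CCOCC1", "CC(C)C")
SIM_LINKERS <- c("CC", "CCC", "CN", "CCN", "CO", "CCO", "C(=O)N", "C(=O)O",
                 "CS", "C(C)C")
SIM_TERMINALS <- c("C", "O", "N", "Cl", "F", "Br", "C#N", "C(F)(F)F", "C(C)C",
                   "OC")
SIM_PHARMACOPHORES <- c("CS(=O)(=O)Nc1ccc(Cl)cc1", "C(=O)Nc1ccc(F)cc1F")

#' Configuration for synthetic SMILES libraries with a planted SAR
#'
#' Compounds are assembled from a fragment grammar (random scaffold, up to
#' two linkers, a closing terminal); a planted "pharmacophore" fragment is
#' attached to a `prevalence` fraction of compounds, and activity is drawn
#' Bernoulli(`p1`) for pharmacophore carriers versus Bernoulli(`p0`)
#' otherwise. With the defaults the expected hit rate is
#' 0.3 x 0.8 + 0.7 x 0.1 = 0.31.
#'
#' @param n_compounds library size (default 2000)
#' @param p0 activity probability without the pharmacophore (default 0.1)
#' @param p1 activity probability with it (default 0.8)
#' @param prevalence fraction of compounds carrying a pharmacophore fragment
#'   (default 0.3)
#' @param pharmacophores SMILES fragments implementing the planted SAR
#' @param library_name library label
#' @param seed integer seed
#' @return list of class `library_sim_config`
#' @export
library_sim_config <- function(n_compounds = 2000, p0 = 0.1, p1 = 0.8,
                               prevalence = 0.3,
                               pharmacophores = SIM_PHARMACOPHORES,
                               library_name = "synthetic", seed = 1) {
  stopifnot(p0 >= 0, p1 <= 1, p0 <= p1, prevalence >= 0, prevalence <= 1)
  structure(list(n_compounds = n_compounds, p0 = p0, p1 = p1,
                 prevalence = prevalence, pharmacophores = pharmacophores,
                 library_name = library_name, seed = as.integer(seed)),
            class = "library_sim_config")
}

#' Generate a synthetic compound library with planted activity
#'
#' @param cfg a `library_sim_config`
#' @param validate check every assembled SMILES parses; failed assemblies are
#'   resampled and counted (attribute `n_resampled`)
#' @return list with `compounds` (data.frame: compound_id, smiles, library,
#'   screen_dose_uM), `labels` (logical true-activity vector) and
#'   `has_pharmacophore` (logical)
#' @export
generate_library <- function(cfg, validate = TRUE) {
  stopifnot(inherits(cfg, "library_sim_config"))
  n <- cfg$n_compounds
  rng <- local_rng(cfg$seed)
  assemble <- function() {
    smi <- SIM_SCAFFOLDS[rng$sample(length(SIM_SCAFFOLDS), 1)]
    for (k in seq_len(rng$sample(3, 1) - 1)) { # 0..2 linkers
      smi <- paste0(smi, SIM_LINKERS[rng$sample(length(SIM_LINKERS), 1)])
    }
    smi
  }
  has_pharm <- rng$runif(n) < cfg$prevalence
  smiles <- character(n)
  for (i in seq_len(n)) {
    tail_frag <- if (has_pharm[i]) {
      cfg$pharmacophores[rng$sample(length(cfg$pharmacophores), 1)]
    } else {
      SIM_TERMINALS[rng$sample(length(SIM_TERMINALS), 1)]
    }
    smiles[i] <- paste0(assemble(), tail_frag)
  }
  n_resampled <- 0L
  if (validate) {
    bad <- is.na(canonical_smiles(smiles))
    while (any(bad)) {
      n_resampled <- n_resampled + sum(bad)
      for (i in which(bad)) {
        tail_frag <- if (has_pharm[i]) {
          cfg$pharmacophores[rng$sample(length(cfg$pharmacophores), 1)]
        } else {
          SIM_TERMINALS[rng$sample(length(SIM_TERMINALS), 1)]
        }
        smiles[i] <- paste0(assemble(), tail_frag)
      }
      bad <- is.na(canonical_smiles(smiles))
    }
  }
  labels <- rng$runif(n) < ifelse(has_pharm, cfg$p1, cfg$p0)
  compounds <- data.frame(
    compound_id = sprintf("SYN%05d", seq_len(n)),
    smiles = smiles,
    library = cfg$library_name,
    screen_dose_uM = 25,
    stringsAsFactors = FALSE
  )
  out <- list(compounds = compounds, labels = labels,
              has_pharmacophore = has_pharm)
  attr(out, "n_resampled") <- n_resampled
  out
}

#' Simulate acute-assay readout plates with planted mechanisms
#'
#' Each compound is assigned a mechanism: `"none"` (inactive in the acute
#' assays), `"general"` (a growth inhibitor with no acute phenotype),
#' `"photosynthesis"` (elevated chlorophyll fluorescence),
#' `"motility"` (no movement in the phototaxis assay), `"sign_reversal"`
#' (movement toward the light, opposite of untreated cells), or combinations
#' joined with `+` (e.g. `"photosynthesis+motility"`). Regrowth after
#' pinning is drawn per the planted cytocidal fraction for compounds with
#' any activity; inactive wells always regrow.
#'
#' @param compound_ids compound identifiers
#' @param mechanism character vector of mechanisms, aligned with
#'   `compound_ids`
#' @param seed integer seed
#' @param geometry plate geometry (default 96)
#' @param n_controls solvent-control wells per plate (default 8)
#' @param control_fluorescence mean control fluorescence (a.u.)
#' @param fluorescence_cv multiplicative noise CV on fluorescence
#' @param planted_fluor_ratio fluorescence elevation of photosynthesis
#'   inhibitors relative to control (default 2)
#' @param cytocidal_fraction probability an active compound's well fails to
#'   regrow (default 0.25)
#' @return list of plates, each with `layout` and `readouts` (a data.frame
#'   consumable by [call_acute()])
#' @export
simulate_acute <- function(compound_ids, mechanism, seed = 1, geometry = 96,
                           n_controls = 8, control_fluorescence = 1000,
                           fluorescence_cv = 0.05, planted_fluor_ratio = 2,
                           cytocidal_fraction = 0.25) {
  stopifnot(length(compound_ids) == length(mechanism))
  known <- c("none", "general", "photosynthesis", "motility", "sign_reversal")
  mech_parts <- strsplit(mechanism, "+", fixed = TRUE)
  if (!all(unlist(mech_parts) %in% known)) {
    stop("unknown mechanism(s): ",
         paste(setdiff(unique(unlist(mech_parts)), known), collapse = ", "))
  }
  rng <- local_rng(seed)
  wells_all <- plate_wells(geometry)
  per_plate <- length(wells_all) - n_controls
  n <- length(compound_ids)
  plates <- list()
  for (p in seq_len(ceiling(n / per_plate))) {
    idx <- ((p - 1) * per_plate + 1):min(p * per_plate, n)
    n_cpd <- length(idx)
    pid <- sprintf("acuteplate%d", p)
    roles <- data.frame(
      well = wells_all[seq_len(n_cpd + n_controls)],
      role = c(rep("compound", n_cpd), rep("solvent_control", n_controls)),
      compound_id = c(compound_ids[idx], rep(NA_character_, n_controls)),
      dose_uM = c(rep(25, n_cpd), rep(NA_real_, n_controls)),
      stringsAsFactors = FALSE
    )
    layout <- plate_layout(pid, roles, geometry = geometry)
    parts <- mech_parts[idx]
    is_ps <- vapply(parts, function(m) "photosynthesis" %in% m, logical(1))
    is_mot <- vapply(parts, function(m) "motility" %in% m, logical(1))
    is_rev <- vapply(parts, function(m) "sign_reversal" %in% m, logical(1))
    is_active <- !vapply(parts, function(m) identical(m, "none"), logical(1))
    fl_mult <- ifelse(is_ps, planted_fluor_ratio, 1)
    noise <- function(k) 1 + rng$rnorm(k, 0, fluorescence_cv)
    fl <- c(control_fluorescence * fl_mult * noise(n_cpd),
            control_fluorescence * noise(n_controls))
    score <- ifelse(is_mot, "no_movement",
             ifelse(is_rev, "toward_light", "away_from_light"))
    regrew <- ifelse(is_active, rng$runif(n_cpd) >= cytocidal_fraction, TRUE)
    readouts <- data.frame(
      well = roles$well,
      fluorescence = pmax(fl, 0),
      phototaxis_score_1 = c(score, rep("away_from_light", n_controls)),
      phototaxis_score_2 = c(score, rep("away_from_light", n_controls)),
      regrew = c(regrew, rep(TRUE, n_controls)),
      stringsAsFactors = FALSE
    )
    plates[[p]] <- list(layout = layout, readouts = readouts)
  }
  plates
}
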