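#' Classify a phototaxis score into a motility class
#'
#' The acute assay photographs wells after exposure to strong directional
#' light; untreated cells are negatively phototactic (swim away from the
#' light). Wells are imaged twice, from opposite sides of the plate; when a
#' second score is supplied the two are reconciled: agreement keeps the
#' class, disagreement yields "missing". Lysed wells are counted as motility
#' inhibited (lysed cells cannot respond to light).
#'
#' @param score,score2 categorical phototaxis scores, one of
#'   "toward_light", "away_from_light", "no_movement", "lysed", "missing"
#'   (NA treated as missing); `score2` optional
#' @param control_direction direction untreated cells swim
#'   ("away_from_light", the default, or "toward_light")
#' @return motility class: "normal", "motility_inhibited", "sign_reversed" or
#'   "missing"
#' @export
score_phototaxis <- function(score, score2 = NULL,
                             control_direction = c("away_from_light",
                                                   "toward_light")) {
  control_direction <- match.arg(control_direction)
  levels_ok <- c("toward_light", "away_from_light", "no_movement", "lysed",
                 "missing")
  norm <- function(s) {
    s <- as.character(s)
    s[is.na(s) | s == ""] <- "missing"
    if (!all(s %in% levels_ok)) {
      stop("unknown phototaxis score(s): ",
           paste(setdiff(unique(s), levels_ok), collapse = ", "))
    }
    s
  }
  classify1 <- function(s) {
    out <- rep("missing", length(s))
    out[s %in% c("no_movement", "lysed")] <- "motility_inhibited"
    moved <- s %in% c("toward_light", "away_from_light")
    out[moved & s == control_direction] <- "normal"
    out[moved & s != control_direction] <- "sign_reversed"
    out
  }
  a <- classify1(norm(score))
  if (is.null(score2)) return(a)
  b <- classify1(norm(score2))
  ifelse(a == b, a, "missing")
}

#' Score the chlorophyll-fluorescence photosynthesis readout
#'
#' Fluorescence induction at the photosystem II emission maximum: light that
#' is not used for photosynthesis is re-emitted, so a fluorescence signal
#' elevated relative to the in-plate solvent controls indicates reduced
#' photosynthetic capacity.
#'
#' @param fluorescence well fluorescence (arbitrary units, >= 0)
#' @param control_mean mean fluorescence of the plate's solvent controls
#'   (must be > 0)
#' @param hit_ratio_threshold call a photosynthesis hit when
#'   fluorescence/control >= this ratio (default 1.35, i.e. a 35% elevation,
#'   mirroring the fitness effect size; a convention, not an instrument
#'   constant)
#' @return list with `fluorescence_ratio` and logical `photosynthesis_hit`
#'   (vectors when `fluorescence` is a vector)
#' @export
score_photosynthesis <- function(fluorescence, control_mean,
                                 hit_ratio_threshold = 1.35) {
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop("control fluorescence mean must be positive: plate failed QC")
  }
  stopifnot(all(is.na(fluorescence) | fluorescence >= 0))
  ratio <- fluorescence / control_mean
  list(fluorescence_ratio = ratio,
       photosynthesis_hit = !is.na(ratio) & ratio >= hit_ratio_threshold)
}

#' Classify cytotoxicity from the regrowth (pinning) assay
#'
#' After treatment, cells are pinned onto compound-free agar: a
#' growth-inhibited well that fails to regrow was killed (cytocidal), one
#' that regrows was arrested (cytostatic); wells that were never inhibited
#' are reversible.
#'
#' @param was_growth_inhibited logical, was growth inhibited under treatment
#' @param regrew logical, did the well regrow after compound removal (NA
#'   yields "missing")
#' @return "cytocidal", "cytostatic", "reversible" or "missing" (vectorized)
#' @export
classify_cytotoxicity <- function(was_growth_inhibited, regrew) {
  n <- max(length(was_growth_inhibited), length(regrew))
  was_growth_inhibited <- rep_len(as.logical(was_growth_inhibited), n)
  regrew <- rep_len(as.logical(regrew), n)
  out <- rep("missing", n)
  known <- !is.na(was_growth_inhibited) & !is.na(regrew)
  out[known & !was_growth_inhibited] <- "reversible"
  out[known & was_growth_inhibited & !regrew] <- "cytocidal"
  out[known & was_growth_inhibited & regrew] <- "cytostatic"
  out
}

#' Read an acute-assay readout table
#'
#' Expected columns: `well,fluorescence,phototaxis_score_1,
#' phototaxis_score_2,regrew` (score_2 and regrew may be blank).
#'
#' @param path CSV/TSV path
#' @return data.frame with typed columns
#' @export
read_acute_readouts <- function(path) {
  df <- read_delim_auto(path)
  need <- c("well", "fluorescence", "phototaxis_score_1")
  if (!all(need %in% names(df))) {
    stop("acute readout file ", path, " needs columns: ",
         paste(need, collapse = ", "))
  }
  df$well <- canonical_well(df$well)
  df$fluorescence <- suppressWarnings(as.numeric(df$fluorescence))
  if (is.null(df$phototaxis_score_2)) df$phototaxis_score_2 <- NA_character_
  df$phototaxis_score_2[df$phototaxis_score_2 == ""] <- NA_character_
  df$regrew <- if (is.null(df$regrew)) NA else
    as.logical(ifelse(df$regrew %in% c("", NA), NA, df$regrew))
  df
}

#' Call acute phenotypes for one plate of readouts
#'
#' Joins the readout table to the plate layout, computes the control
#' fluorescence mean from solvent-control wells, and produces one phenotype
#' call per compound well.
#'
#' @param readouts data.frame as from [read_acute_readouts()] (or
#'   [simulate_acute()])
#' @param layout the plate's `plate_layout`
#' @param hit_ratio_threshold passed to [score_photosynthesis()]
#' @param control_direction passed to [score_phototaxis()]
#' @param fitness optional `fitness_result` used to decide which compounds
#'   count as growth-inhibited for the cytotoxicity call; when absent the
#'   cytotoxicity of regrowth-negative wells cannot be classified
#' @return data.frame of class `phenotype_call` with columns compound_id,
#'   motility_class, fluorescence_ratio, photosynthesis_hit, cytotoxicity
#' @export
call_acute <- function(readouts, layout, hit_ratio_threshold = 1.35,
                       control_direction = "away_from_light",
                       fitness = NULL) {
  stopifnot(inherits(layout, "plate_layout"))
  readouts$well <- canonical_well(readouts$well)
  roles <- layout$wells[match(readouts$well, layout$wells$well), ]
  if (anyNA(roles$role)) {
    stop("acute readout well(s) not in layout: ",
         paste(readouts$well[is.na(roles$role)], collapse = ", "))
  }
  ctrl <- readouts$fluorescence[roles$role == "solvent_control"]
  ctrl <- ctrl[!is.na(ctrl)]
  if (!length(ctrl)) stop("no control fluorescence readings on plate ",
                          layout$plate_id)
  is_cpd <- roles$role == "compound"
  ps <- score_photosynthesis(readouts$fluorescence[is_cpd], mean(ctrl),
                             hit_ratio_threshold)
  mot <- score_phototaxis(readouts$phototaxis_score_1[is_cpd],
                          readouts$phototaxis_score_2[is_cpd],
                          control_direction)
  cpd_ids <- roles$compound_id[is_cpd]
  inhibited <- if (is.null(fitness)) NA else
    fitness$is_hit[match(cpd_ids, fitness$compound_id)]
  regrew <- if (is.null(readouts$regrew)) rep(NA, sum(is_cpd)) else
    readouts$regrew[is_cpd]
  out <- data.frame(
    compound_id = cpd_ids,
    motility_class = mot,
    fluorescence_ratio = ps$fluorescence_ratio,
    photosynthesis_hit = ps$photosynthesis_hit,
    cytotoxicity = classify_cytotoxicity(inhibited, regrew),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("phenotype_call", "data.frame")
  out
}

#' Overlap accounting for the acute screens
#'
#' Counts motility/phototaxis actives (motility inhibited or sign reversed),
#' photosynthesis actives, their intersection and union, and how many of the
#' unique acute actives are also fitness hits. The identity
#' `n_unique_acute = n_motility + n_photosynthesis - n_both` holds by
#' construction.
#'
#' @param calls `phenotype_call` data.frame (one row per compound)
#' @param fitness optional `fitness_result` for the fitness-overlap count
#' @return list with n_screened, n_motility, n_photosynthesis, n_both,
#'   n_unique_acute, n_also_fitness (NA when `fitness` is absent)
#' @export
summarize_acute <- function(calls, fitness = NULL) {
  if (anyDuplicated(calls$compound_id)) {
    stop("duplicate compound_id in phenotype calls: ",
         paste(unique(calls$compound_id[duplicated(calls$compound_id)]),
               collapse = ", "))
  }
  mot <- calls$compound_id[calls$motility_class %in%
                             c("motility_inhibited", "sign_reversed")]
  ps <- calls$compound_id[!is.na(calls$photosynthesis_hit) &
                            calls$photosynthesis_hit]
  both <- intersect(mot, ps)
  unique_acute <- union(mot, ps)
  n_also <- if (is.null(fitness)) NA_integer_ else
    length(intersect(unique_acute,
                     fitness$compound_id[fitness$is_hit]))
  list(n_screened = nrow(calls),
       n_motility = length(mot),
       n_photosynthesis = length(ps),
       n_both = length(both),
       n_unique_acute = length(unique_acute),
       n_also_fitness = n_also)
}
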