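#' Area under a growth curve
#'
#' Trapezoidal integral of optical density over time (OD·hours). By default
#' the well's initial OD is subtracted before integration (floored at zero),
#' which makes downstream AUC ratios robust to inoculum differences between
#' plates; set `baseline = "raw"` to integrate the curve as recorded.
#'
#' @param series a `well_series`
#' @param window optional `c(t_start, t_end)` in hours restricting the
#'   integration; must lie within the recorded range and contain >= 2 points
#' @param baseline "subtract" (default) or "raw"
#' @return area in OD·hours
#' @export
trapezoid_auc <- function(series, window = NULL,
                          baseline = c("subtract", "raw")) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(series, "well_series"))
  t <- series$times
  y <- series$od
  if (baseline == "subtract") y <- pmax(y - y[1], 0)
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] < window[2])
    if (window[1] < min(t) || window[2] > max(t)) {
      stop("integration window outside recorded time range")
    }
    keep <- t >= window[1] & t <= window[2]
    if (sum(keep) < 2) stop("integration window contains fewer than 2 points")
    t <- t[keep]
    y <- y[keep]
  }
  pracma::trapz(t, y)
}

#' Growth ratio of a compound well against the in-plate control
#'
#' @param compound_auc AUC of the compound well (OD·hours)
#' @param control_auc mean AUC over the plate's solvent-control wells; must
#'   be positive (a non-positive control AUC means the plate failed QC)
#' @return dimensionless ratio compound/control
#' @export
growth_ratio <- function(compound_auc, control_auc) {
  if (any(!is.finite(control_auc)) || any(control_auc <= 0)) {
    stop("control AUC must be positive: plate failed QC")
  }
  compound_auc / control_auc
}

#' Call a fitness hit from a growth ratio
#'
#' A compound is a fitness inhibitor when its growth ratio is at or below the
#' threshold (default 0.65, i.e. at least 35% growth inhibition). The
#' comparison is inclusive by default; set `inclusive = FALSE` for a strict
#' `<` comparison.
#'
#' @param ratio growth ratio(s), >= 0
#' @param threshold hit threshold (default 0.65)
#' @param inclusive use `<=` (default) rather than `<`
#' @return logical hit call(s)
#' @export
call_fitness_hit <- function(ratio, threshold = 0.65, inclusive = TRUE) {
  stopifnot(all(is.na(ratio) | ratio >= 0))
  if (inclusive) ratio <= threshold else ratio < threshold
}

#' Aggregate per-replicate growth ratios
#'
#' @param ratios numeric vector of per-replicate growth ratios (length >= 1)
#' @return list with `mean`, `sd` (sample SD; NA when n < 2) and `n`
#' @export
aggregate_replicates <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (!length(ratios)) stop("no replicate ratios to aggregate")
  list(mean = mean(ratios),
       sd = if (length(ratios) >= 2) stats::sd(ratios) else NA_real_,
       n = length(ratios))
}

#' Score a set of replicate plates against in-plate controls
#'
#' For each plate: computes every well's AUC, averages the solvent-control
#' AUCs into the plate control, flags plates whose control coefficient of
#' variation exceeds `qc_cv`, and forms per-compound-well growth ratios.
#' Ratios are then aggregated across plates by compound id and hits are
#' called on the replicate mean.
#'
#' @param plates list of plates, each a list with elements `layout`
#'   (`plate_layout`) and `series` (list of `well_series` as returned by
#'   [read_growth_table()] or [simulate_plate()])
#' @param threshold fitness hit threshold on the mean growth ratio
#' @param baseline passed to [trapezoid_auc()]
#' @param window passed to [trapezoid_auc()]
#' @param qc_cv flag plates whose control AUC CV exceeds this bound
#' @param inclusive passed to [call_fitness_hit()]
#' @return data.frame of class `fitness_result` with columns compound_id,
#'   growth_ratio (replicate mean), replicate_sd, n_replicates, is_hit;
#'   attribute `qc_flagged` lists plates failing the control-CV bound
#' @export
score_plates <- function(plates, threshold = 0.65,
                         baseline = c("subtract", "raw"), window = NULL,
                         qc_cv = 0.2, inclusive = TRUE) {
  baseline <- match.arg(baseline)
  per_well <- list()
  qc_flagged <- character(0)
  for (p in plates) {
    layout <- p$layout
    stopifnot(inherits(layout, "plate_layout"))
    aucs <- vapply(p$series, trapezoid_auc, numeric(1),
                   window = window, baseline = baseline)
    roles <- layout$wells[match(names(p$series), layout$wells$well), ]
    ctrl <- aucs[roles$role == "solvent_control"]
    if (!length(ctrl)) stop("plate ", layout$plate_id, " has no control series")
    ctrl_mean <- mean(ctrl)
    if (length(ctrl) >= 2 && ctrl_mean > 0 &&
        stats::sd(ctrl) / ctrl_mean > qc_cv) {
      qc_flagged <- c(qc_flagged, layout$plate_id)
      warning("plate ", layout$plate_id, " control CV ",
              sprintf("%.1f%%", 100 * stats::sd(ctrl) / ctrl_mean),
              " exceeds QC bound ", sprintf("%.0f%%", 100 * qc_cv))
    }
    is_cpd <- roles$role == "compound"
    if (any(is_cpd)) {
      per_well[[length(per_well) + 1L]] <- data.frame(
        compound_id = roles$compound_id[is_cpd],
        ratio = growth_ratio(aucs[is_cpd], ctrl_mean),
        stringsAsFactors = FALSE
      )
    }
  }
  all_wells <- do.call(rbind, per_well)
  if (is.null(all_wells)) stop("no compound wells found on any plate")
  by_cpd <- split(all_wells$ratio, all_wells$compound_id)
  agg <- lapply(by_cpd, aggregate_replicates)
  res <- data.frame(
    compound_id = names(by_cpd),
    growth_ratio = vapply(agg, `[[`, numeric(1), "mean"),
    replicate_sd = vapply(agg, `[[`, numeric(1), "sd"),
    n_replicates = vapply(agg, `[[`, numeric(1), "n"),
    stringsAsFactors = FALSE
  )
  res$is_hit <- call_fitness_hit(res$growth_ratio, threshold, inclusive)
  rownames(res) <- NULL
  attr(res, "qc_flagged") <- unique(qc_flagged)
  attr(res, "threshold") <- threshold
  class(res) <- c("fitness_result", "data.frame")
  res
}

#' Summarize a fitness screen
#'
#' @param results a `fitness_result` data.frame (or any data.frame with an
#'   `is_hit` column)
#' @param digits rounding for the reported hit percentage (default 0,
#'   i.e. nearest integer)
#' @return list with n_screened, n_hits, hit_pct
#' @export
summarize_screen <- function(results, digits = 0) {
  n <- nrow(results)
  if (!n) stop("no compounds screened")
  n_hits <- sum(results$is_hit, na.rm = TRUE)
  list(n_screened = n, n_hits = n_hits,
       hit_pct = round(100 * n_hits / n, digits))
}

#' Write per-compound fitness results as CSV
#' @param results a `fitness_result` data.frame
#' @param path output CSV path
#' @export
write_fitness_results <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
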