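#' Stratified k-fold split
#'
#' Partitions ids into k disjoint folds whose sizes differ by at most one.
#' When labels are supplied the split is stratified: actives and inactives
#' are distributed separately, so each fold's active fraction matches the
#' global fraction within rounding.
#'
#' @param ids vector of identifiers
#' @param k number of folds (default 5)
#' @param seed integer seed (the split is deterministic given the seed)
#' @param labels optional logical labels for stratification
#' @return list of k vectors of ids
#' @export
kfold_split <- function(ids, k = 5, seed, labels = NULL) {
  n <- length(ids)
  if (k > n) stop("k = ", k, " exceeds the number of ids (", n, ")")
  stopifnot(k >= 2)
  rng <- local_rng(seed)
  fold_of <- integer(n)
  if (is.null(labels)) labels <- rep(TRUE, n)
  for (grp in unique(labels)) {
    idx <- which(labels == grp)
    idx <- idx[rng$sample(length(idx))]
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) ids[fold_of == f])
}

# Seeded RNG scoped to this object: leaves the caller's .Random.seed alone.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  env$state <- get(".Random.seed", globalenv())
  restore <- function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    prev <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(prev)) rm(".Random.seed", envir = globalenv()) else
        assign(".Random.seed", prev, envir = globalenv())
    })
    f()
  }
  restore()
  list(
    sample = function(n, size = n) with_state(function() sample.int(n, size)),
    runif = function(n) with_state(function() stats::runif(n)),
    rnorm = function(n, mean = 0, sd = 1)
      with_state(function() stats::rnorm(n, mean, sd)),
    rbinom = function(n, size, prob)
      with_state(function() stats::rbinom(n, size, prob))
  )
}

#' Enrichment factor at a screening fraction
#'
#' EF = (actives found in the top `ceil(fraction * n)` of the ranked list,
#' per compound selected) / (active rate in the whole list). EF = 1 is the
#' random expectation; the combinatorial maximum at fraction f is
#' `min(m, n_active) / (m * n_active / n)` with `m = ceil(f * n)`, attained
#' by a perfect ranking.
#'
#' @param ranked_labels logical labels in ranked order (best first)
#' @param fraction screening fraction in (0, 1]
#' @return the enrichment factor (dimensionless)
#' @export
enrichment_factor <- function(ranked_labels, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  ranked_labels <- as.logical(ranked_labels)
  n <- length(ranked_labels)
  n_active <- sum(ranked_labels)
  if (n_active == 0) stop("ranked list contains no actives")
  m <- ceiling(fraction * n)
  found <- sum(ranked_labels[seq_len(m)])
  (found / m) / (n_active / n)
}

#' Cumulative enrichment curve
#'
#' @param ranked_labels logical labels in ranked order (best first)
#' @param fractions ordered vector of screening fractions in (0, 1]
#' @return data.frame of class `enrichment_curve` with columns `fraction`,
#'   `cumulative_actives`, `ef`; attributes `n_total`, `n_active`
#' @export
enrichment_curve <- function(ranked_labels,
                             fractions = seq(0.05, 1, by = 0.05)) {
  ranked_labels <- as.logical(ranked_labels)
  n <- length(ranked_labels)
  n_active <- sum(ranked_labels)
  cum <- cumsum(ranked_labels)
  m <- pmin(ceiling(fractions * n), n)
  out <- data.frame(fraction = fractions,
                    cumulative_actives = cum[m],
                    ef = (cum[m] / m) / (n_active / n))
  attr(out, "n_total") <- n
  attr(out, "n_active") <- n_active
  class(out) <- c("enrichment_curve", "data.frame")
  out
}

#' Expected hits from screening a ranked versus a random subset
#'
#' The budgeting arithmetic behind prioritized screening: picking a fraction
#' of a library at random finds `n * fraction * hit_rate` hits; screening the
#' model-ranked top fraction instead finds `ef` times as many (capped at the
#' number of compounds screened).
#'
#' @param n_library library size
#' @param fraction fraction screened, in (0, 1]
#' @param hit_rate proportion of actives in the library
#' @param ef enrichment factor of the prioritized list
#' @return list with `random_hits` and `prioritized_hits`, both rounded to
#'   the nearest integer
#' @export
expected_hits <- function(n_library, fraction, hit_rate, ef) {
  stopifnot(n_library > 0, fraction > 0, fraction <= 1, hit_rate > 0, ef > 0)
  screened <- n_library * fraction
  random_hits <- screened * hit_rate
  prioritized <- random_hits * ef
  if (prioritized > screened) {
    warning("enrichment ", ef, " would imply more hits than compounds ",
            "screened; capping at ", round(screened))
    prioritized <- screened
  }
  list(random_hits = round(random_hits),
       prioritized_hits = round(prioritized))
}

#' Repeated-holdout evaluation of the ranking model
#'
#' Five-fold (by default) stratified cross-validation of the naive Bayes
#' ranker: each fold in turn is held out, the model is trained on the other
#' four fifths, the held-out fifth is ranked, and the enrichment factor at
#' the stated fraction is computed. Reports the per-fold EFs, their mean and
#' the standard error over folds, plus each fold's enrichment curve.
#'
#' @param fps `fingerprint_set` for the labelled library
#' @param labels logical activity labels aligned with `fps`
#' @param k number of folds (default 5)
#' @param fraction EF screening fraction (default 0.10)
#' @param seed integer seed controlling the fold assignment
#' @param trainer model-fitting function, default [nb_train()]
#' @return object of class `crossval_result`: list with `fold_ef`, `mean_ef`,
#'   `se`, `k`, `fraction`, `seed`, `curves` (list of `enrichment_curve`)
#' @export
evaluate_model <- function(fps, labels, k = 5, fraction = 0.10, seed,
                           trainer = nb_train) {
  stopifnot(length(fps) == length(labels))
  ids <- names(fps)
  folds <- kfold_split(ids, k = k, seed = seed, labels = labels)
  names(labels) <- ids
  fold_ef <- rep(NA_real_, k)
  curves <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(ids, test_ids)
    model <- trainer(fps[train_ids], labels[train_ids])
    ranked <- rank_library(model, fps[test_ids])
    rl <- labels[ranked$compound_id]
    if (!any(rl)) {
      warning("fold ", f, " holds no actives; EF undefined, excluded")
      next
    }
    fold_ef[f] <- enrichment_factor(rl, fraction)
    curves[[f]] <- enrichment_curve(rl)
  }
  ok <- !is.na(fold_ef)
  structure(
    list(fold_ef = fold_ef,
         mean_ef = mean(fold_ef[ok]),
         se = if (sum(ok) >= 2) stats::sd(fold_ef[ok]) / sqrt(sum(ok)) else NA_real_,
         k = k, fraction = fraction, seed = seed,
         stratified = TRUE, top_cut = "ceiling",
         curves = curves),
    class = "crossval_result"
  )
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf(
    "crossval_result: %d-fold, EF@%d%% = %.2f +/- %.2f (SE); folds: %s\n",
    x$k, round(100 * x$fraction), x$mean_ef, x$se,
    paste(sprintf("%.2f", x$fold_ef), collapse = ", ")))
  invisible(x)
}
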