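#' Train a Laplacian-corrected naive Bayes activity model
#'
#' For every fingerprint feature F seen in training, with T_F compounds
#' carrying F, A_F of them active, and base rate P_a = actives/total, the
#' model stores the log-weight
#'
#'   w(F) = log\[(A_F + 1) / ((T_F + 1/P_a) * P_a)\]
#'
#' the Laplacian-corrected estimator of how over-represented F is in the
#' active class. Low-count features are shrunk toward zero evidence: a
#' feature never seen (T_F = 0) would score log(1) = 0, which is exactly the
#' convention applied to unseen features at prediction time. A compound's
#' score is the sum of its features' weights; scores are relative ranks, not
#' calibrated probabilities.
#'
#' @param fps `fingerprint_set` (named list of feature-identifier vectors)
#' @param labels logical vector of activity labels aligned with `fps`
#' @return object of class `bayes_model`: list with `base_rate`, `n_train`,
#'   `feature_id`, `weight`, `total_count`, `active_count`
#' @export
nb_train <- function(fps, labels) {
  stopifnot(length(fps) == length(labels))
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be TRUE/FALSE with no missing values")
  n <- length(labels)
  n_active <- sum(labels)
  if (n_active == 0 || n_active == n) {
    stop("training set needs at least one active and one inactive compound")
  }
  if (any(lengths(fps) == 0)) stop("empty fingerprint in training set")
  p_a <- n_active / n
  feat <- unlist(fps, use.names = FALSE)
  cpd <- rep(seq_len(n), lengths(fps))
  total <- table_int(feat)
  active <- table_int(feat[labels[cpd]], universe = total$value)
  weight <- log((active$count + 1) / ((total$count + 1 / p_a) * p_a))
  structure(
    list(base_rate = p_a, n_train = n, feature_id = total$value,
         weight = weight, total_count = total$count,
         active_count = active$count),
    class = "bayes_model"
  )
}

# counts of each distinct value; `universe` fixes the value set (zeros kept)
table_int <- function(x, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(x))
  idx <- match(x, universe)
  list(value = universe,
       count = tabulate(idx[!is.na(idx)], nbins = length(universe)))
}

#' @export
print.bayes_model <- function(x, ...) {
  cat(sprintf(
    "bayes_model: %d features, trained on %d compounds (base rate %.3f)\n",
    length(x$feature_id), x$n_train, x$base_rate))
  invisible(x)
}

#' Score compounds with a trained model
#'
#' Sum of the model's feature weights over the compound's features; features
#' absent from the model contribute 0.
#'
#' @param model a `bayes_model`
#' @param fps `fingerprint_set`, or a single feature vector
#' @return named numeric vector of scores (log-units, unbounded)
#' @export
nb_score <- function(model, fps) {
  stopifnot(inherits(model, "bayes_model"))
  if (!is.list(fps)) fps <- structure(list(fps), names = "x")
  if (any(lengths(fps) == 0)) stop("cannot score an empty fingerprint")
  vapply(fps, function(f) {
    w <- model$weight[match(f, model$feature_id)]
    sum(w, na.rm = TRUE)
  }, numeric(1))
}

#' Rank a compound library by predicted activity
#'
#' Stable descending sort by model score; ties are broken by compound id so
#' the ranking is deterministic.
#'
#' @param model a `bayes_model`
#' @param fps `fingerprint_set` of the library
#' @return data.frame with compound_id, score, rank (descending score)
#' @export
rank_library <- function(model, fps) {
  scores <- nb_score(model, fps)
  ord <- order(-scores, names(scores))
  data.frame(compound_id = names(scores)[ord],
             score = unname(scores[ord]),
             rank = seq_along(scores),
             stringsAsFactors = FALSE)
}

#' Serialize a model to JSON
#' @param model a `bayes_model`
#' @param path output path
#' @export
write_bayes_model <- function(model, path) {
  jsonlite::write_json(
    list(base_rate = model$base_rate, n_train = model$n_train,
         feature_id = model$feature_id, weight = model$weight,
         total_count = model$total_count,
         active_count = model$active_count),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [write_bayes_model()]
#' @param path JSON path
#' @return a `bayes_model`
#' @export
read_bayes_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x[c("base_rate", "n_train", "feature_id", "weight",
                "total_count", "active_count")],
            class = "bayes_model")
}

#' Bernoulli naive Bayes scorer (alternative backend)
#'
#' A vanilla presence/absence Bernoulli naive Bayes over the same features,
#' provided for comparison with the Laplacian-corrected estimator: the score
#' is the log posterior-odds of activity with add-one smoothing on the
#' per-class feature probabilities, using only features present in the
#' compound.
#'
#' @inheritParams nb_train
#' @return a `bayes_model` with an extra class `bernoulli` whose weights are
#'   per-feature log likelihood-ratios plus a prior offset term
#' @export
nb_train_bernoulli <- function(fps, labels) {
  m <- nb_train(fps, labels)
  n_active <- round(m$base_rate * m$n_train)
  n_inactive <- m$n_train - n_active
  p_act <- (m$active_count + 1) / (n_active + 2)
  p_inact <- (m$total_count - m$active_count + 1) / (n_inactive + 2)
  m$weight <- log(p_act / p_inact)
  m$prior <- log(n_active / n_inactive)
  class(m) <- c("bernoulli", "bayes_model")
  m
}
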