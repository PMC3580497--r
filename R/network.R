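#' Build a chemical similarity network
#'
#' Nodes are compounds; an edge joins two compounds when their fingerprint
#' Tanimoto similarity strictly exceeds the cutoff (a pair at exactly the
#' cutoff is not connected). Singletons are retained as isolated nodes and
#' flagged via the `isolated` vertex attribute, since figures typically show
#' only the connected subset.
#'
#' @param fps a `fingerprint_set`
#' @param cutoff similarity cutoff in `[0, 1]` (default 0.5)
#' @return an `igraph` graph with edge attribute `weight` (similarity) and
#'   vertex attribute `isolated`
#' @export
build_network <- function(fps, cutoff = 0.5) {
  stopifnot(length(fps) >= 1)
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  ids <- names(fps)
  sim <- tanimoto_matrix(fps)
  sim[lower.tri(sim, diag = TRUE)] <- 0
  idx <- which(sim > cutoff, arr.ind = TRUE)
  # deterministic edge order regardless of input order
  idx <- idx[order(ids[idx[, 1]], ids[idx[, 2]]), , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]),
                           weight = sim[idx])
  }
  g <- igraph::set_vertex_attr(g, "isolated",
                               value = igraph::degree(g) == 0)
  g
}

#' Map phenotype attributes onto a similarity network
#'
#' Node color encodes the acute phenotypes: green = active in both
#' photosynthesis and motility/phototaxis, red = photosynthesis only,
#' blue = motility/phototaxis only, white = neither; node shape encodes
#' fitness: circle = fitness inhibitor, diamond = no fitness inhibition.
#'
#' @param net graph from [build_network()]
#' @param fitness `fitness_result` data.frame
#' @param acute `phenotype_call` data.frame
#' @return the graph with vertex attributes `fitness_hit`, `shape`,
#'   `photosynthesis`, `motility`, `color`
#' @export
annotate_network <- function(net, fitness = NULL, acute = NULL) {
  ids <- igraph::V(net)$name
  fit_hit <- rep(NA, length(ids))
  if (!is.null(fitness)) {
    fit_hit <- fitness$is_hit[match(ids, fitness$compound_id)]
  }
  ps <- mot <- rep(NA, length(ids))
  if (!is.null(acute)) {
    m <- match(ids, acute$compound_id)
    ps <- acute$photosynthesis_hit[m]
    mot <- acute$motility_class[m] %in% c("motility_inhibited",
                                          "sign_reversed")
    mot[is.na(m)] <- NA
  }
  unknown <- is.na(fit_hit) & is.na(ps) & is.na(mot)
  if (any(unknown)) {
    warning(sum(unknown), " network compound(s) absent from all attribute ",
            "tables: ", paste(ids[unknown], collapse = ", "))
  }
  ps0 <- !is.na(ps) & ps
  mot0 <- !is.na(mot) & mot
  color <- ifelse(ps0 & mot0, "green",
           ifelse(ps0, "red",
           ifelse(mot0, "blue", "white")))
  color[unknown] <- NA
  shape <- ifelse(!is.na(fit_hit) & fit_hit, "circle", "diamond")
  shape[unknown] <- NA
  net <- igraph::set_vertex_attr(net, "fitness_hit", value = fit_hit)
  net <- igraph::set_vertex_attr(net, "photosynthesis", value = ps0)
  net <- igraph::set_vertex_attr(net, "motility", value = mot0)
  net <- igraph::set_vertex_attr(net, "color", value = color)
  net <- igraph::set_vertex_attr(net, "shape", value = shape)
  net
}

#' Per-component phenotype percentages
#'
#' For each connected component of the annotated network, reports its size
#' and the percentage of member compounds in each phenotype class. Classes
#' overlap, so percentages need not sum to 100.
#'
#' @param net annotated graph from [annotate_network()]
#' @return data.frame with component id, size, and percentage columns
#' @export
cluster_summary <- function(net) {
  comp <- igraph::components(net)
  fit <- igraph::V(net)$fitness_hit
  ps <- igraph::V(net)$photosynthesis
  mot <- igraph::V(net)$motility
  pct <- function(x, members) {
    v <- x[members]
    if (all(is.na(v))) return(NA_real_)
    100 * sum(v, na.rm = TRUE) / length(v)
  }
  rows <- lapply(seq_len(comp$no), function(k) {
    members <- which(comp$membership == k)
    data.frame(component = k, size = length(members),
               pct_fitness = pct(fit, members),
               pct_photosynthesis = pct(ps, members),
               pct_motility = pct(mot, members))
  })
  out <- do.call(rbind, rows)
  out[order(-out$size, out$component), ]
}

#' Export a network as SIF plus a node-attribute CSV
#'
#' SIF lines are `idA pp idB`; isolated nodes appear as single-column lines
#' so graph tools retain them. The attribute CSV carries the vertex
#' attributes set by [annotate_network()].
#'
#' @param net the graph
#' @param sif_path output SIF path
#' @param attr_path optional output CSV path for node attributes
#' @return `sif_path`, invisibly
#' @export
write_network_sif <- function(net, sif_path, attr_path = NULL) {
  el <- igraph::as_edgelist(net)
  lines <- if (nrow(el)) paste(el[, 1], "pp", el[, 2]) else character(0)
  iso <- igraph::V(net)$name[igraph::degree(net) == 0]
  writeLines(c(lines, iso), sif_path)
  if (!is.null(attr_path)) {
    av <- igraph::vertex_attr(net)
    utils::write.csv(as.data.frame(av, stringsAsFactors = FALSE), attr_path,
                     row.names = FALSE)
  }
  invisible(sif_path)
}

#' Export a network as GraphML with embedded attributes
#'
#' @param net the graph
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network_graphml <- function(net, path) {
  # GraphML cannot carry NA logicals; encode as character
  for (a in igraph::vertex_attr_names(net)) {
    v <- igraph::vertex_attr(net, a)
    if (is.logical(v)) {
      net <- igraph::set_vertex_attr(net, a, value = as.character(v))
    }
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
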