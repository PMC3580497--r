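# Circular (ECFP-style) substructure fingerprints.
#
# Molecule normalisation (SMILES -> canonical SMILES -> SDF with explicit
# hydrogens) is delegated to OpenBabel; this file owns only the fingerprint
# algorithm itself: iterative hashing of circular atom environments with
# bond-set deduplication, yielding a sparse set of integer feature
# identifiers per molecule. Feature identifiers are implementation-defined
# (as for any ECFP reimplementation); similarities, not raw identifiers, are
# comparable across toolkits.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (p == "") stop("OpenBabel 'obabel' executable not found on PATH")
  p
}

run_obabel <- function(in_lines, in_fmt, out_fmt, extra = character(0)) {
  inf <- tempfile(fileext = paste0(".", in_fmt))
  outf <- tempfile(fileext = paste0(".", out_fmt))
  on.exit(unlink(c(inf, outf)), add = TRUE)
  writeLines(in_lines, inf)
  status <- suppressWarnings(system2(
    obabel_path(),
    c(inf, paste0("-i", in_fmt), paste0("-o", out_fmt), "-O", outf,
      "-e", extra),
    stdout = FALSE, stderr = FALSE
  ))
  if (status != 0 || !file.exists(outf)) {
    stop("obabel conversion ", in_fmt, " -> ", out_fmt, " failed")
  }
  readLines(outf)
}

#' Canonical SMILES via OpenBabel
#'
#' Unparseable inputs yield NA (and are reported by callers); two spellings
#' of the same molecule map to the same canonical string.
#'
#' @param smiles character vector of SMILES
#' @return character vector of canonical SMILES, NA where unparseable
#' @export
canonical_smiles <- function(smiles) {
  n <- length(smiles)
  if (!n) return(character(0))
  out_lines <- run_obabel(paste(smiles, seq_len(n)), "smi", "can")
  out <- rep(NA_character_, n)
  parts <- strsplit(out_lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2) out[as.integer(p[2])] <- p[1]
  }
  out
}

# Per-atom aromaticity by scanning atom tokens of a (canonical) SMILES.
# Atom order in OpenBabel's SMILES->SDF conversion follows token order, so
# the flags align with the SDF atom block (explicit H are appended after the
# heavy atoms). Bracket atoms are aromatic iff their element symbol is
# lower-case; organic-subset aromatic atoms are b, c, n, o, p, s.
smiles_atom_aromatic <- function(smi) {
  chars <- strsplit(smi, "")[[1]]
  arom <- logical(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      token <- paste(chars[(i + 1):(j - 1)], collapse = "")
      sym <- regmatches(token, regexpr("^[0-9]*([A-Za-z][a-z]?)", token))
      sym <- sub("^[0-9]*", "", sym)
      # strip trailing H-count letter mistaken as part of symbol, e.g. "NH"
      if (nchar(sym) == 2 && substr(sym, 2, 2) == "H" &&
          substr(sym, 1, 1) != "T") {
        sym <- substr(sym, 1, 1)
      }
      arom <- c(arom, substr(sym, 1, 1) %in% letters)
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "P", "S", "B", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) i <- i + 1L
      arom <- c(arom, FALSE)
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "p", "s", "b")) {
      arom <- c(arom, TRUE)
      i <- i + 1L
    } else {
      # ring digits, %, bonds, branches, dots, stereo marks
      i <- i + 1L
    }
  }
  arom
}

# MDL old-style charge codes in the atom block: 1..7 -> +3..-3 (4 = radical)
decode_mdl_charge <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2,
           `7` = -3)
  unname(map[as.character(code)])
}

#' Parse SMILES into heavy-atom molecular graphs
#'
#' Canonicalizes each SMILES, converts to SDF with explicit hydrogens via
#' OpenBabel, and extracts the heavy-atom graph: element, formal charge,
#' attached-hydrogen count, heavy-atom degree, ring membership and aromatic
#' flags per atom; order and aromaticity per bond. Ring membership is
#' computed graph-theoretically (a bond is in a ring iff it is not a bridge).
#'
#' @param smiles character vector of SMILES
#' @return list (one element per input; NULL where unparseable) of lists with
#'   `atoms` (data.frame) and `bonds` (data.frame); attribute
#'   `canonical_smiles` carries the canonical strings
#' @export
smiles_to_graphs <- function(smiles) {
  can <- canonical_smiles(smiles)
  out <- vector("list", length(smiles))
  ok <- which(!is.na(can))
  if (length(ok)) {
    sdf_lines <- run_obabel(paste(can[ok], seq_along(ok)), "smi", "sdf",
                            extra = "-h")
    sdfset <- ChemmineR::read.SDFset(ChemmineR::read.SDFstr(sdf_lines))
    ids <- as.integer(ChemmineR::sdfid(sdfset))
    for (k in seq_along(sdfset)) {
      idx <- ok[ids[k]]
      out[[idx]] <- sdf_to_graph(sdfset[[k]], can[idx])
    }
  }
  attr(out, "canonical_smiles") <- can
  out
}

sdf_to_graph <- function(sdf, can_smiles) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  charge <- if ("C6" %in% colnames(ab)) decode_mdl_charge(ab[, "C6"]) else
    rep(0L, nrow(ab))
  is_h <- elements == "H"
  heavy_idx <- which(!is_h)
  if (!length(heavy_idx)) return(NULL)
  # remap to heavy-only indices
  remap <- rep(NA_integer_, length(elements))
  remap[heavy_idx] <- seq_along(heavy_idx)
  b1 <- as.integer(bb[, "C1"])
  b2 <- as.integer(bb[, "C2"])
  border <- as.integer(bb[, "C3"])
  n_heavy <- length(heavy_idx)
  nH <- integer(n_heavy)
  keep <- !is_h[b1] & !is_h[b2]
  hb <- which(xor(is_h[b1], is_h[b2]))
  for (i in hb) {
    heavy_end <- if (is_h[b1[i]]) b2[i] else b1[i]
    nH[remap[heavy_end]] <- nH[remap[heavy_end]] + 1L
  }
  bonds <- data.frame(a1 = remap[b1[keep]], a2 = remap[b2[keep]],
                      order = border[keep])
  # ring bonds: not bridges of the heavy-atom graph
  in_ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds)) {
    g <- igraph::graph_from_edgelist(cbind(bonds$a1, bonds$a2),
                                     directed = FALSE)
    if (igraph::vcount(g) < n_heavy) {
      g <- igraph::add_vertices(g, n_heavy - igraph::vcount(g))
    }
    br <- igraph::bridges(g)
    in_ring_bond <- !(seq_len(nrow(bonds)) %in% as.integer(br))
  }
  in_ring_atom <- rep(FALSE, n_heavy)
  if (any(in_ring_bond)) {
    in_ring_atom[unique(c(bonds$a1[in_ring_bond],
                          bonds$a2[in_ring_bond]))] <- TRUE
  }
  arom_flags <- smiles_atom_aromatic(can_smiles)
  aromatic <- rep(FALSE, n_heavy)
  if (length(arom_flags) == n_heavy) {
    aromatic <- arom_flags
  } else if (length(arom_flags) > 0) {
    aromatic[seq_len(min(length(arom_flags), n_heavy))] <-
      arom_flags[seq_len(min(length(arom_flags), n_heavy))]
  }
  bonds$aromatic <- in_ring_bond & aromatic[bonds$a1] & aromatic[bonds$a2]
  atoms <- data.frame(
    element = elements[heavy_idx],
    charge = as.integer(charge[heavy_idx]),
    nH = nH,
    degree = tabulate(c(bonds$a1, bonds$a2), nbins = n_heavy),
    in_ring = in_ring_atom,
    aromatic = aromatic
  )
  list(atoms = atoms, bonds = bonds)
}

# periodic table lookup restricted to elements the screen's libraries use
ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                   S = 16, Cl = 17, Se = 34, Br = 35, I = 53)

#' Circular fingerprint of one molecular graph
#'
#' Implements the extended-connectivity recipe: each heavy atom starts from a
#' hash of its invariants (atomic number, total degree, attached hydrogens,
#' formal charge, ring membership); at every iteration an atom's identifier
#' is rehashed together with the sorted (bond type, neighbor identifier)
#' pairs of its neighbors, extending the environment by one bond. Radius 2
#' (diameter 4) is the ECFP_4 equivalent. Environments at radius >= 1 whose
#' bond set duplicates an already-recorded environment are discarded, so
#' symmetric or fully-overlapping environments contribute one feature, as in
#' reference implementations.
#'
#' @param graph a graph from [smiles_to_graphs()]
#' @param radius maximum environment radius in bonds (default 2)
#' @return sorted numeric vector of distinct feature identifiers
#' @keywords internal
graph_fingerprint <- function(graph, radius = 2) {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- nrow(atoms)
  anum <- ATOMIC_NUMBER[atoms$element]
  anum[is.na(anum)] <- 99
  codes <- vapply(seq_len(n), function(i) {
    hash_ints(c(anum[i], atoms$degree[i] + atoms$nH[i], atoms$nH[i],
                atoms$charge[i] + 8, as.integer(atoms$in_ring[i])))
  }, numeric(1))
  feature_ids <- unique(codes)
  if (!nrow(bonds) || radius < 1) return(sort(feature_ids))
  # neighbor list with bond indices and types (aromatic coded as 12)
  btype <- ifelse(bonds$aromatic, 12L, bonds$order)
  nbrs <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    nbrs[[bonds$a1[b]]] <- rbind(nbrs[[bonds$a1[b]]], c(bonds$a2[b], b, btype[b]))
    nbrs[[bonds$a2[b]]] <- rbind(nbrs[[bonds$a2[b]]], c(bonds$a1[b], b, btype[b]))
  }
  env_bonds <- rep(list(integer(0)), n)
  seen_envs <- new.env(hash = TRUE, parent = emptyenv())
  for (r in seq_len(radius)) {
    new_codes <- codes
    new_env <- env_bonds
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      if (is.null(nb)) next
      ord <- order(nb[, 3], codes[nb[, 1]])
      atts <- rbind(nb[ord, 3], codes[nb[ord, 1]])
      new_codes[i] <- hash_ints(c(r, codes[i], as.vector(atts)))
      eb <- nb[, 2]
      for (j in nb[, 1]) eb <- c(eb, env_bonds[[j]])
      new_env[[i]] <- sort(unique(c(env_bonds[[i]], eb)))
    }
    # accept environments in (identifier, atom) order; drop bond-set dupes
    cand <- which(!vapply(nbrs, is.null, logical(1)))
    for (i in cand[order(new_codes[cand], cand)]) {
      key <- paste(new_env[[i]], collapse = ",")
      if (!exists(key, envir = seen_envs, inherits = FALSE)) {
        assign(key, TRUE, envir = seen_envs)
        feature_ids <- c(feature_ids, new_codes[i])
      }
    }
    codes <- new_codes
    env_bonds <- new_env
  }
  sort(unique(feature_ids))
}

#' Compute circular fingerprints for a set of compounds
#'
#' @param smiles character vector of SMILES
#' @param ids compound identifiers (default names of `smiles` or index)
#' @param radius environment radius in bonds (default 2, the ECFP_4
#'   equivalent)
#' @return named list of sorted feature-identifier vectors, class
#'   `fingerprint_set`; unparseable inputs are dropped with a warning and
#'   listed in attribute `rejected`
#' @export
compute_fingerprints <- function(smiles, ids = NULL, radius = 2) {
  if (is.null(ids)) ids <- names(smiles) %||% as.character(seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  # fingerprint each distinct canonical structure once
  graphs <- smiles_to_graphs(smiles)
  can <- attr(graphs, "canonical_smiles")
  bad <- is.na(can) | vapply(graphs, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " unparseable SMILES dropped: ",
            paste(ids[bad], collapse = ", "))
  }
  keep <- which(!bad)
  first_of <- !duplicated(can[keep])
  uniq_idx <- keep[first_of]
  uniq_fp <- lapply(graphs[uniq_idx], graph_fingerprint, radius = radius)
  names(uniq_fp) <- can[uniq_idx]
  fps <- uniq_fp[can[keep]]
  names(fps) <- ids[keep]
  attr(fps, "radius") <- radius
  attr(fps, "rejected") <- ids[bad]
  class(fps) <- "fingerprint_set"
  fps
}

#' Compute the fingerprint of a single SMILES
#'
#' @inheritParams compute_fingerprints
#' @return sorted numeric vector of feature identifiers
#' @export
compute_fingerprint <- function(smiles, radius = 2) {
  stopifnot(length(smiles) == 1)
  fps <- compute_fingerprints(smiles, ids = "x", radius = radius)
  if (!length(fps)) stop("unparseable SMILES: ", smiles)
  fps[[1]]
}

#' @export
print.fingerprint_set <- function(x, ...) {
  sizes <- lengths(unclass(x))
  cat("fingerprint_set:", length(x), "molecules, radius",
      attr(x, "radius") %||% "?", "- features/molecule",
      if (length(x)) paste0(min(sizes), "..", max(sizes)) else "", "\n")
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' |A intersect B| / |A union B| over the sparse feature sets; 1 means
#' identical fingerprints.
#'
#' @param a,b feature-identifier vectors (non-empty)
#' @return similarity in `[0, 1]`
#' @export
tanimoto <- function(a, b) {
  if (!length(a) || !length(b)) stop("cannot compare an empty fingerprint")
  n_int <- length(intersect(a, b))
  n_int / (length(unique(a)) + length(unique(b)) - n_int)
}

# sparse feature x compound incidence matrix for fast batch operations
fp_incidence <- function(fps) {
  stopifnot(length(fps) >= 1)
  feats <- sort(unique(unlist(fps, use.names = FALSE)))
  i <- match(unlist(fps, use.names = FALSE), feats)
  j <- rep(seq_along(fps), lengths(fps))
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(feats), length(fps)),
                       dimnames = list(NULL, names(fps)))
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fps a `fingerprint_set` (or named list of feature vectors)
#' @return dense symmetric matrix of similarities with unit diagonal
#' @export
tanimoto_matrix <- function(fps) {
  if (any(lengths(fps) == 0)) stop("cannot compare an empty fingerprint")
  X <- fp_incidence(fps)
  inter <- as.matrix(Matrix::crossprod(X))
  sizes <- Matrix::colSums(X)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- inter / uni
  dimnames(sim) <- list(names(fps), names(fps))
  sim
}
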