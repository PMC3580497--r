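test_that("edges require similarity strictly above the cutoff", {
  fps <- structure(list(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4),
                        C = c(3, 4, 5, 6), D = c(100, 101)),
                   class = "fingerprint_set")
  # A~B identical (1.0), A~C = 2/6 = 1/3, C at exactly 0.5 vs E below
  net <- build_network(fps, cutoff = 0.5)
  expect_equal(igraph::ecount(net), 1)
  expect_equal(sort(igraph::ends(net, 1)), c("A", "B"))
  expect_equal(igraph::E(net)$weight, 1)
  expect_equal(sum(igraph::V(net)$isolated), 2)

  # a pair at exactly the cutoff is not connected
  half <- structure(list(X = c(1, 2), Y = c(1, 2, 3, 4)),
                    class = "fingerprint_set")
  expect_equal(igraph::ecount(build_network(half, cutoff = 0.5)), 0)
  expect_equal(igraph::ecount(build_network(half, cutoff = 0.49)), 1)

  # cutoff 1 keeps only exact duplicates... of which there are none at 1.0
  expect_equal(igraph::ecount(build_network(fps, cutoff = 1)), 0)
  expect_error(build_network(fps, cutoff = 1.5), "cutoff")
})

test_that("the edge set is invariant to input order and monotone in cutoff", {
  fx <- fp_fixture()
  fps <- compute_fingerprints(fx$smiles, ids = sprintf("M%02d", seq_len(nrow(fx))))
  edge_key <- function(net) {
    el <- igraph::as_edgelist(net)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  n1 <- build_network(fps, cutoff = 0.2)
  perm <- rev(seq_along(fps))
  fps_rev <- structure(unclass(fps)[perm], class = "fingerprint_set")
  n2 <- build_network(fps_rev, cutoff = 0.2)
  expect_identical(edge_key(n1), edge_key(n2))
  # lowering the cutoff never removes edges
  for (cut in c(0.5, 0.35, 0.2, 0.1)) {
    e <- edge_key(build_network(fps, cutoff = cut))
    if (exists("prev_e")) expect_true(all(prev_e %in% e))
    prev_e <- e
  }
})

test_that("phenotype attributes map to the figure's colors and shapes", {
  fps <- structure(list(A = 1:3, B = 1:3, C = 1:3, D = 1:3, E = 1:3),
                   class = "fingerprint_set")
  net <- build_network(fps, cutoff = 0.5)
  fitness <- data.frame(compound_id = c("A", "B", "C", "D"),
                        is_hit = c(TRUE, FALSE, TRUE, FALSE))
  acute <- data.frame(
    compound_id = c("A", "B", "C", "D"),
    motility_class = c("motility_inhibited", "sign_reversed", "normal",
                       "normal"),
    photosynthesis_hit = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  expect_warning(net <- annotate_network(net, fitness, acute), "E")
  v <- igraph::vertex_attr(net)
  i <- match(c("A", "B", "C", "D", "E"), v$name)
  expect_equal(v$color[i], c("green", "blue", "red", "white", NA))
  expect_equal(v$shape[i], c("circle", "diamond", "circle", "diamond", NA))
})

test_that("cluster summaries report per-component percentages", {
  # two pairs of identical molecules plus a singleton
  fps <- structure(list(A = 1:4, B = 1:4, C = 11:14, D = 11:14, E = 21:24),
                   class = "fingerprint_set")
  net <- build_network(fps, cutoff = 0.5)
  fitness <- data.frame(compound_id = c("A", "B", "C", "D", "E"),
                        is_hit = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  acute <- data.frame(compound_id = c("A", "B", "C", "D", "E"),
                      motility_class = "normal",
                      photosynthesis_hit = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  cs <- cluster_summary(annotate_network(net, fitness, acute))
  expect_equal(nrow(cs), 3)
  ab <- cs[cs$size == 2 & cs$pct_photosynthesis == 100, ]
  expect_equal(ab$pct_fitness, 50)
  single <- cs[cs$size == 1, ]
  expect_equal(single$pct_fitness, 100)
})

test_that("network exports load back with attributes intact", {
  fps <- structure(list(A = 1:4, B = 1:4, C = 9:10),
                   class = "fingerprint_set")
  net <- build_network(fps, cutoff = 0.5)
  fitness <- data.frame(compound_id = c("A", "B", "C"),
                        is_hit = c(TRUE, FALSE, FALSE))
  net <- suppressWarnings(annotate_network(net, fitness, NULL))
  sif <- withr::local_tempfile(fileext = ".sif")
  attrs <- withr::local_tempfile(fileext = ".csv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_sif(net, sif, attrs)
  lines <- readLines(sif)
  expect_true("A pp B" %in% lines)
  expect_true("C" %in% lines) # isolated node retained
  adf <- read.csv(attrs)
  expect_equal(nrow(adf), 3)
  write_network_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 1)
  expect_setequal(igraph::V(back)$name, c("A", "B", "C"))
})
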