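test_that("graph construction enforces simple undirected structure", {
  g <- ppi_graph(data.frame(from = c("a", "a", "b", "c"),
                            to = c("b", "b", "b", "c")))
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 1L)  # multi-edge collapsed, loop dropped
  expect_false(igraph::any_loop(g))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_a\tprotein_b\tweight", "A\tB\t0.9", "B\tC\t0.8"), tsv)
  g2 <- read_edge_list(tsv)
  expect_equal(sort(igraph::V(g2)$name), c("A", "B", "C"))
  expect_equal(igraph::ecount(g2), 2L)
})

test_that("subgraph centrality matches closed forms and the series oracle", {
  # isolated node: e^0 = 1
  iso <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(iso)$name <- "x"
  expect_equal(unname(subgraph_centrality(iso)), 1)

  # K2: cosh(1) per node
  k2 <- ppi_graph(data.frame(from = "a", to = "b"))
  expect_equal(unname(subgraph_centrality(k2)), rep(cosh(1), 2),
               tolerance = 1e-10)

  # triangle: e^2/3 + 2 e^-1 / 3 per node
  tri <- ppi_graph(data.frame(from = c("a", "b", "c"),
                              to = c("b", "c", "a")))
  expect_equal(unname(subgraph_centrality(tri)),
               rep(exp(2) / 3 + 2 * exp(-1) / 3, 3), tolerance = 1e-10)

  # random graphs vs the truncated power series
  for (s in 1:10) {
    g <- random_named_gnp(sample(4:12, 1), 0.4, seed = 100 + s)
    expect_equal(subgraph_centrality(g), series_subgraph_centrality(g),
                 tolerance = 1e-8)
  }
})

test_that("betweenness matches brute-force path enumeration", {
  path3 <- ppi_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
  cb <- betweenness_centrality(path3)
  expect_equal(cb[["b"]], 1)
  expect_equal(cb[["a"]], 0)

  star <- ppi_graph(data.frame(from = "hub", to = c("l1", "l2", "l3")))
  expect_equal(betweenness_centrality(star)[["hub"]], 3)

  k4 <- ppi_graph(as.data.frame(t(combn(letters[1:4], 2))))
  expect_true(all(betweenness_centrality(k4) == 0))

  for (s in 1:12) {
    g <- random_named_gnp(sample(5:9, 1), 0.35, seed = 200 + s)
    expect_equal(betweenness_centrality(g), brute_betweenness(g),
                 tolerance = 1e-10)
  }
})

test_that("closeness follows the component-size form and literal variant", {
  star <- ppi_graph(data.frame(from = "hub", to = c("l1", "l2", "l3")))
  cc <- closeness_centrality(star)
  expect_equal(cc[["hub"]], 1.0)
  expect_equal(cc[["l1"]], 3 / 5)

  k5 <- ppi_graph(as.data.frame(t(combn(letters[1:5], 2))))
  expect_true(all(closeness_centrality(k5) == 1))

  # literal variant: neighbor-count numerator
  lit <- closeness_centrality(star, variant = "literal")
  expect_equal(lit[["hub"]], (3 - 1) / 3)
  expect_equal(lit[["l1"]], 0)  # degree 1 - 1 = 0

  # disconnected graphs: per-component values, singletons 0
  two <- ppi_graph(data.frame(from = c("a", "c"), to = c("b", "d")))
  two <- igraph::add_vertices(two, 1, name = "z")
  cc2 <- closeness_centrality(two)
  expect_equal(cc2[["a"]], 1)
  expect_equal(cc2[["z"]], 0)
})

test_that("centralities are invariant under node relabeling", {
  g <- random_named_gnp(10, 0.3, seed = 42)
  perm <- aconiqstr:::local_seed(43, sample(10))
  g2 <- igraph::permute(g, perm)
  for (f in list(subgraph_centrality, betweenness_centrality,
                 closeness_centrality)) {
    a <- f(g); b <- f(g2)
    expect_equal(a[sort(names(a))], b[sort(names(b))], tolerance = 1e-10)
  }
})

test_that("top-decile overlap honors ties and planted hubs", {
  # one node strictly top in all three measures
  star10 <- ppi_graph(data.frame(from = "hub", to = paste0("l", 1:9)))
  tab <- centrality_table(star10, top = 0.10)
  expect_identical(top_decile_overlap(tab), "hub")

  # total tie: every node flagged, intersection = all nodes
  ring <- ppi_graph(data.frame(from = letters[1:6],
                               to = letters[c(2:6, 1)]))
  tabr <- centrality_table(ring, top = 0.10)
  expect_setequal(top_decile_overlap(tabr), letters[1:6])

  # planted hubs recovered
  g <- gen_ba_network(100, 5, seed = 3)
  sub <- top_decile_overlap(centrality_table(g))
  expect_true(all(attr(g, "hubs") %in% sub))

  # pairwise merge is a superset of the strict intersection
  expect_true(all(top_decile_overlap(tab) %in%
                    top_decile_overlap(tab, merge = "pairwise")))
})

test_that("cluster metrics follow their closed forms", {
  tri <- ppi_graph(data.frame(from = c("a", "b", "c"),
                              to = c("b", "c", "a")))
  cm <- cluster_metrics(tri, c("a", "b", "c"), n_perm = 99, seed = 1)
  expect_equal(cm$density, 1)
  expect_equal(cm$quality, 1)

  # independent set inside a larger graph: zero density
  g <- make_planted_clique_graph(seed = 5)
  far <- setdiff(igraph::V(g)$name, attr(g, "clique"))
  # pick nodes with no edges among them
  sub <- far[1]
  for (v in far[-1]) {
    if (!any(igraph::are_adjacent(g, v, sub))) sub <- c(sub, v)
    if (length(sub) == 4) break
  }
  cmi <- cluster_metrics(g, sub, n_perm = 99, seed = 2)
  expect_equal(cmi$density, 0)

  expect_error(cluster_metrics(tri, "a", n_perm = 99), "at least 2")
  expect_error(cluster_metrics(tri, c("a", "b"), n_perm = 10), "at least 99")
  # deterministic under seed
  a <- cluster_metrics(g, attr(g, "clique"), n_perm = 199, seed = 7)
  b <- cluster_metrics(g, attr(g, "clique"), n_perm = 199, seed = 7)
  expect_identical(a, b)
})

test_that("cluster filtering applies the four thresholds at the boundary", {
  mk <- function(size, density, quality, p) {
    structure(list(members = letters[1:size], size = size,
                   density = density, quality = quality, p_value = p),
              class = "cluster_metrics")
  }
  pass <- mk(6, 1, 0.6, 0.001)
  small <- mk(2, 1, 1, 0.001)
  thin <- mk(6, 0.44, 0.9, 0.001)
  weak <- mk(6, 0.9, 0.49, 0.001)
  insig <- mk(6, 0.9, 0.9, 0.05)
  kept <- filter_clusters(list(pass, small, thin, weak, insig))
  expect_equal(attr(kept, "accepted"), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # boundary values 0.45 / 0.5 are inclusive, p = 0.05 exclusive
  expect_equal(attr(filter_clusters(mk(3, 0.45, 0.5, 0.0499)), "accepted"),
               TRUE)
})

test_that("target intersection ranks shared subnetwork proteins", {
  hits <- list(
    c1 = data.frame(protein = c("P1", "P2", "P3"), score = c(9, 8, 7)),
    c2 = data.frame(protein = c("P2", "P1", "P4"), score = c(9, 5, 4)),
    c3 = data.frame(protein = c("P1", "P2", "P5"), score = c(7, 9, 2)))
  out <- intersect_targets(c("P1", "P2", "P9"), hits)
  expect_equal(out$protein, c("P2", "P1"))  # mean scores 8.667 vs 7
  expect_equal(out$mean_score[1], mean(c(8, 9, 9)))

  # disjoint lists: empty result
  disj <- list(a = data.frame(protein = "X", score = 1),
               b = data.frame(protein = "Y", score = 1))
  expect_equal(nrow(intersect_targets(c("X", "Y"), disj)), 0L)

  # ids outside the subnetwork are reported, not fatal
  expect_message(intersect_targets("P1", hits), "dropped: P2")
})
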