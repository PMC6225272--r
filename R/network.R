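#' Build a simple protein-protein interaction graph
#'
#' Accepts a two- or three-column edge table (node, node, optional
#' weight), drops self-loops, and collapses multi-edges (summing weights).
#'
#' @param edges Data frame or matrix; first two columns are node ids,
#'   optional third column a positive weight (default 1).
#' @return An undirected simple `igraph` object.
#' @export
ppi_graph <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edge table needs at least two columns")
  names(edges)[1:2] <- c("from", "to")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (ncol(edges) >= 3L) names(edges)[3] <- "weight" else edges$weight <- 1
  g <- igraph::graph_from_data_frame(edges[, c("from", "to", "weight")],
                                     directed = FALSE)
  igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE,
                   edge.attr.comb = list(weight = "sum"))
}

#' Read an edge-list TSV into a PPI graph
#'
#' @param path TSV with two node-id columns and an optional weight column;
#'   a header line is detected and skipped.
#' @return An `igraph` object (see [ppi_graph()]).
#' @export
read_edge_list <- function(path) {
  first <- utils::read.delim(path, nrows = 1, header = FALSE,
                             stringsAsFactors = FALSE)
  header <- ncol(first) >= 3 && is.na(suppressWarnings(as.numeric(first[[3]])))
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  ppi_graph(df)
}

adjacency_dense <- function(graph, weighted = TRUE) {
  attr <- if (weighted && "weight" %in% igraph::edge_attr_names(graph))
    "weight" else NULL
  as.matrix(igraph::as_adjacency_matrix(graph, attr = attr, sparse = TRUE))
}

#' Subgraph centrality
#'
#' Participation of each node in all closed walks of the network, with
#' short walks weighted most:
#' `CS(u) = sum_v (v_vu)^2 exp(lambda_v)`, the diagonal of the adjacency
#' matrix exponential, computed from the symmetric eigendecomposition.
#' An isolated node scores exactly 1.
#'
#' @param graph An `igraph` object.
#' @param weighted Use edge weights in the adjacency matrix (default TRUE).
#' @return Named numeric vector of per-node CS values.
#' @export
subgraph_centrality <- function(graph, weighted = TRUE) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  A <- adjacency_dense(graph, weighted)
  eg <- eigen(A, symmetric = TRUE)
  cs <- rowSums(eg$vectors^2 %*% diag(exp(eg$values), n, n))
  stats::setNames(cs, igraph::V(graph)$name)
}

#' Shortest-path betweenness centrality
#'
#' `CB(u) = sum over unordered pairs s != u != t of the fraction of
#' shortest s-t paths passing through u`; pairs in different components
#' contribute zero. Paths are hop-count shortest paths (edge weights are
#' ignored, matching the screening convention for interaction networks).
#'
#' @param graph An `igraph` object.
#' @return Named numeric vector of per-node CB values.
#' @export
betweenness_centrality <- function(graph) {
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA)
  stats::setNames(as.numeric(b), igraph::V(graph)$name)
}

#' Closeness centrality
#'
#' Standard variant (default): within each connected component of size
#' `k`, `CC(u) = (k - 1) / sum_v dist(u, v)`, which is 1 for a node
#' adjacent to every other node of its component and 0 for singletons.
#' The `literal` variant replaces the numerator by `deg(u) - 1` (the
#' node's neighbor count minus one), a non-standard form kept for
#' comparability with screening tools that print it.
#'
#' @param graph An `igraph` object.
#' @param variant `"standard"` or `"literal"`.
#' @return Named numeric vector of per-node CC values.
#' @export
closeness_centrality <- function(graph, variant = c("standard", "literal")) {
  variant <- match.arg(variant)
  n <- igraph::vcount(graph)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  dmat <- igraph::distances(graph, weights = NA)
  comp <- igraph::components(graph)
  cc <- vapply(seq_len(n), function(u) {
    same <- comp$membership == comp$membership[u]
    k <- sum(same)
    if (k < 2L) return(0)
    tot <- sum(dmat[u, same])
    num <- if (variant == "standard") k - 1
           else igraph::degree(graph)[u] - 1
    num / tot
  }, numeric(1))
  stats::setNames(cc, igraph::V(graph)$name)
}

#' Centrality table with top-decile flags
#'
#' Computes subgraph, betweenness and closeness centrality for every node
#' and flags, per measure, the top `ceiling(top * n)` nodes; ties at the
#' decile boundary are all included (inclusive rule, favoring recall of
#' essential proteins).
#'
#' @param graph An `igraph` object.
#' @param top Fraction per measure (default 0.10).
#' @param closeness_variant Passed to [closeness_centrality()].
#' @return Data frame with columns `node`, `subgraph`, `betweenness`,
#'   `closeness` and logical `top_*` flags.
#' @export
centrality_table <- function(graph, top = 0.10,
                             closeness_variant = "standard") {
  cs <- subgraph_centrality(graph)
  cb <- betweenness_centrality(graph)
  cc <- closeness_centrality(graph, closeness_variant)
  n <- length(cs)
  top_flag <- function(v) {
    if (n == 0L) return(logical(0))
    k <- ceiling(top * n)
    thr <- sort(v, decreasing = TRUE)[min(k, n)]
    # boundary ties are inclusive; tolerance absorbs eigensolver jitter
    v >= thr - 1e-9 * max(1, abs(thr))
  }
  data.frame(node = names(cs), subgraph = as.numeric(cs),
             betweenness = as.numeric(cb), closeness = as.numeric(cc),
             top_subgraph = top_flag(cs), top_betweenness = top_flag(cb),
             top_closeness = top_flag(cc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap of the three top-decile sets
#'
#' Nodes flagged top-decile under subgraph, betweenness and closeness
#' centrality simultaneously (`merge = "intersection"`, default), or
#' under at least two of the three measures
#' (`merge = "pairwise"`), the union-of-pairwise-overlaps reading.
#'
#' @param table Output of [centrality_table()].
#' @param merge `"intersection"` or `"pairwise"`.
#' @return Character vector of node ids.
#' @export
top_decile_overlap <- function(table, merge = c("intersection", "pairwise")) {
  merge <- match.arg(merge)
  f <- table[, c("top_subgraph", "top_betweenness", "top_closeness")]
  keep <- if (merge == "intersection") rowSums(f) == 3L else rowSums(f) >= 2L
  table$node[keep]
}

#' Quality metrics of one candidate cluster
#'
#' For a node set of size `k` with `m_in` internal edges:
#' density `= 2 m_in / (k (k - 1))`; cohesiveness quality
#' `= w_in / (w_in + w_boundary)` where `w_in` is the total internal edge
#' weight and `w_boundary` the weight of edges leaving the set; and a
#' permutation p-value: the tail probability, with add-one continuity
#' correction, that a uniformly random k-node set has density at least as
#' high, estimated from `n_perm` seeded draws.
#'
#' @param graph An `igraph` object.
#' @param members Character vector of member node ids (at least 2).
#' @param n_perm Number of permutation draws (default 999, minimum 99).
#' @param seed Seed for the permutation draws.
#' @return An object of class `cluster_metrics`: `members`, `size`,
#'   `density`, `quality`, `p_value`.
#' @export
cluster_metrics <- function(graph, members, n_perm = 999, seed = 1) {
  members <- as.character(members)
  nodes <- igraph::V(graph)$name
  if (!all(members %in% nodes)) stop("cluster members missing from graph")
  k <- length(members)
  if (k < 2L) stop("a cluster needs at least 2 members")
  if (n_perm < 99L) stop("use at least 99 permutation draws")
  dens <- function(mem) {
    sub <- igraph::induced_subgraph(graph, mem)
    2 * igraph::ecount(sub) / (k * (k - 1))
  }
  density <- dens(members)
  w <- if ("weight" %in% igraph::edge_attr_names(graph))
    igraph::E(graph)$weight else rep(1, igraph::ecount(graph))
  ends <- igraph::ends(graph, igraph::E(graph))
  in1 <- ends[, 1] %in% members; in2 <- ends[, 2] %in% members
  w_in <- sum(w[in1 & in2])
  w_bound <- sum(w[xor(in1, in2)])
  quality <- if (w_in + w_bound == 0) 0 else w_in / (w_in + w_bound)
  perm <- local_seed(seed, vapply(seq_len(n_perm), function(i)
    dens(sample(nodes, k)), numeric(1)))
  p_value <- (1 + sum(perm >= density)) / (n_perm + 1)
  structure(list(members = members, size = k, density = density,
                 quality = quality, p_value = p_value),
            class = "cluster_metrics")
}

#' @export
print.cluster_metrics <- function(x, ...) {
  cat(sprintf(
    "<cluster_metrics> k=%d density=%.3f quality=%.3f p=%.4f\n",
    x$size, x$density, x$quality, x$p_value))
  invisible(x)
}

#' Accept or discard candidate clusters
#'
#' Keeps a cluster iff size >= `min_size` AND density >= `min_density`
#' AND quality >= `min_quality` AND p-value < `max_p` (defaults 3, 0.45,
#' 0.5, 0.05 — the conventional screening thresholds).
#'
#' @param metrics A `cluster_metrics` object or a list of them.
#' @param min_size,min_density,min_quality,max_p Thresholds.
#' @return The accepted subset (a list), with attribute `"accepted"`
#'   giving the logical keep vector.
#' @export
filter_clusters <- function(metrics, min_size = 3, min_density = 0.45,
                            min_quality = 0.5, max_p = 0.05) {
  if (inherits(metrics, "cluster_metrics")) metrics <- list(metrics)
  keep <- vapply(metrics, function(m)
    m$size >= min_size && m$density >= min_density &&
      m$quality >= min_quality && m$p_value < max_p, logical(1))
  structure(metrics[keep], accepted = keep)
}

#' Intersect a screened subnetwork with pharmacophore hit lists
#'
#' Returns the proteins present in every hit list and in the subnetwork,
#' ranked by decreasing mean fit score across the lists. Hit-list ids
#' absent from the subnetwork universe are reported via `message()` and
#' dropped, never fatal.
#'
#' @param subnetwork Character vector of node ids (e.g. from
#'   [top_decile_overlap()]).
#' @param hit_lists Named list of data frames, each with columns `protein`
#'   and `score` (one ranked hit list per query compound).
#' @return Data frame `protein`, `mean_score`, sorted by score.
#' @export
intersect_targets <- function(subnetwork, hit_lists) {
  stopifnot(length(hit_lists) >= 1L)
  hit_lists <- lapply(hit_lists, function(h) {
    h <- as.data.frame(h)
    stopifnot(all(c("protein", "score") %in% names(h)))
    h$protein <- as.character(h$protein)
    h
  })
  common <- Reduce(intersect, lapply(hit_lists, `[[`, "protein"))
  unmapped <- setdiff(common, subnetwork)
  if (length(unmapped))
    message("hit-list proteins outside the subnetwork dropped: ",
            paste(unmapped, collapse = ", "))
  hits <- intersect(common, subnetwork)
  if (length(hits) == 0L)
    return(data.frame(protein = character(0), mean_score = numeric(0)))
  ms <- vapply(hits, function(p)
    mean(vapply(hit_lists, function(h) h$score[match(p, h$protein)],
                numeric(1))), numeric(1))
  out <- data.frame(protein = hits, mean_score = as.numeric(ms),
                    stringsAsFactors = FALSE)
  out[order(-out$mean_score), , drop = FALSE]
}
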