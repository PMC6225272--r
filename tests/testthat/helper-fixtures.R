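# Shared builders and independent oracles used across the suite.

make_methane <- function() {
  aligned_molecule("methane", c("C", "H", "H", "H", "H"),
    coords = rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
                   c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89)),
    bonds = data.frame(from = 1, to = 2:5, order = 1))
}

make_ethanol <- function() {
  aligned_molecule("ethanol",
    c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    coords = rbind(c(-0.89, 0.16, 0), c(0.46, -0.51, 0), c(1.51, 0.43, 0),
                   c(-0.97, 0.79, 0.89), c(-0.97, 0.79, -0.89),
                   c(-1.69, -0.58, 0), c(0.56, -1.15, 0.88),
                   c(0.56, -1.15, -0.88), c(2.36, -0.03, 0)),
    bonds = data.frame(from = c(1, 2, 1, 1, 1, 2, 2, 3),
                       to = c(2, 3, 4, 5, 6, 7, 8, 9), order = 1))
}

# molecule with one charged probe-target atom plus two far, inert atoms,
# so single-atom closed forms apply at the near grid point
make_lone_atom <- function(element = "C", charge = 0, at = c(0, 0, 0)) {
  aligned_molecule("lone", c(element, "H", "H"),
    coords = rbind(at, c(500, 500, 500), c(503, 500, 500)),
    charges = c(charge, 0, 0))
}

# Adjacency matrix of a seeded Erdos-Renyi igraph with letter names
random_named_gnp <- function(n, p, seed) {
  g <- aconiqstr:::local_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

# Independent oracle: subgraph centrality by truncated power series
# sum_{l=0}^{terms} diag(A^l) / l!
series_subgraph_centrality <- function(graph, terms = 30) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  n <- nrow(A)
  acc <- diag(n)
  out <- diag(acc)
  Ak <- diag(n)
  for (l in seq_len(terms)) {
    Ak <- Ak %*% A
    out <- out + diag(Ak) / factorial(l)
  }
  stats::setNames(out, igraph::V(graph)$name)
}

# Independent oracle: betweenness by exhaustive shortest-path enumeration
# over the raw adjacency matrix (no igraph shortest-path machinery).
brute_betweenness <- function(graph) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph)) > 0
  n <- nrow(A)
  # BFS distances from every source
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ])
        new <- nb[d[nb] == Inf]
        d[new] <- d[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
  }
  # enumerate all shortest paths between a pair by DFS on the distance DAG
  paths_through <- function(s, t) {
    count <- rep(0, n); total <- 0
    rec <- function(v, visited) {
      if (v == t) {
        total <<- total + 1
        inner <- setdiff(visited, c(s, t))
        count[inner] <<- count[inner] + 1
        return(invisible())
      }
      for (w in which(A[v, ])) {
        if (dist[s, w] == dist[s, v] + 1 && dist[w, t] == dist[v, t] - 1)
          rec(w, c(visited, w))
      }
    }
    rec(s, s)
    list(count = count, total = total)
  }
  cb <- rep(0, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dist[s, t]) || dist[s, t] == 0) next
    pt <- paths_through(s, t)
    if (pt$total > 0) cb <- cb + pt$count / pt$total
  }
  stats::setNames(cb, igraph::V(graph)$name)
}

# 60-node sparse background with a 6-clique planted on the first 6 nodes
make_planted_clique_graph <- function(seed = 11, n = 60, p_bg = 0.035,
                                      k = 6) {
  g <- aconiqstr:::local_seed(seed, igraph::sample_gnp(n, p_bg))
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  members <- sprintf("N%02d", seq_len(k))
  g <- igraph::simplify(
    igraph::add_edges(g, as.character(utils::combn(members, 2))))
  attr(g, "clique") <- members
  g
}
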