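#' Generate a latent-structure QSTR dataset
#'
#' Emulates the statistical structure a molecular-field QSTR assumes: the
#' descriptor matrix is `X = T P' + E` with `n_comp` Gaussian latent
#' scores `T` at geometrically decreasing scales (sd `2^(n_comp - k)` for
#' component `k`, so each planted dimension carries its own variance
#' tier and the optimum component count is well defined), orthonormal
#' loadings `P`, and i.i.d. Gaussian column noise of sd `x_noise_sd`
#' (defaulting to `noise_sd`); the activity is `y = T q + f` with unit
#' latent weights (`q = 1`) and Gaussian noise `f` of sd `noise_sd`. The
#' planted truth (`T`, `P`, `q`, the implied descriptor-space
#' coefficients `beta = P q`) is attached as attribute `"truth"` for
#' recovery tests. Columns are split evenly between two pseudo-fields and
#' a 3:1 activity-stratified train/test split is assigned.
#'
#' @param n_mol Number of molecules (must exceed `n_comp + 2`).
#' @param n_cols Number of descriptor columns.
#' @param n_comp Number of planted latent components.
#' @param noise_sd Activity-noise standard deviation.
#' @param x_noise_sd Descriptor-noise standard deviation (defaults to
#'   `noise_sd`; set separately to decouple the population R2 of the
#'   activity from descriptor degradation).
#' @param seed RNG seed (bit-reproducible output).
#' @return A [qstr_dataset()] with attribute `"truth"`.
#' @export
gen_latent_qstr <- function(n_mol = 33, n_cols = 60, n_comp = 3,
                            noise_sd = 0.1, x_noise_sd = noise_sd,
                            seed = 1) {
  if (n_mol <= n_comp + 2L) stop("need n_mol > n_comp + 2")
  if (n_cols < n_comp) stop("need n_cols >= n_comp")
  out <- local_seed(seed, {
    Tm <- matrix(stats::rnorm(n_mol * n_comp), n_mol, n_comp)
    Tm <- sweep(Tm, 2, 2^(n_comp - seq_len(n_comp)), `*`)
    P <- qr.Q(qr(matrix(stats::rnorm(n_cols * n_comp), n_cols, n_comp)))
    q <- rep(1, n_comp)
    X <- tcrossprod(Tm, P) +
      x_noise_sd * matrix(stats::rnorm(n_mol * n_cols), n_mol, n_cols)
    y <- as.numeric(Tm %*% q) + noise_sd * stats::rnorm(n_mol)
    list(Tm = Tm, P = P, q = q, X = X, y = y)
  })
  colnames(out$X) <- paste0(rep(c("fieldA", "fieldB"),
                                c(ceiling(n_cols / 2), floor(n_cols / 2))),
                            "_", seq_len(n_cols))
  rownames(out$X) <- sprintf("mol%02d", seq_len(n_mol))
  meta <- data.frame(grid_index = seq_len(n_cols),
                     field = sub("_[0-9]+$", "", colnames(out$X)),
                     stringsAsFactors = FALSE)
  block <- structure(list(matrix = out$X, column_meta = meta,
                          dropped_columns = character(0),
                          grid = NULL, type = "synthetic"),
                     class = "field_block")
  ds <- qstr_dataset(block, out$y, ratio = 3, seed = seed + 1L)
  attr(ds, "truth") <- list(scores = out$Tm, loadings = out$P, q = out$q,
                            beta = as.numeric(out$P %*% out$q),
                            n_comp = n_comp)
  ds
}

#' Generate random point-atom molecules in a shared frame
#'
#' Atoms are placed uniformly in a cubic box, elements drawn from a small
#' organic palette, and partial charges drawn from a centered normal and
#' shifted to sum exactly to zero. No connectivity is generated; property
#' weights come from the element rules of [atom_properties()]. Useful for
#' property-based testing of the field engines.
#'
#' @param n_mol Number of molecules.
#' @param n_atoms Atoms per molecule (>= 3).
#' @param box Edge length of the cubic frame in Angstrom.
#' @param seed RNG seed.
#' @return List of [aligned_molecule()] objects.
#' @export
gen_point_molecules <- function(n_mol = 5, n_atoms = 8, box = 8, seed = 1) {
  if (n_atoms < 3L) stop("need at least 3 atoms per molecule")
  palette <- c("C", "C", "C", "N", "O", "H")
  local_seed(seed, lapply(seq_len(n_mol), function(i) {
    el <- sample(palette, n_atoms, replace = TRUE)
    xyz <- matrix(stats::runif(n_atoms * 3, -box / 2, box / 2), n_atoms, 3)
    q <- stats::rnorm(n_atoms, sd = 0.2)
    q <- q - mean(q)
    aligned_molecule(sprintf("pm%02d", i), el, xyz, charges = q)
  }))
}

#' Generate a hub-rich interaction network with planted hubs
#'
#' A preferential-attachment background graph over the non-hub nodes plus
#' `n_hubs` planted hubs: each hub is wired to a random `hub_frac`
#' fraction of the full node set and the hubs form a clique among
#' themselves, mimicking the densely interconnected essential-protein
#' core of curated cardiotoxicity interaction networks. The background
#' default of one attachment edge per node gives a sparse, tree-like
#' periphery so the planted hubs are the unambiguous centrality truth;
#' denser backgrounds grow emergent hubs of their own and blur the
#' planted structure. The hub ids are attached as attribute `"hubs"`.
#'
#' @param n_nodes Total node count (must exceed `3 * n_hubs`).
#' @param n_hubs Number of planted hubs.
#' @param hub_frac Fraction of nodes each hub attaches to (default 1/3,
#'   at least 30 percent by construction intent).
#' @param m Preferential-attachment edges per background node (default 1).
#' @param seed RNG seed.
#' @return An undirected simple `igraph` with attribute `"hubs"`.
#' @export
gen_ba_network <- function(n_nodes = 100, n_hubs = 5, hub_frac = 1 / 3,
                           m = 1, seed = 1) {
  if (n_nodes <= 3L * n_hubs) stop("need n_nodes > 3 * n_hubs")
  g <- local_seed(seed, {
    n_bg <- n_nodes - n_hubs
    bg <- igraph::sample_pa(n_bg, m = m, directed = FALSE)
    bg_names <- sprintf("P%03d", seq_len(n_bg))
    igraph::V(bg)$name <- bg_names
    hub_names <- sprintf("HUB%d", seq_len(n_hubs))
    g <- igraph::add_vertices(bg, n_hubs, name = hub_names)
    k_attach <- ceiling(hub_frac * n_nodes)
    new_edges <- character(0)
    for (h in hub_names) {
      targets <- sample(bg_names, min(k_attach, n_bg))
      new_edges <- c(new_edges, rbind(h, targets))
    }
    if (n_hubs > 1L)
      new_edges <- c(new_edges, as.character(utils::combn(hub_names, 2)))
    g <- igraph::add_edges(g, new_edges)
    igraph::simplify(g)
  })
  attr(g, "hubs") <- sprintf("HUB%d", seq_len(n_hubs))
  g
}

#' Generate a ranking table at a fixed Kendall distance from ideal
#'
#' Relevance values are drawn positive (uniform on the pLD50-like range
#' 0.5-5) without ties; the predicted ordering starts from the ideal
#' (descending-relevance) permutation and applies exactly
#' `kendall_distance` adjacent transpositions, each chosen among the
#' currently concordant neighbor pairs so every swap adds exactly one
#' inversion.
#'
#' @param n_items Number of items.
#' @param kendall_distance Number of inversions, in
#'   `0 .. n_items*(n_items-1)/2`.
#' @param seed RNG seed.
#' @return A [ranking_table()] with orderings `ideal` and `predicted`.
#' @export
gen_ranking <- function(n_items = 20, kendall_distance = 0, seed = 1) {
  max_d <- n_items * (n_items - 1) / 2
  if (kendall_distance < 0 || kendall_distance > max_d)
    stop(sprintf("kendall_distance must lie in 0..%d", max_d))
  local_seed(seed, {
    rel <- stats::runif(n_items, 0.5, 5)
    # position vector: pos[i] = rank of item i under the predicted ordering;
    # items indexed in decreasing-relevance order, ideal = identity
    ord <- order(rel, decreasing = TRUE)
    pos_seq <- seq_len(n_items)          # sequence of item indices by position
    for (s in seq_len(kendall_distance)) {
      conc <- which(pos_seq[-n_items] < pos_seq[-1])
      j <- if (length(conc) == 1L) conc else sample(conc, 1L)
      pos_seq[c(j, j + 1L)] <- pos_seq[c(j + 1L, j)]
    }
    # pos_seq lists sorted-item indices by predicted position; convert to
    # per-item ranks in the original item order
    pred_rank_sorted <- order(pos_seq)   # rank of sorted-item k
    pred <- integer(n_items)
    pred[ord] <- pred_rank_sorted
    ideal <- integer(n_items)
    ideal[ord] <- seq_len(n_items)
    ranking_table(sprintf("item%02d", seq_len(n_items)), rel,
                  data.frame(ideal = ideal, predicted = pred))
  })
}

# content hashes of the shipped fixture files
fixture_md5 <- c(
  aconitine_activity.csv = "c4b49a811ab0c362fe4a9883948d11ad",
  aconitine_rankings.csv = "d84ec9187003715bd10d45f950420701",
  cardiotoxicity_proteins.csv = "bb9b3b8ba43ac0e45f273fcd1475a3f2"
)

#' Load the bundled aconitine-alkaloid fixtures
#'
#' Three small plain-text tables shipped with the package: the activity
#' table of the 33 aconitine alkaloids (compound id, CAS number,
#' substituent string, experimental pLD50, external-test flag), the
#' docking-rank table (experimental toxicity rank and the fit-score ranks
#' against the CAMK2G and CAMK2A receptors, PDB 2V7O and 2VZ6), and the
#' literature-frequency list of 12 cardiotoxicity-associated proteins.
#' File contents are checked against frozen MD5 hashes.
#'
#' @return List with elements `activity` (data frame), `rankings` (a
#'   [ranking_table()] with orderings `experimental`, `fit_2V7O`,
#'   `fit_2VZ6`, relevance = experimental pLD50), and `proteins`
#'   (data frame).
#' @export
load_fixtures <- function() {
  dir <- system.file("extdata", package = "aconiqstr")
  files <- names(fixture_md5)
  paths <- file.path(dir, files)
  sums <- tools::md5sum(paths)
  bad <- files[is.na(sums) | sums != fixture_md5]
  if (length(bad))
    stop("fixture checksum mismatch: ", paste(bad, collapse = ", "))
  activity <- utils::read.csv(paths[1], stringsAsFactors = FALSE)
  ranks <- utils::read.csv(paths[2], stringsAsFactors = FALSE)
  proteins <- utils::read.csv(paths[3], stringsAsFactors = FALSE)
  rel <- activity$pld50[match(ranks$compound, activity$compound)]
  rt <- ranking_table(as.character(ranks$compound), rel,
                      data.frame(experimental = ranks$exp_rank,
                                 fit_2V7O = ranks$fit_2V7O,
                                 fit_2VZ6 = ranks$fit_2VZ6))
  list(activity = activity, rankings = rt, proteins = proteins)
}
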