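#' Discounted cumulative gain
#'
#' `DCG = rel_1 + sum_{i >= 2} rel_i / log2(i)` for graded relevance
#' values listed in the order under evaluation (the original
#' Jarvelin-Kekalainen discount: position 1 undiscounted, position i
#' discounted by log2 of its rank).
#'
#' @param relevance Numeric vector of nonnegative graded relevance values
#'   in ranked order.
#' @return The discounted sum.
#' @examples
#' dcg(c(3, 2, 1))  # 3 + 2/1 + 1/log2(3)
#' @export
dcg <- function(relevance) {
  relevance <- as.numeric(relevance)
  p <- length(relevance)
  if (p == 0L) stop("empty relevance list")
  if (any(!is.finite(relevance)) || any(relevance < 0))
    stop("relevance must be finite and nonnegative")
  if (p == 1L) return(relevance)
  relevance[1] + sum(relevance[-1] / log2(seq_len(p)[-1]))
}

#' Ideal discounted cumulative gain
#'
#' The DCG of the relevance values sorted in decreasing order — the best
#' achievable DCG for that relevance multiset (permutation invariant).
#'
#' @param relevance Numeric vector of graded relevance values.
#' @return The ideal DCG.
#' @export
idcg <- function(relevance) {
  dcg(sort(as.numeric(relevance), decreasing = TRUE))
}

#' Assemble a ranking table
#'
#' @param items Character vector of item (compound) ids.
#' @param relevance Nonnegative graded relevance per item; by convention
#'   the experimental pLD50.
#' @param orderings Named data frame / list of integer rank vectors, one
#'   per named ordering (rank 1 = first position); each must be a
#'   permutation of `1..n`.
#' @return An object of class `ranking_table`.
#' @export
ranking_table <- function(items, relevance, orderings) {
  items <- as.character(items)
  n <- length(items)
  relevance <- as.numeric(relevance)
  stopifnot(length(relevance) == n, all(is.finite(relevance)),
            all(relevance >= 0))
  orderings <- as.data.frame(orderings)
  for (nm in names(orderings)) {
    r <- orderings[[nm]]
    if (!setequal(r, seq_len(n)))
      stop(sprintf("ordering '%s' is not a permutation of 1..%d", nm, n))
  }
  structure(list(items = items, relevance = relevance,
                 orderings = orderings),
            class = "ranking_table")
}

#' @export
print.ranking_table <- function(x, ...) {
  cat(sprintf("<ranking_table> %d items, orderings: %s\n",
              length(x$items), paste(names(x$orderings), collapse = ", ")))
  invisible(x)
}

#' Normalized discounted cumulative gain of one ordering
#'
#' Arranges the relevance values in the order given by the named rank
#' column and divides their DCG by the ideal DCG. The result lies in
#' (0, 1] for nonnegative, not-all-zero relevance and equals 1 exactly
#' when the ordering sorts relevance in decreasing order (up to ties).
#'
#' @param table A [ranking_table()].
#' @param ordering Name of one of the table's orderings.
#' @return List with `dcg`, `idcg`, `ndcg`.
#' @export
ndcg <- function(table, ordering) {
  stopifnot(inherits(table, "ranking_table"))
  if (!ordering %in% names(table$orderings))
    stop(sprintf("unknown ordering '%s'", ordering))
  ideal <- idcg(table$relevance)
  if (ideal == 0) stop("all-zero relevance: NDCG undefined")
  d <- dcg(table$relevance[order(table$orderings[[ordering]])])
  list(dcg = d, idcg = ideal, ndcg = d / ideal)
}

#' NDCG of every ordering in a table
#'
#' @param table A [ranking_table()].
#' @param digits Rounding applied to the returned `ndcg` column (default
#'   4, the customary reporting precision); `NA` disables rounding.
#' @return Data frame with one row per ordering: `ordering`, `dcg`,
#'   `idcg`, `ndcg`.
#' @export
ndcg_table <- function(table, digits = 4) {
  rows <- lapply(names(table$orderings), function(nm) {
    r <- ndcg(table, nm)
    data.frame(ordering = nm, dcg = r$dcg, idcg = r$idcg,
               ndcg = if (is.na(digits)) r$ndcg else round(r$ndcg, digits),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read a ranking table from CSV
#'
#' Expects a column `id`, a relevance column (default `relevance`), and
#' one integer rank column per ordering.
#'
#' @param path CSV path.
#' @param relevance_col Name of the relevance column.
#' @return A [ranking_table()].
#' @export
read_ranking_csv <- function(path, relevance_col = "relevance") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(df), relevance_col %in% names(df))
  ord_cols <- setdiff(names(df), c("id", relevance_col))
  ranking_table(df$id, df[[relevance_col]], df[ord_cols])
}
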