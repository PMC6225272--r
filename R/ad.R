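#' Hat-matrix leverages
#'
#' Diagonal of `H = X (X'X)^-1 X'` for a design matrix that already
#' carries its intercept column. For QSTR models the design is the
#' intercept plus the PLS latent scores (raw field descriptors are
#' rank-deficient and would make the normal equations singular).
#'
#' @param design Numeric matrix, n rows > p columns, full column rank.
#' @return Numeric vector of leverages `h_i` with `sum(h) = p` and
#'   `0 <= h_i <= 1`.
#' @export
leverages <- function(design) {
  design <- as.matrix(design)
  n <- nrow(design); p <- ncol(design)
  if (n <= p) stop("need more rows than design columns")
  if (qr(design)$rank < p)
    stop("design is rank deficient; use the latent-score design ",
         "(intercept + PLS scores) instead of raw descriptors")
  xtx_inv <- solve(crossprod(design))
  rowSums((design %*% xtx_inv) * design)
}

#' Critical leverage threshold
#'
#' The conventional warning limit `h* = 3 p / n`, where `p` is the number
#' of model variables plus one (intercept) and `n` the number of training
#' objects.
#'
#' @param p Number of model variables plus one.
#' @param n Number of training objects.
#' @return `3 * p / n`.
#' @export
critical_leverage <- function(p, n) {
  stopifnot(n > 0, p > 0)
  3 * p / n
}

#' Williams-plot applicability-domain report
#'
#' Computes, for every training compound, the leverage in the latent-score
#' design `[1 | T]`, the standardized residual (residual divided by the
#' n-1 residual standard deviation), and the two flag sets: outliers
#' (|standardized residual| > `sigma_limit`, default 3) and high-leverage
#' compounds (h > h* = 3p/n). With zero residual variance all
#' standardized residuals are reported as 0 and nothing is flagged.
#'
#' @param model A fitted `pls_model`.
#' @param dataset The [qstr_dataset()] it was fitted on.
#' @param sigma_limit Outlier threshold in residual-sd units (default 3).
#' @return An object of class `ad_report`: data frame `table` (id, h,
#'   std_residual, outlier, high_leverage) plus `h_star`, `p`, `n`.
#' @export
williams_report <- function(model, dataset, sigma_limit = 3) {
  stopifnot(inherits(model, "pls_model"), inherits(dataset, "qstr_dataset"))
  d <- train_xy(dataset)
  design <- cbind(intercept = 1, model$scores)
  h <- leverages(design)
  res <- d$y - predict(model, d$X)
  s <- stats::sd(res)
  std <- if (!is.finite(s) || s < 1e-14) rep(0, length(res)) else res / s
  p <- ncol(design)
  h_star <- critical_leverage(p, length(res))
  ids <- rownames(d$X)
  if (is.null(ids)) ids <- as.character(seq_along(res))
  tab <- data.frame(id = ids, h = h, std_residual = std,
                    outlier = abs(std) > sigma_limit,
                    high_leverage = h > h_star,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, h_star = h_star, p = p, n = length(res)),
            class = "ad_report")
}

#' @export
print.ad_report <- function(x, ...) {
  cat(sprintf(
    "<ad_report> n=%d, p=%d, h*=%.3f; %d outlier(s), %d high-leverage\n",
    x$n, x$p, x$h_star, sum(x$table$outlier), sum(x$table$high_leverage)))
  invisible(x)
}

#' Write an applicability-domain report to CSV
#'
#' @param report An `ad_report`.
#' @param path Output CSV path.
#' @export
write_ad_csv <- function(report, path) {
  stopifnot(inherits(report, "ad_report"))
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
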