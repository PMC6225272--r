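#' Bundle a field block with activities into a QSTR dataset
#'
#' @param block A `field_block` (or bare numeric matrix, which is wrapped).
#' @param y Numeric vector of pLD50 values, one per molecule.
#' @param is_test Logical vector flagging external-test compounds. When
#'   `NULL`, a seeded activity-stratified split at `ratio` (train:test)
#'   is drawn: compounds are ordered by activity and every
#'   `(ratio+1)`-th one, at a random phase within each stratum, goes to
#'   the test set, so both sets span the activity range.
#' @param ratio Train:test ratio used for the automatic split (default 3).
#' @param seed Seed for the automatic split.
#' @return An object of class `qstr_dataset`.
#' @export
qstr_dataset <- function(block, y, is_test = NULL, ratio = 3, seed = 1) {
  if (is.matrix(block)) {
    nm <- colnames(block)
    fields <- if (!is.null(nm) && all(grepl("^.+_[0-9]+$", nm)))
      sub("_[0-9]+$", "", nm) else rep("x", ncol(block))
    block <- structure(list(matrix = block,
                            column_meta = data.frame(
                              grid_index = seq_len(ncol(block)),
                              field = fields),
                            dropped_columns = character(0),
                            grid = NULL, type = NA),
                       class = "field_block")
  }
  stopifnot(inherits(block, "field_block"))
  n <- nrow(block$matrix)
  y <- as.numeric(y)
  if (length(y) != n || !all(is.finite(y)))
    stop("'y' must be finite with one value per molecule")
  if (is.null(is_test)) {
    is_test <- local_seed(seed, {
      ord <- order(y)
      n_test <- max(1L, round(n / (ratio + 1)))
      grp <- cut(seq_len(n), n_test, labels = FALSE)
      flag <- logical(n)
      for (g in seq_len(n_test)) {
        idx <- ord[grp == g]
        flag[if (length(idx) == 1L) idx else sample(idx, 1L)] <- TRUE
      }
      flag
    })
  }
  stopifnot(length(is_test) == n)
  if (all(is_test)) stop("training set is empty")
  structure(list(block = block, y = y, is_test = as.logical(is_test)),
            class = "qstr_dataset")
}

#' @export
print.qstr_dataset <- function(x, ...) {
  cat(sprintf("<qstr_dataset> %d molecules (%d train / %d test), %d descriptors\n",
              length(x$y), sum(!x$is_test), sum(x$is_test),
              ncol(x$block$matrix)))
  invisible(x)
}

train_xy <- function(dataset) {
  tr <- !dataset$is_test
  list(X = dataset$block$matrix[tr, , drop = FALSE], y = dataset$y[tr])
}

# Core NIPALS on already-centered X, y. Returns latent structure and the
# regression vector in centered-X space.
nipals_pls <- function(Xc, yc, a) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, a); P <- matrix(0, p, a)
  Tm <- matrix(0, n, a); qv <- numeric(a)
  X <- Xc; y <- yc
  for (k in seq_len(a)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop("degenerate descriptor matrix: no covariance left at component ", k)
    w <- w / nw
    tt <- X %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-12)
      stop("degenerate descriptor matrix: zero-variance score at component ", k)
    p_k <- crossprod(X, tt) / tt2
    q_k <- sum(y * tt) / tt2
    X <- X - tcrossprod(tt, p_k)
    y <- y - q_k * tt
    W[, k] <- w; P[, k] <- p_k; Tm[, k] <- tt; qv[k] <- q_k
  }
  R <- W %*% solve(crossprod(P, W))
  list(weights = W, loadings = P, scores = Tm, q = qv,
       coefficients = as.numeric(R %*% qv))
}

#' Fit a PLS regression of activity on field descriptors
#'
#' NIPALS decomposition of the column-centered training block; the fit is
#' deterministic for fixed input. Predictions are
#' `y_mean + (X - x_mean) %*% coefficients`.
#'
#' @param dataset A [qstr_dataset()].
#' @param n_components Number of latent components.
#' @return An object of class `pls_model` with the latent structure
#'   (`weights`, `loadings`, `scores`), centering vectors, `coefficients`
#'   in descriptor space, and `n_components`.
#' @export
fit_pls <- function(dataset, n_components) {
  stopifnot(inherits(dataset, "qstr_dataset"), n_components >= 1)
  d <- train_xy(dataset)
  if (nrow(d$X) <= n_components)
    stop("need more training molecules than components")
  x_mean <- colMeans(d$X)
  y_mean <- mean(d$y)
  Xc <- sweep(d$X, 2, x_mean)
  fit <- nipals_pls(Xc, d$y - y_mean, n_components)
  structure(c(fit, list(x_mean = x_mean, y_mean = y_mean,
                        n_components = n_components)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d descriptors\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict activities from a fitted PLS model
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix of descriptors (columns as in training),
#'   a `field_block`, or a `qstr_dataset`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "qstr_dataset")) newdata <- newdata$block
  if (inherits(newdata, "field_block")) newdata <- newdata$matrix
  newdata <- rbind(newdata)
  as.numeric(object$y_mean +
               sweep(newdata, 2, object$x_mean) %*% object$coefficients)
}

#' Leave-one-out cross-validated q2
#'
#' Each training compound is predicted by a model refit without it at the
#' same component count; `q2 = 1 - PRESS / SS` with
#' `SS = sum((y - mean(y))^2)` over the training activities. This is the
#' exact refit loop; the covariance-trick shortcut used by legacy software
#' gives the same numbers.
#'
#' @param dataset A [qstr_dataset()].
#' @param n_components Component count for every refit.
#' @return The cross-validated q2 (can be negative for uninformative X).
#' @export
loo_q2 <- function(dataset, n_components) {
  stopifnot(inherits(dataset, "qstr_dataset"))
  d <- train_xy(dataset)
  n <- nrow(d$X)
  if (n < 3L) stop("need at least 3 training molecules")
  if (n_components >= n - 1L)
    stop("n_components must be below n_train - 1 for LOO refits")
  press <- 0
  for (i in seq_len(n)) {
    Xi <- d$X[-i, , drop = FALSE]; yi <- d$y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    fit <- nipals_pls(sweep(Xi, 2, xm), yi - ym, n_components)
    pred <- ym + sum((d$X[i, ] - xm) * fit$coefficients)
    press <- press + (d$y[i] - pred)^2
  }
  1 - press / sum((d$y - mean(d$y))^2)
}

#' Choose the optimum number of components by LOO q2
#'
#' Scans `1..max_components` (clamped below the LOO feasibility limit) and
#' returns the count maximizing q2, breaking ties toward fewer components.
#'
#' @param dataset A [qstr_dataset()].
#' @param max_components Upper end of the scan (default 10).
#' @param tol Two q2 values closer than `tol` count as tied (default 1e-10).
#' @return Integer component count; the q2 profile is attached as
#'   attribute `"q2"`.
#' @export
select_components <- function(dataset, max_components = 10, tol = 1e-10) {
  stopifnot(max_components >= 1)
  n_train <- sum(!dataset$is_test)
  kmax <- min(max_components, n_train - 2L)
  q2 <- numeric(0)
  for (k in seq_len(kmax)) {
    # a degenerate refit means the latent space is exhausted: stop the scan
    qk <- tryCatch(loo_q2(dataset, k), error = function(e) {
      if (grepl("degenerate", conditionMessage(e))) NA_real_ else stop(e)
    })
    if (is.na(qk)) break
    q2 <- c(q2, qk)
  }
  if (length(q2) == 0L) stop("no usable component count in 1..", kmax)
  best <- which(q2 >= max(q2) - tol)[1L]
  structure(as.integer(best), q2 = q2)
}

#' Training-set fit statistics
#'
#' `r2 = 1 - RSS/SS` on the training compounds,
#' `SEE = sqrt(RSS / (n - c - 1))` and
#' `F = (r2/c) / ((1 - r2)/(n - c - 1))` with `c` latent components
#' (degrees of freedom in the legacy QSAR convention). A perfect fit
#' reports `SEE = 0` and `F = Inf`.
#'
#' @param model A fitted `pls_model`.
#' @param dataset The [qstr_dataset()] it was fitted on.
#' @return List with `r2`, `see`, `f_stat`, `n_train`, `n_components`.
#' @export
model_stats <- function(model, dataset) {
  stopifnot(inherits(model, "pls_model"), inherits(dataset, "qstr_dataset"))
  d <- train_xy(dataset)
  n <- length(d$y); cc <- model$n_components
  if (n <= cc + 1L) stop("need n_train > n_components + 1")
  res <- d$y - predict(model, d$X)
  rss <- sum(res^2)
  ss <- sum((d$y - mean(d$y))^2)
  r2 <- 1 - rss / ss
  see <- sqrt(rss / (n - cc - 1))
  f_stat <- if (rss < 1e-14 * ss || r2 >= 1) Inf
            else (r2 / cc) / ((1 - r2) / (n - cc - 1))
  list(r2 = r2, see = see, f_stat = f_stat, n_train = n, n_components = cc)
}

#' Predictive r2 on the external test set
#'
#' `r2_pred = 1 - PRESS_test / sum_test((y - mean(y_train))^2)`. When the
#' test activities are all equal to the training mean the denominator
#' vanishes and `NA` is returned with a warning.
#'
#' @param model A fitted `pls_model`.
#' @param dataset A [qstr_dataset()] with a non-empty test set.
#' @return Numeric r2_pred (or flagged `NA`).
#' @export
predictive_r2 <- function(model, dataset) {
  stopifnot(inherits(model, "pls_model"), inherits(dataset, "qstr_dataset"))
  te <- dataset$is_test
  if (!any(te)) stop("dataset has no test compounds")
  y_te <- dataset$y[te]
  pred <- predict(model, dataset$block$matrix[te, , drop = FALSE])
  ybar_tr <- mean(dataset$y[!te])
  denom <- sum((y_te - ybar_tr)^2)
  if (denom < 1e-12) {
    warning("test activities equal the training mean; r2_pred undefined")
    return(NA_real_)
  }
  1 - sum((y_te - pred)^2) / denom
}

#' Per-field fraction contributions
#'
#' `fraction_k = sum_{j in field k} |coef_j| sd_j / sum_j |coef_j| sd_j`
#' with column standard deviations taken over the training compounds; the
#' fractions are nonnegative and sum to one.
#'
#' @param model A fitted `pls_model`.
#' @param dataset The [qstr_dataset()] it was fitted on.
#' @return Named numeric vector, one fraction per field.
#' @export
field_fractions <- function(model, dataset) {
  stopifnot(inherits(model, "pls_model"), inherits(dataset, "qstr_dataset"))
  meta <- dataset$block$column_meta
  d <- train_xy(dataset)
  sds <- apply(d$X, 2, stats::sd)
  w <- abs(model$coefficients) * sds
  tot <- sum(w)
  if (tot < 1e-300) {
    fr <- rep(0, length(unique(meta$field)))
    names(fr) <- unique(meta$field)
    return(fr)
  }
  fr <- tapply(w, meta$field, sum) / tot
  fr[unique(meta$field)]
}

#' Standard-deviation-times-coefficient contour grid
#'
#' Exports, for one field, the per-lattice-point `sd_j * coef_j` values
#' together with the favored/disfavored iso-levels at the `hi_pct` and
#' `lo_pct` percentiles of the nonzero values. Visualization is left to
#' external tools (see [write_cube()]).
#'
#' @param model A fitted `pls_model`.
#' @param dataset The [qstr_dataset()] it was fitted on.
#' @param field Field name present in the block's column metadata.
#' @param lo_pct,hi_pct Percentiles (0-100) for the disfavored/favored
#'   levels; defaults 20 and 80.
#' @return List with `grid_index`, `value`, `lo_level`, `hi_level`,
#'   `field`.
#' @export
contour_grid <- function(model, dataset, field, lo_pct = 20, hi_pct = 80) {
  meta <- dataset$block$column_meta
  if (!field %in% meta$field)
    stop(sprintf("unknown field '%s'", field))
  sel <- meta$field == field
  d <- train_xy(dataset)
  sds <- apply(d$X[, sel, drop = FALSE], 2, stats::sd)
  vals <- sds * model$coefficients[sel]
  nz <- vals[vals != 0]
  levels <- if (length(nz) == 0L) c(NA_real_, NA_real_)
            else stats::quantile(nz, c(lo_pct, hi_pct) / 100, names = FALSE)
  list(grid_index = meta$grid_index[sel], value = vals,
       lo_level = levels[1], hi_level = levels[2], field = field)
}

#' Minimum-quality acceptance rule for a QSTR model
#'
#' A model is conventionally called acceptable when the cross-validated
#' q2 exceeds 0.5 and the fitted r2 exceeds 0.6.
#'
#' @param q2,r2 Cross-validated and fitted determination coefficients.
#' @return Logical.
#' @export
model_acceptable <- function(q2, r2) {
  isTRUE(q2 > 0.5) && isTRUE(r2 > 0.6)
}
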