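test_that("noiseless one-factor data are fit exactly", {
  ds <- gen_latent_qstr(n_mol = 20, n_cols = 15, n_comp = 1,
                        noise_sd = 0, seed = 3)
  m <- fit_pls(ds, 1)
  st <- model_stats(m, ds)
  expect_equal(st$r2, 1, tolerance = 1e-9)
  expect_equal(st$see, 0, tolerance = 1e-7)
  expect_equal(st$f_stat, Inf)
  expect_gt(loo_q2(ds, 1), 0.99)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(21)
  X <- matrix(rnorm(15 * 4), 15, 4)
  y <- X %*% c(1, -2, 0.5, 3) + rnorm(15, sd = 0.3)
  colnames(X) <- paste0("x_", 1:4)
  ds <- qstr_dataset(X, y, is_test = rep(FALSE, 15))
  m <- fit_pls(ds, 4)
  ols <- stats::lm.fit(cbind(1, X), as.numeric(y))
  expect_equal(predict(m, X), as.numeric(cbind(1, X) %*% ols$coefficients),
               tolerance = 1e-8)
})

test_that("LOO q2 equals the brute-force refit loop bit for bit", {
  ds <- gen_latent_qstr(n_mol = 16, n_cols = 20, n_comp = 2,
                        noise_sd = 0.2, seed = 8)
  tr <- which(!ds$is_test)
  naive <- local({
    press <- 0
    y <- ds$y[tr]
    for (i in seq_along(tr)) {
      sub <- ds
      sub$block$matrix <- ds$block$matrix[tr[-i], , drop = FALSE]
      sub$y <- y[-i]
      sub$is_test <- rep(FALSE, length(tr) - 1L)
      m <- fit_pls(sub, 2)
      pred <- predict(m, ds$block$matrix[tr[i], , drop = FALSE])
      press <- press + (y[i] - pred)^2
    }
    1 - press / sum((y - mean(y))^2)
  })
  expect_identical(loo_q2(ds, 2), naive)
})

test_that("pure-noise activities give a near-zero or negative q2", {
  ds <- gen_latent_qstr(n_mol = 24, n_cols = 40, n_comp = 3,
                        noise_sd = 0.1, seed = 7)
  ds$y <- aconiqstr:::local_seed(707, rnorm(24))
  expect_lte(loo_q2(ds, 2), 0.2)
})

test_that("component selection recovers planted dimensionality", {
  hits <- vapply(1:5, function(s) {
    ds <- gen_latent_qstr(n_mol = 33, n_cols = 60, n_comp = 3,
                          noise_sd = 0.1, seed = s)
    as.integer(select_components(ds, 8))
  }, integer(1))
  expect_gte(sum(hits == 3L), 4L)

  one <- gen_latent_qstr(n_mol = 20, n_cols = 15, n_comp = 1,
                         noise_sd = 0, seed = 3)
  expect_equal(as.integer(select_components(one, 4)), 1L)

  # centering invariance: shifting y leaves the profile untouched
  ds <- gen_latent_qstr(n_mol = 20, n_cols = 24, n_comp = 2,
                        noise_sd = 0.15, seed = 12)
  shifted <- ds; shifted$y <- ds$y + 100
  expect_equal(as.integer(select_components(ds, 5)),
               as.integer(select_components(shifted, 5)))
})

test_that("fit statistics match an independent residual computation", {
  ds <- gen_latent_qstr(n_mol = 22, n_cols = 30, n_comp = 2,
                        noise_sd = 0.3, seed = 4)
  m <- fit_pls(ds, 2)
  st <- model_stats(m, ds)
  tr <- !ds$is_test
  res <- ds$y[tr] - predict(m, ds$block$matrix[tr, , drop = FALSE])
  n <- sum(tr)
  r2 <- 1 - sum(res^2) / sum((ds$y[tr] - mean(ds$y[tr]))^2)
  expect_equal(st$r2, r2)
  expect_equal(st$see, sqrt(sum(res^2) / (n - 3)))
  expect_equal(st$f_stat, (r2 / 2) / ((1 - r2) / (n - 3)))
  # F formula spot value: r2 = 0.5, n = 22, c = 1 gives exactly 20
  expect_equal((0.5 / 1) / ((1 - 0.5) / (22 - 1 - 1)), 20)
  # r2 is invariant to positive rescaling of y
  sc <- ds; sc$y <- ds$y * 7
  expect_equal(model_stats(fit_pls(sc, 2), sc)$r2, st$r2, tolerance = 1e-12)
})

test_that("predictive r2 behaves at its limits and in expectation", {
  # test set drawn from the training model's exact law scores ~1
  ds <- gen_latent_qstr(n_mol = 24, n_cols = 20, n_comp = 2,
                        noise_sd = 0, seed = 5)
  m <- fit_pls(ds, 2)
  expect_gt(predictive_r2(m, ds), 0.999)
  # degenerate denominator is flagged undefined
  flat <- ds
  flat$y[flat$is_test] <- mean(flat$y[!flat$is_test])
  m2 <- fit_pls(flat, 2)
  expect_warning(r2p <- predictive_r2(m2, flat), "undefined")
  expect_true(is.na(r2p))
  # population R2 = 0.8 envelope across seeds (activity noise tuned
  # analytically: latent signal variance 16+4+1, sd = sqrt(21 * 0.25);
  # descriptor noise kept at its 0.1 default so X stays informative)
  vals <- vapply(1:20, function(s) {
    d <- gen_latent_qstr(n_mol = 32, n_cols = 40, n_comp = 3,
                         noise_sd = sqrt(21 * 0.25), x_noise_sd = 0.1,
                         seed = s)
    predictive_r2(fit_pls(d, 3), d)
  }, numeric(1))
  expect_true(all(vals > 0.35 & vals < 0.98))
  expect_gt(mean(vals), 0.6)
})

test_that("field fractions are a proper decomposition", {
  ds <- gen_latent_qstr(n_mol = 20, n_cols = 24, n_comp = 2,
                        noise_sd = 0.1, seed = 6)
  m <- fit_pls(ds, 2)
  fr <- field_fractions(m, ds)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_true(all(fr >= 0))

  # single-field block: fraction 1
  one <- ds
  one$block$column_meta$field <- "steric"
  expect_equal(unname(field_fractions(m, one)), 1)

  # duplicated fields split 50/50 by symmetry
  X <- ds$block$matrix
  dup <- cbind(X, X)
  colnames(dup) <- c(paste0("A_", seq_len(ncol(X))),
                     paste0("B_", seq_len(ncol(X))))
  dds <- qstr_dataset(dup, ds$y, is_test = ds$is_test)
  dds$block$column_meta$field <- rep(c("A", "B"), each = ncol(X))
  md <- fit_pls(dds, 2)
  frd <- field_fractions(md, dds)
  expect_equal(unname(frd["A"]), 0.5, tolerance = 1e-9)

  # planted: only field A's columns carry signal
  set.seed(31)
  n <- 24
  sig <- matrix(rnorm(n * 10, sd = 2), n, 10)
  noise <- matrix(rnorm(n * 10, sd = 0.01), n, 10)
  Xp <- cbind(sig, noise)
  colnames(Xp) <- c(paste0("A_", 1:10), paste0("B_", 1:10))
  yp <- rowSums(sig[, 1:3]) + rnorm(n, sd = 0.05)
  pds <- qstr_dataset(Xp, yp, is_test = rep(FALSE, n))
  pds$block$column_meta$field <- rep(c("A", "B"), each = 10)
  mp <- fit_pls(pds, 3)
  expect_gt(field_fractions(mp, pds)["A"], 0.9)
})

test_that("contour grids export sd-weighted coefficients with levels", {
  ds <- gen_latent_qstr(n_mol = 20, n_cols = 24, n_comp = 2,
                        noise_sd = 0.1, seed = 10)
  m <- fit_pls(ds, 2)
  cg <- contour_grid(m, ds, "fieldA")
  expect_length(cg$value, sum(ds$block$column_meta$field == "fieldA"))
  expect_lte(cg$lo_level, cg$hi_level)
  expect_error(contour_grid(m, ds, "nope"), "unknown field")

  # equal percentiles collapse the two levels
  cg2 <- contour_grid(m, ds, "fieldA", lo_pct = 50, hi_pct = 50)
  expect_equal(cg2$lo_level, cg2$hi_level)

  # all-zero coefficients give an empty contour set
  m0 <- m; m0$coefficients <- rep(0, length(m0$coefficients))
  cg0 <- contour_grid(m0, ds, "fieldA")
  expect_true(all(cg0$value == 0))
  expect_true(is.na(cg0$lo_level) && is.na(cg0$hi_level))

  # a single informative column dominates |sd * coef|
  set.seed(77)
  Xs <- matrix(rnorm(18 * 12, sd = 0.05), 18, 12)
  Xs[, 5] <- rnorm(18, sd = 3)
  colnames(Xs) <- paste0("steric_", 1:12)
  ys <- Xs[, 5] * 2 + rnorm(18, sd = 0.05)
  sds <- qstr_dataset(Xs, ys, is_test = rep(FALSE, 18))
  ms <- fit_pls(sds, 1)
  cgs <- contour_grid(ms, sds, "steric")
  expect_equal(unname(which.max(abs(cgs$value))), 5L)
})

test_that("model quality predicate uses the conventional thresholds", {
  expect_true(model_acceptable(0.51, 0.61))
  expect_false(model_acceptable(0.5, 0.9))
  expect_false(model_acceptable(0.7, 0.6))
})

test_that("degenerate and undersized inputs raise errors", {
  ds <- gen_latent_qstr(n_mol = 10, n_cols = 8, n_comp = 2,
                        noise_sd = 0.1, seed = 2)
  expect_error(fit_pls(ds, 50), "more training molecules")
  expect_error(loo_q2(ds, 7), "below n_train")
  const <- ds
  const$block$matrix[] <- 1
  expect_error(fit_pls(const, 1), "degenerate")
})
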