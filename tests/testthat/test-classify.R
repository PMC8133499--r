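test_that("z-scoring centres, scales and passes constants through", {
  x <- matrix(c(1, 2, 3, 10, 20, 60), ncol = 2)
  z <- zscore_fit_apply(x)
  expect_equal(colMeans(z), c(0, 0))
  expect_equal(apply(z, 2, sd), c(1, 1))
  expect_equal(z[, 1], (x[, 1] - 2) / 1)   # hand-computed first column
  z2 <- zscore_fit_apply(z)
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12)
  expect_warning(zc <- zscore_fit_apply(cbind(x, 5)), "zero-variance")
  expect_equal(zc[, 3], rep(0, 3))
})

test_that("PCA ratios, orthonormality and reconstruction behave", {
  set.seed(14)
  # collinear data: one direction carries all variance
  t <- rnorm(30)
  line <- cbind(t, 2 * t)
  pl <- pca_fit(line)
  expect_equal(pl$ratios[1], 1)

  x <- matrix(rnorm(25 * 6), 25)
  p <- pca_fit(x)
  expect_equal(t(p$rotation) %*% p$rotation, diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(p$ratios) <= 1e-12))
  expect_equal(sum(p$ratios), 1)
  # full-rank reconstruction is exact
  rec <- p$scores %*% t(p$rotation)
  centred <- sweep(x, 2, p$center)
  expect_equal(rec, centred, tolerance = 1e-10, ignore_attr = TRUE)
  # eigen-decomposition oracle for the ratios
  ev <- eigen(cov(x))$values
  expect_equal(p$ratios, ev / sum(ev), tolerance = 1e-10)
  # deterministic sign: the largest loading of each component is positive
  expect_true(all(apply(p$rotation, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("component selection covers all four modes", {
  expect_equal(select_components(c(0.6, 0.3, 0.1), "cumvar95"), 3)
  expect_equal(select_components(c(0.99, 0.01), "cumvar99"), 1)
  expect_equal(select_components(c(0.5, 0.3, 0.2), "fixed", k = 2), 2)
  expect_error(select_components(c(0.5, 0.5), "fixed", k = 3))
  # 'best' returns the argmax of the scorer, smallest k on ties
  scores <- c(0.7, 0.9, 0.9, 0.8)
  expect_equal(select_components(rep(0.25, 4), "best",
                                 scorer = function(k) scores[k]), 2)
})

test_that("stratified SVM CV separates clusters and matches 'best' sweep", {
  set.seed(50)
  n <- 40
  x <- rbind(matrix(rnorm(n * 2, 0), n), matrix(rnorm(n * 2, 6), n))
  y <- rep(c("expert", "amateur"), each = n)
  rep1 <- svm_cv(x, y, folds = 10, seed = 1)
  expect_equal(rep1$mean_f1, 1)
  expect_equal(length(rep1$fold_f1), 10)

  # every fold contains both classes by construction
  expect_error(svm_cv(x[1:12, ], y[c(1:11, 41)], folds = 10),
               "stratification")

  # exhaustive sweep oracle for the 'best' mode on this toy set
  z <- zscore_fit_apply(x)
  pca <- pca_fit(z)
  score_k <- function(k) svm_cv(pca$scores[, seq_len(k), drop = FALSE], y,
                                folds = 10, seed = 1)$mean_f1
  ks <- vapply(seq_along(pca$ratios), score_k, numeric(1))
  expect_equal(select_components(pca$ratios, "best", scorer = score_k),
               which.max(ks))
})

test_that("labels shuffled off the features score near one half", {
  set.seed(60)
  x <- matrix(rnorm(60 * 8), 60)
  f1 <- replicate(15, {
    y <- sample(rep(c("expert", "amateur"), each = 30))
    svm_cv(x, y, folds = 6, seed = sample.int(1000, 1))$mean_f1
  })
  expect_gt(mean(f1), 0.35)
  expect_lt(mean(f1), 0.65)
})

test_that("the pipeline is invariant to affine rescaling of a column", {
  set.seed(71)
  n <- 30
  x <- rbind(matrix(rnorm(n * 5, 0), n), matrix(rnorm(n * 5, 1.5), n))
  y <- rep(c("expert", "amateur"), each = n)
  run <- function(m) {
    z <- zscore_fit_apply(m)
    p <- pca_fit(z)
    svm_cv(p$scores, y, folds = 5, seed = 3)$fold_f1
  }
  x2 <- x
  x2[, 2] <- x2[, 2] * -40 + 7
  expect_equal(run(x2), run(x), tolerance = 1e-8)
})

test_that("feature-set comparison honours the component conditions", {
  set.seed(90)
  n <- 17
  mk_group <- function(mu) matrix(rnorm(n * 64, mu), n)
  fm <- rbind(mk_group(0), mk_group(1))
  colnames(fm) <- feature_names()
  y <- rep(c("expert", "amateur"), each = n)
  res <- run_comparison(fm, y, modes = "cumvar99", fixed_k = c(10, 40),
                        folds = 5, seed = 4)
  # DBH (16 columns) is skipped for fixed 40, present for fixed 10
  expect_false(any(res$feature_set == "dbh" & res$mode == "fixed40"))
  expect_equal(sum(res$mode == "fixed10"), 3)
  expect_true(all(res$mean_f1 >= 0 & res$mean_f1 <= 1))
  expect_true(all(res$n_components <= 64))

  # with every component retained, cumvar99 on the 16-dim DBH set equals
  # fixed(16): identical folds, identical scores
  dbh_cols <- feature_set_columns("dbh")
  z <- zscore_fit_apply(fm[, dbh_cols])
  p <- pca_fit(z)
  k99 <- select_components(p$ratios, "cumvar99")
  r99 <- svm_cv(p$scores[, 1:k99, drop = FALSE], y, folds = 5, seed = 4)
  rk <- svm_cv(p$scores[, 1:16, drop = FALSE], y, folds = 5, seed = 4)
  if (k99 == 16) expect_equal(r99$fold_f1, rk$fold_f1)
})

test_that("fold-safe variant fits the scaler and PCA inside folds", {
  set.seed(95)
  n <- 20
  x <- rbind(matrix(rnorm(n * 6, 0), n), matrix(rnorm(n * 6, 3), n))
  y <- rep(c("expert", "amateur"), each = n)
  rep_safe <- svm_cv(x, y, folds = 5, seed = 2, fold_safe = TRUE,
                     n_components = 4)
  expect_equal(rep_safe$mean_f1, 1)
})
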