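# Proficiency classification: column z-scoring, PCA, component selection
# (cumulative explained variance, best-score sweep, or a fixed count), and
# a linear soft-margin SVM (C = 1) under stratified 10-fold cross-validation
# scored by F1 with "expert" as the positive class.
#
# By default the scaler and the PCA are fitted on the whole data set before
# cross-validation; `fold_safe = TRUE` refits both inside each training fold.

#' Column-wise z-scoring
#'
#' Centres each column to mean 0 and scales to sample SD 1. Zero-variance
#' columns are passed through as zeros with a warning.
#'
#' @param x Numeric matrix (rows = performances).
#' @return Matrix of the same shape with attributes `center` and `scale`.
#' @export
zscore_fit_apply <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  zero <- sd == 0 | !is.finite(sd)
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) passed through as zeros")
    sd[zero] <- 1
  }
  out <- sweep(sweep(x, 2, mu), 2, sd, "/")
  attr(out, "center") <- mu
  attr(out, "scale") <- sd
  out
}

#' Principal component analysis with explained-variance ratios
#'
#' Components are orthonormal and sorted by decreasing explained variance;
#' ratios are normalised over the first `min(n - 1, p)` components and sum
#' to 1. Signs follow the convention that each component's
#' largest-magnitude loading is positive.
#'
#' @param x Numeric matrix (typically already z-scored).
#' @return List with `rotation` (p x k loadings), `scores` (n x k),
#'   `ratios` (explained-variance ratios), `center`.
#' @export
pca_fit <- function(x) {
  x <- as.matrix(x)
  k <- min(nrow(x) - 1L, ncol(x))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  sco <- pr$x[, seq_len(k), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, "*")
  sco <- sweep(sco, 2, flip, "*")
  var_k <- pr$sdev[seq_len(k)]^2
  list(rotation = rot, scores = sco, ratios = var_k / sum(var_k),
       center = pr$center)
}

#' Choose the number of principal components
#'
#' @param ratios Explained-variance ratios from [pca_fit()].
#' @param mode `"cumvar95"` / `"cumvar99"`: smallest k whose cumulative
#'   ratio reaches the threshold; `"best"`: argmax over k of the scorer's
#'   mean F1 (ties to the smallest k); `"fixed"`: the supplied `k`.
#' @param k Component count for `mode = "fixed"`.
#' @param scorer For `mode = "best"`: `function(k)` returning a mean F1.
#' @return Integer component count.
#' @export
select_components <- function(ratios, mode = c("cumvar95", "cumvar99",
                                               "best", "fixed"),
                              k = NULL, scorer = NULL) {
  mode <- match.arg(mode)
  K <- length(ratios)
  switch(mode,
    cumvar95 = which(cumsum(ratios) >= 0.95 - 1e-12)[1],
    cumvar99 = which(cumsum(ratios) >= 0.99 - 1e-12)[1],
    fixed = {
      stopifnot(!is.null(k), k >= 1, k <= K)
      as.integer(k)
    },
    best = {
      stopifnot(is.function(scorer))
      scores <- vapply(seq_len(K), scorer, numeric(1))
      which.max(scores)  # ties resolve to the smallest k
    }
  )
}

f1_score <- function(truth, pred, positive = "expert") {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (tp == 0) return(if (fp == 0 && fn == 0) 1 else 0)
  2 * tp / (2 * tp + fp + fn)
}

# Stratified fold assignment: within each class, shuffle then deal
# round-robin, so fold sizes differ by at most one per class.
stratified_folds <- function(y, folds, seed) {
  assign <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  if (any(table(factor(assign, levels = seq_len(folds)), y) == 0)) {
    stop("stratification error: a fold lacks one of the classes")
  }
  assign
}

#' Linear SVM under stratified k-fold cross-validation
#'
#' Soft-margin linear SVM (penalty `C`), folds stratified from a seeded
#' shuffle, F1 computed per fold with `positive` as the positive class.
#'
#' @param x Feature matrix (rows = performances). With the default
#'   `fold_safe = FALSE` the matrix is used as given (z-score/PCA already
#'   fitted on all rows); with `fold_safe = TRUE`, z-scoring and PCA with
#'   `n_components` are refitted inside each training fold.
#' @param y Binary labels.
#' @param folds Number of folds.
#' @param C SVM cost parameter.
#' @param seed Seed for the fold shuffle.
#' @param positive Positive class for F1.
#' @param fold_safe Fit scaler and PCA inside each training fold.
#' @param n_components Component count for `fold_safe = TRUE`.
#' @return A `classification_report` list: `mean_f1`, `sd_f1`, `fold_f1`,
#'   `folds`, `C`, `seed`, `n`, `positive`.
#' @export
svm_cv <- function(x, y, folds = 10, C = 1.0, seed = 0,
                   positive = "expert", fold_safe = FALSE,
                   n_components = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (length(unique(y)) != 2) stop("binary labels required")
  if (nrow(x) < folds) stop("need at least as many rows as folds")
  fold_id <- stratified_folds(y, folds, seed)
  fold_f1 <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (fold_safe) {
      z <- zscore_fit_apply(xtr)
      pca <- pca_fit(z)
      k <- min(n_components %||% ncol(pca$rotation), ncol(pca$rotation))
      xtr <- pca$scores[, seq_len(k), drop = FALSE]
      zte <- sweep(sweep(xte, 2, attr(z, "center")), 2, attr(z, "scale"), "/")
      xte <- sweep(zte, 2, pca$center) %*% pca$rotation[, seq_len(k), drop = FALSE]
    }
    fit <- e1071::svm(xtr, factor(y[tr]), kernel = "linear", cost = C,
                      scale = FALSE)
    pred <- as.character(stats::predict(fit, xte))
    fold_f1[f] <- f1_score(y[!tr], pred, positive)
  }
  structure(list(mean_f1 = mean(fold_f1), sd_f1 = stats::sd(fold_f1),
                 fold_f1 = fold_f1, folds = folds, C = C, seed = seed,
                 n = nrow(x), positive = positive),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("linear SVM %d-fold CV: mean F1 = %.4f (sd %.4f), n = %d\n",
              x$folds, x$mean_f1, x$sd_f1, x$n))
  invisible(x)
}

#' Feature-set column selectors
#'
#' @param label `"basic"` (48 BH/RH/LH columns), `"dbh"` (16 DBH columns)
#'   or `"basic_plus_dbh"` (all 64).
#' @return Character vector of feature-column names.
#' @export
feature_set_columns <- function(label = c("basic", "dbh", "basic_plus_dbh")) {
  label <- match.arg(label)
  fn <- feature_names()
  switch(label,
    basic = fn[!startsWith(fn, "DBH_")],
    dbh = fn[startsWith(fn, "DBH_")],
    basic_plus_dbh = fn
  )
}

#' Compare feature sets across component-selection conditions
#'
#' Runs the z-score + PCA + linear-SVM pipeline for the `basic`, `dbh` and
#' `basic_plus_dbh` feature sets under each requested condition. Fixed
#' component counts larger than a set's dimensionality (the 16-feature DBH
#' set with 20 or 40 components) are skipped.
#'
#' @param feature_matrix Numeric matrix with the 64 named feature columns.
#' @param labels Group labels aligned with the rows.
#' @param modes Conditions: any of `"cumvar95"`, `"cumvar99"`, `"best"`.
#' @param fixed_k Additional fixed component counts (e.g. `c(10, 20, 40)`).
#' @param folds,C,seed,fold_safe Passed to [svm_cv()].
#' @return Tibble: `feature_set`, `mode`, `n_components`, `mean_f1`,
#'   `sd_f1`, `seed`.
#' @export
run_comparison <- function(feature_matrix, labels,
                           modes = c("cumvar95", "cumvar99", "best"),
                           fixed_k = c(10, 20, 40),
                           folds = 10, C = 1.0, seed = 0,
                           fold_safe = FALSE) {
  feature_matrix <- as.matrix(feature_matrix)
  rows <- list()
  for (set in c("basic", "dbh", "basic_plus_dbh")) {
    cols <- feature_set_columns(set)
    xs <- feature_matrix[, cols, drop = FALSE]
    z <- zscore_fit_apply(xs)
    pca <- pca_fit(z)
    K <- ncol(pca$scores)
    score_k <- function(k) {
      svm_cv(pca$scores[, seq_len(k), drop = FALSE], labels,
             folds = folds, C = C, seed = seed)$mean_f1
    }
    conds <- c(as.list(modes),
               lapply(fixed_k, function(k) list(mode = "fixed", k = k)))
    for (cond in conds) {
      if (is.list(cond)) {
        if (cond$k > length(cols)) next  # e.g. DBH with 20/40 components
        kk <- select_components(pca$ratios, "fixed", k = min(cond$k, K))
        mode_lab <- paste0("fixed", cond$k)
      } else {
        kk <- select_components(pca$ratios, cond, scorer = score_k)
        mode_lab <- cond
      }
      rep <- if (fold_safe) {
        svm_cv(xs, labels, folds = folds, C = C, seed = seed,
               fold_safe = TRUE, n_components = kk)
      } else {
        svm_cv(pca$scores[, seq_len(kk), drop = FALSE], labels,
               folds = folds, C = C, seed = seed)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature_set = set, mode = mode_lab, n_components = kk,
        mean_f1 = rep$mean_f1, sd_f1 = rep$sd_f1, seed = seed
      )
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}
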