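test_that("degenerate ANOVA input gives F = 0, p = 1 across effects", {
  res <- mixed_anova_2x2(rep(3, 6), rep(3, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, c(0, 0, 0))
  expect_equal(res$p, c(1, 1, 1))
  expect_equal(res$partial_eta_sq, c(0, 0, 0))
})

test_that("split-plot decomposition matches a hand-rolled toy and aov()", {
  rh <- c(10, 12, 20, 23)
  lh <- c(8, 11, 15, 14)
  grp <- c("am", "am", "ex", "ex")
  res <- mixed_anova_2x2(rh, lh, grp)

  # independent oracle: the same design fitted by stats::aov with an
  # Error(subject) stratum
  df <- data.frame(y = c(rh, lh),
                   hand = rep(c("RH", "LH"), each = 4),
                   group = rep(grp, 2),
                   subj = factor(rep(1:4, 2)))
  fit <- stats::aov(y ~ group * hand + Error(subj), data = df)
  s <- summary(fit)
  btw <- s[["Error: subj"]][[1]]
  wth <- s[["Error: Within"]][[1]]
  expect_equal(res$F[res$effect == "group"], btw["group", "F value"],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "hand"], wth["hand", "F value"],
               tolerance = 1e-10)
  expect_equal(res$F[res$effect == "hand:group"],
               wth["group:hand", "F value"], tolerance = 1e-10)
  expect_equal(res$df2, rep(2L, 3))

  ss <- attr(res, "ss")
  expect_equal(sum(ss[c("ss_hand", "ss_group", "ss_interaction",
                        "ss_subj_within", "ss_within_err")]),
               ss[["ss_total"]], tolerance = 1e-9)
})

test_that("interaction F equals the squared t on hand differences", {
  set.seed(88)
  for (rep in 1:5) {
    rh <- rnorm(12, 10, 2); lh <- rnorm(12, 9, 2)
    grp <- rep(c("expert", "amateur"), each = 6)
    res <- mixed_anova_2x2(rh, lh, grp)
    diffs <- rh - lh
    tt <- independent_t_pooled(diffs[grp == "expert"], diffs[grp == "amateur"])
    expect_equal(res$F[res$effect == "hand:group"], tt$t^2,
                 tolerance = 1e-10)
    # sum-of-squares conservation on random data
    ss <- attr(res, "ss")
    expect_equal(sum(ss[setdiff(names(ss), "ss_total")]), ss[["ss_total"]],
                 tolerance = 1e-9)
  }
})

test_that("pooled t agrees between raw samples and summary statistics", {
  set.seed(5)
  x <- rnorm(14); y <- rnorm(17, 0.4)
  t_raw <- independent_t_pooled(x, y)
  t_sum <- independent_t_pooled(mean_ref = mean(x), sd_ref = sd(x),
                                n_ref = length(x), mean_cmp = mean(y),
                                sd_cmp = sd(y), n_cmp = length(y))
  expect_equal(t_raw$t, t_sum$t, tolerance = 1e-12)
  expect_equal(t_raw$p, t_sum$p, tolerance = 1e-12)
  expect_equal(t_raw$df, length(x) + length(y) - 2)

  # n = 3 toy against fully hand-computed pooled formula
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  tt <- independent_t_pooled(a, b)
  sp2 <- ((3 - 1) * var(a) + (3 - 1) * var(b)) / 4
  expect_equal(tt$t, (mean(b) - mean(a)) / sqrt(sp2 * (2 / 3)))

  expect_equal(independent_t_pooled(c(1, 2), c(1, 2))$t, 0)
  zed <- independent_t_pooled(c(1, 1), c(2, 2))
  expect_true(zed$infinite)
})

test_that("type-I error of the pooled t sits at the nominal level", {
  set.seed(1234)
  reps <- 10000; n <- 34
  x <- matrix(rnorm(reps * n), reps)
  y <- matrix(rnorm(reps * n), reps)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n - 1)
  vy <- rowSums((y - my)^2) / (n - 1)
  tstat <- (my - mx) / sqrt((vx + vy) / 2 * (2 / n))
  rej <- mean(abs(tstat) > qt(0.975, 2 * n - 2))
  expect_gt(rej, 0.042)
  expect_lt(rej, 0.058)
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.01, 4), 0.04)
  expect_equal(bonferroni(0.4, 4), 1)
  expect_equal(bonferroni(c(0.2, 0.8), 1), c(0.2, 0.8))
})

test_that("Cohen's d follows the pooled-SD two-condition form", {
  x <- c(4, 5, 6, 7)
  expect_equal(cohens_d_hands(x, x)$cohens_d, 0)
  set.seed(9)
  rh <- rnorm(20, 2); lh <- rnorm(20)
  d <- cohens_d_hands(rh, lh)$cohens_d
  expect_equal(d, (mean(rh) - mean(lh)) / sqrt((var(rh) + var(lh)) / 2))
  # unit effect: mean gap equal to the pooled SD
  lh2 <- x - sqrt((var(x) + var(x)) / 2)
  expect_equal(cohens_d_hands(x, lh2)$cohens_d, 1)
})

test_that("Levene test holds its size and detects 10-fold variance gaps", {
  set.seed(31)
  null_rej <- mean(replicate(200, {
    g <- rep(c("a", "b"), each = 34)
    levene_test(c(rnorm(34), rnorm(34)), g)$p < 0.05
  }))
  expect_lt(null_rej, 0.11)
  power_rej <- mean(replicate(100, {
    g <- rep(c("a", "b"), each = 34)
    levene_test(c(rnorm(34, sd = 1), rnorm(34, sd = sqrt(10))), g)$p < 0.05
  }))
  expect_gt(power_rej, 0.9)
  expect_error(levene_test(c(1, 2, 3), c("a", "b", "b")), "at least 2")
})

test_that("Shapiro-Wilk wrapper reports the published statistic", {
  set.seed(2)
  x <- rnorm(50)
  res <- shapiro_wilk(x)
  ref <- stats::shapiro.test(x)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$test, "shapiro_wilk")
})
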