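# The statistical protocol: 2x2 split-plot (mixed) ANOVA with partial eta
# squared, pooled-variance independent t tests oriented amateur-minus-expert,
# Bonferroni correction by explicit multiplication, Cohen's d for the
# hand contrast, and the Levene / Shapiro-Wilk assumption checks.

#' Two-by-two split-plot (mixed) ANOVA
#'
#' Hand (RH vs LH) is the within-subject factor and group the
#' between-subject factor. The between-subject error term is subjects
#' within groups; the within error is hand-by-subject within groups; each
#' effect's partial eta squared is `SS_effect / (SS_effect + SS_error)`
#' against its own error term. All F tests have df (1, N - 2).
#'
#' @param rh,lh Per-subject feature values for the two hands.
#' @param group Per-subject group labels (two levels, >= 2 subjects each).
#' @return A tibble with one row per effect (`hand`, `group`,
#'   `hand:group`): `F`, `df1`, `df2`, `p`, `partial_eta_sq`, plus the sums
#'   of squares as attribute `ss` (including `ss_total`).
#' @export
mixed_anova_2x2 <- function(rh, lh, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) != 2) stop("exactly two groups are required")
  if (any(table(group) < 2)) stop("each group needs at least 2 subjects")
  n <- length(rh)
  stopifnot(length(lh) == n, length(group) == n)
  if (anyNA(rh) || anyNA(lh)) stop("complete data required")

  y <- c(rh, lh)
  grand <- mean(y)
  subj_mean <- (rh + lh) / 2
  grp_mean <- tapply(subj_mean, group, mean)
  hand_mean <- c(RH = mean(rh), LH = mean(lh))
  cell_mean <- rbind(RH = tapply(rh, group, mean), LH = tapply(lh, group, mean))
  n_g <- table(group)

  ss_between_subj <- 2 * sum((subj_mean - grand)^2)
  ss_group <- 2 * sum(n_g * (grp_mean - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_hand <- n * sum((hand_mean - grand)^2)
  ss_hg <- 0
  for (h in c("RH", "LH")) {
    for (g in levels(group)) {
      ss_hg <- ss_hg + n_g[[g]] *
        (cell_mean[h, g] - grp_mean[[g]] - hand_mean[[h]] + grand)^2
    }
  }
  ss_total <- sum((y - grand)^2)
  ss_within_err <- ss_total - ss_group - ss_subj_within - ss_hand - ss_hg

  df_err <- n - 2
  f_of <- function(ss_eff, ss_err) {
    if (ss_err <= 1e-300) {
      if (ss_eff <= 1e-300) return(c(F = 0, p = 1))
      return(c(F = Inf, p = 0))
    }
    f <- (ss_eff / 1) / (ss_err / df_err)
    c(F = f, p = stats::pf(f, 1, df_err, lower.tail = FALSE))
  }
  fg <- f_of(ss_group, ss_subj_within)
  fh <- f_of(ss_hand, ss_within_err)
  fi <- f_of(ss_hg, ss_within_err)
  pes <- function(ss_eff, ss_err) {
    if (ss_eff + ss_err <= 1e-300) return(0)
    ss_eff / (ss_eff + ss_err)
  }
  out <- tibble::tibble(
    effect = c("hand", "group", "hand:group"),
    F = c(fh[["F"]], fg[["F"]], fi[["F"]]),
    df1 = 1L, df2 = as.integer(df_err),
    p = c(fh[["p"]], fg[["p"]], fi[["p"]]),
    partial_eta_sq = c(pes(ss_hand, ss_within_err),
                       pes(ss_group, ss_subj_within),
                       pes(ss_hg, ss_within_err))
  )
  structure(out,
            ss = c(ss_hand = ss_hand, ss_group = ss_group,
                   ss_interaction = ss_hg, ss_subj_within = ss_subj_within,
                   ss_within_err = ss_within_err, ss_total = ss_total),
            class = c("mixed_anova", class(out)))
}

#' Pooled-variance independent two-sample t test
#'
#' Student's t with the pooled variance estimate and df `n_a + n_b - 2`,
#' oriented so that `t` carries the sign of `mean(comparison) -
#' mean(reference)` (the printed tables subtract expert from amateur).
#' Callable from raw samples or from summary statistics.
#'
#' @param reference,comparison Raw samples (reference = expert group in the
#'   study's orientation), or `NULL` when summaries are given.
#' @param mean_ref,sd_ref,n_ref,mean_cmp,sd_cmp,n_cmp Summary statistics,
#'   used when raw samples are absent.
#' @return A list of class `ttest_pooled`: `t`, `df`, `p` (two-sided),
#'   per-group means, SDs and n, and `infinite` flag (zero pooled variance
#'   with unequal means).
#' @export
independent_t_pooled <- function(reference = NULL, comparison = NULL,
                                 mean_ref = NULL, sd_ref = NULL, n_ref = NULL,
                                 mean_cmp = NULL, sd_cmp = NULL, n_cmp = NULL) {
  if (!is.null(reference)) {
    reference <- reference[is.finite(reference)]
    comparison <- comparison[is.finite(comparison)]
    mean_ref <- mean(reference); sd_ref <- stats::sd(reference)
    n_ref <- length(reference)
    mean_cmp <- mean(comparison); sd_cmp <- stats::sd(comparison)
    n_cmp <- length(comparison)
  }
  if (n_ref < 2 || n_cmp < 2) stop("need n >= 2 per group")
  df <- n_ref + n_cmp - 2
  sp2 <- ((n_ref - 1) * sd_ref^2 + (n_cmp - 1) * sd_cmp^2) / df
  se <- sqrt(sp2 * (1 / n_ref + 1 / n_cmp))
  diff <- mean_cmp - mean_ref
  infinite <- FALSE
  if (se == 0) {
    if (diff == 0) {
      t <- 0
    } else {
      t <- sign(diff) * Inf
      infinite <- TRUE
    }
  } else {
    t <- diff / se
  }
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(t = t, df = df, p = p,
                 mean_ref = mean_ref, sd_ref = sd_ref, n_ref = n_ref,
                 mean_cmp = mean_cmp, sd_cmp = sd_cmp, n_cmp = n_cmp,
                 infinite = infinite),
            class = "ttest_pooled")
}

#' @export
print.ttest_pooled <- function(x, ...) {
  cat(sprintf("pooled t(%d) = %.3f, p = %.4g (comparison - reference)\n",
              x$df, x$t, x$p))
  invisible(x)
}

#' Bonferroni correction by explicit multiplication
#'
#' `p_adj = min(1, p * m)`.
#'
#' @param p Vector of raw p values.
#' @param m Number of comparisons (defaults to `length(p)`).
#' @return Adjusted p values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

#' Cohen's d for the hand contrast
#'
#' Pooled-SD two-condition form: `d = (mean(RH) - mean(LH)) /
#' sqrt((sd(RH)^2 + sd(LH)^2) / 2)`.
#'
#' @param rh,lh Per-subject values for the two hands.
#' @param label Comparison label stored on the result.
#' @return List with `cohens_d` and `label`.
#' @export
cohens_d_hands <- function(rh, lh, label = "RH vs LH") {
  s_pool <- sqrt((stats::var(rh) + stats::var(lh)) / 2)
  d <- if (s_pool == 0) {
    if (mean(rh) == mean(lh)) 0 else sign(mean(rh) - mean(lh)) * Inf
  } else {
    (mean(rh) - mean(lh)) / s_pool
  }
  list(cohens_d = d, label = label)
}

#' Levene's test for equality of variances (mean-centred)
#'
#' Classic Levene W: a one-way ANOVA on absolute deviations from the group
#' means, referred to the F distribution.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return List with `statistic`, `p`, `test = "levene"`.
#' @export
levene_test <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (any(table(groups) < 2)) stop("each group needs at least 2 values")
  res <- withCallingHandlers(
    car::leveneTest(values, groups, center = mean),
    # tiny samples can centre to identical deviations; the F is still the
    # documented statistic, so keep R's perfect-fit notice quiet
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  list(statistic = res[1, "F value"], p = res[1, "Pr(>F)"], test = "levene")
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample (3 to 5000 values).
#' @return List with `statistic`, `p`, `test = "shapiro_wilk"`.
#' @export
shapiro_wilk <- function(x) {
  res <- stats::shapiro.test(x)
  list(statistic = unname(res$statistic), p = res$p.value,
       test = "shapiro_wilk")
}

#' Run the full statistical protocol on a feature table
#'
#' Mirrors the study's result tables: for every Basic feature statistic a
#' mixed ANOVA with hand as within-subject factor (using the RH_/LH_
#' columns), and for every DBH feature statistic an expert-vs-amateur
#' pooled t test with Cohen's d and Levene/Shapiro checks, per excerpt.
#'
#' @param feature_table Tibble from [build_feature_table()]: columns
#'   `performer_id`, `group`, `excerpt`, plus the 64 features.
#' @param bonferroni_m Number of comparisons used for the correction of the
#'   t-test p values (default: number of DBH tests per excerpt).
#' @return List of tibbles `anova` and `ttests`.
#' @export
analyze_features <- function(feature_table, bonferroni_m = NULL) {
  excerpts <- unique(feature_table$excerpt)
  stats_sfx <- c("mean", "sd")
  anova_rows <- list()
  t_rows <- list()
  for (exc in excerpts) {
    tab <- feature_table[feature_table$excerpt == exc, , drop = FALSE]
    grp <- tab$group
    for (f in BASIC_FEATURES) {
      for (s in stats_sfx) {
        rh <- tab[[paste0("RH_", f, "_", s)]]
        lh <- tab[[paste0("LH_", f, "_", s)]]
        ok <- is.finite(rh) & is.finite(lh)
        res <- mixed_anova_2x2(rh[ok], lh[ok], grp[ok])
        anova_rows[[length(anova_rows) + 1L]] <-
          cbind(feature = f, statistic = s, excerpt = exc,
                as.data.frame(res))
      }
    }
    for (f in DBH_FEATURES) {
      for (s in stats_sfx) {
        v <- tab[[paste0("DBH_", f, "_", s)]]
        ok <- is.finite(v)
        tt <- independent_t_pooled(v[ok & grp == "expert"],
                                   v[ok & grp == "amateur"])
        lev <- levene_test(v[ok], grp[ok])
        t_rows[[length(t_rows) + 1L]] <- data.frame(
          feature = f, statistic = s, excerpt = exc,
          mean_expert = tt$mean_ref, sd_expert = tt$sd_ref,
          mean_amateur = tt$mean_cmp, sd_amateur = tt$sd_cmp,
          t = tt$t, df = tt$df, p = tt$p,
          levene_p = lev$p
        )
      }
    }
  }
  tt_tab <- tibble::as_tibble(do.call(rbind, t_rows))
  m <- bonferroni_m %||% (length(DBH_FEATURES) * length(stats_sfx))
  tt_tab$p_bonferroni <- bonferroni(tt_tab$p, m)
  list(anova = tibble::as_tibble(do.call(rbind, anova_rows)),
       ttests = tt_tab)
}
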