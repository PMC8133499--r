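# End-to-end orchestration: simulate -> align -> extract -> analyze ->
# classify, driven by a validated configuration list, with all randomness
# funnelled through named seeds so a rerun reproduces every number.

#' Build and validate a pipeline configuration
#'
#' @param n_expert,n_amateur Cohort sizes.
#' @param seed Master simulation seed.
#' @param hanon_patterns,scale_octaves Excerpt sizes.
#' @param costs Alignment costs, see [alignment_costs()].
#' @param expert_params,amateur_params Generator parameters.
#' @param bonferroni_m Comparisons used by the Bonferroni correction
#'   (`NULL` = number of DBH tests).
#' @param classify_modes,fixed_k,folds,C,classify_seed,fold_safe
#'   Classification options, see [run_comparison()].
#' @param out_dir Optional artifact directory.
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(n_expert = 34, n_amateur = 34, seed = 0,
                            hanon_patterns = 7, scale_octaves = 4,
                            costs = alignment_costs(),
                            expert_params = group_params("expert"),
                            amateur_params = group_params("amateur"),
                            bonferroni_m = NULL,
                            classify_modes = c("cumvar95", "cumvar99", "best"),
                            fixed_k = c(10, 20, 40),
                            folds = 10, C = 1.0, classify_seed = 0,
                            fold_safe = FALSE, out_dir = NULL) {
  cfg <- list(n_expert = n_expert, n_amateur = n_amateur, seed = seed,
              hanon_patterns = hanon_patterns, scale_octaves = scale_octaves,
              costs = costs, expert_params = expert_params,
              amateur_params = amateur_params, bonferroni_m = bonferroni_m,
              classify_modes = classify_modes, fixed_k = fixed_k,
              folds = folds, C = C, classify_seed = classify_seed,
              fold_safe = fold_safe, out_dir = out_dir)
  stopifnot(cfg$n_expert >= 1, cfg$n_amateur >= 1,
            cfg$hanon_patterns >= 1, cfg$scale_octaves >= 1,
            cfg$folds >= 2, cfg$C > 0)
  if (!is.null(out_dir) && !is.character(out_dir)) {
    stop("out_dir must be a path or NULL")
  }
  structure(cfg, class = "pipeline_config")
}

#' Feature table of a simulated or loaded cohort
#'
#' Aligns and extracts every performance, then appends per-performer
#' `"all"` rows averaging the feature vectors of the two excerpts.
#'
#' @param cohort Result of [generate_cohort()].
#' @param excerpts The named list of `piano_score`s the cohort performed.
#' @param costs Alignment costs.
#' @return Tibble: `performer_id`, `group`, `excerpt` (excerpt names plus
#'   `"all"`), and the 64 feature columns.
#' @export
build_feature_table <- function(cohort, excerpts,
                                costs = alignment_costs()) {
  meta <- cohort$meta
  vecs <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    vecs[[i]] <- extract_features(cohort$performances[[i]],
                                  excerpts[[meta$excerpt[i]]], costs)
  }
  base <- cbind(meta[, c("performer_id", "group", "excerpt")],
                tibble::as_tibble(do.call(rbind, vecs)))
  all_rows <- list()
  for (pid in unique(meta$performer_id)) {
    idx <- which(meta$performer_id == pid)
    if (length(idx) < 2) next
    avg <- Reduce(`+`, vecs[idx]) / length(idx)
    all_rows[[length(all_rows) + 1L]] <-
      cbind(data.frame(performer_id = pid, group = meta$group[idx[1]],
                       excerpt = "all"),
            tibble::as_tibble(t(avg)))
  }
  out <- rbind(base, do.call(rbind, all_rows))
  tibble::as_tibble(out)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate the cohort, align and extract features, run the
#' statistical protocol, run the classification comparison. Artifacts
#' (feature table, statistics tables, classification report, run log) are
#' written under `config$out_dir` when set. Each stage failure is
#' re-raised with the stage name; artifacts of completed stages remain.
#'
#' @param config A [pipeline_config()].
#' @return List with `feature_table`, `stats` (list of tibbles),
#'   `classification` (tibble), `cohort`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_msg <- function(...) message("[pianodbh] ", ...)
  stage <- function(name, expr) {
    log_msg("stage ", name, " ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  excerpts <- list(
    hanon = build_hanon_score(n_patterns = config$hanon_patterns),
    scale = build_scale_score(octaves = config$scale_octaves)
  )
  cohort <- stage("simulate", generate_cohort(
    n_expert = config$n_expert, n_amateur = config$n_amateur,
    excerpts = excerpts, seed = config$seed,
    expert_params = config$expert_params,
    amateur_params = config$amateur_params,
    out_dir = if (is.null(out_dir)) NULL else file.path(out_dir, "midi")
  ))
  feature_table <- stage("extract",
                         build_feature_table(cohort, excerpts, config$costs))
  if (!is.null(out_dir)) {
    utils::write.csv(feature_table, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
  }
  stats_res <- stage("analyze",
                     analyze_features(feature_table, config$bonferroni_m))
  if (!is.null(out_dir)) {
    utils::write.csv(stats_res$anova, file.path(out_dir, "anova.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_res$ttests, file.path(out_dir, "ttests.csv"),
                     row.names = FALSE)
  }
  all_tab <- feature_table[feature_table$excerpt == "all", , drop = FALSE]
  classification <- stage("classify", run_comparison(
    as.matrix(all_tab[, feature_names()]), all_tab$group,
    modes = config$classify_modes, fixed_k = config$fixed_k,
    folds = config$folds, C = config$C, seed = config$classify_seed,
    fold_safe = config$fold_safe
  ))
  if (!is.null(out_dir)) {
    utils::write.csv(classification, file.path(out_dir, "classification.csv"),
                     row.names = FALSE)
    jsonlite::write_json(classification, file.path(out_dir,
                                                   "classification.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  log_msg("done")
  list(feature_table = feature_table, stats = stats_res,
       classification = classification, cohort = cohort, config = config)
}
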