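# Per-note performance features and their aggregation into the
# 64-dimensional per-performance vector: 48 Basic entries (BH/RH/LH x
# {rDuration, rIOI, Articulation, Velocity} and their note-to-note deltas,
# each as mean and SD) and 16 DBH (right-minus-left) entries.
#
# Conventions, fixed across the package:
#   * all "logarithmic scale" ratios use the natural log;
#   * the denominator of rDuration and rIOI is the score note's nominal
#     duration in seconds at the excerpt's notated tempo (0.25 s for both
#     built-in excerpts), so rDuration tracks absolute tempo while
#     Articulation (performed duration / performed IOI) tracks the
#     performer's own tempo;
#   * missed and extra notes contribute nothing, and no delta or IOI is
#     formed across the gap a missed note leaves;
#   * the BH statistic is the arithmetic mean of the two per-hand
#     statistics (including the SDs); sample SDs use the n-1 denominator.

BASIC_FEATURES <- c("rDuration", "rDuration_delta", "rIOI", "rIOI_delta",
                    "Articulation", "Articulation_delta",
                    "Velocity", "Velocity_delta")
DBH_FEATURES <- c("duration", "duration_delta", "attack_dev",
                  "attack_dev_delta", "articulation", "articulation_delta",
                  "velocity", "velocity_delta")

#' Names of the 64 aggregate features
#'
#' @return Character vector: 48 Basic names (`BH_`/`RH_`/`LH_` scope,
#'   feature, `_mean`/`_sd`) followed by 16 `DBH_` names.
#' @export
feature_names <- function() {
  basic <- as.vector(t(outer(
    c("BH", "RH", "LH"),
    as.vector(t(outer(BASIC_FEATURES, c("mean", "sd"), paste, sep = "_"))),
    paste, sep = "_")))
  dbh <- as.vector(t(outer(
    "DBH", as.vector(t(outer(DBH_FEATURES, c("mean", "sd"), paste, sep = "_"))),
    paste, sep = "_")))
  c(basic, dbh)
}

#' Compute per-note features for both hands
#'
#' For each matched note of a hand: `rDuration = ln(performed duration /
#' score duration in seconds)`, `rIOI = ln(performed IOI / score duration)`
#' where the performed IOI is the onset distance to the hand's next matched
#' note (defined only when that next score note is the immediate successor),
#' `Articulation = ln(performed duration / performed IOI)`, and `Velocity`
#' is the MIDI velocity. Deltas are differences between consecutive matched
#' notes of the same hand.
#'
#' @param hands Result of [split_hands()] (per-hand alignments).
#' @param performance The aligned `piano_performance`.
#' @param score The `piano_score` that was aligned.
#' @return Tibble with one row per matched note: `hand`, `score_ordinal`,
#'   raw values (`onset_sec`, `perf_dur`, `velocity`), the four features and
#'   their deltas (`NA` where undefined). Attribute `n_dropped` counts
#'   records dropped for non-positive performed IOI.
#' @export
compute_note_features <- function(hands, performance, score) {
  bpm <- attr(score, "nominal_bpm")
  dropped <- 0L
  one_hand <- function(aln, h) {
    sc <- score_hand(score, h)
    sc_dur_sec <- sc$duration_beats * 60 / bpm
    mt <- aln[aln$status %in% c("match", "sub"), , drop = FALSE]
    mt <- mt[order(mt$score_ordinal), , drop = FALSE]
    n <- nrow(mt)
    if (n == 0) return(NULL)
    onset <- performance$onset_sec[mt$perf_index]
    dur <- performance$offset_sec[mt$perf_index] - onset
    vel <- performance$velocity[mt$perf_index]
    sdur <- sc_dur_sec[mt$score_ordinal + 1L]

    # performed IOI to the next matched note, only without a score gap
    ioi <- rep(NA_real_, n)
    if (n > 1) {
      consec <- mt$score_ordinal[-1] == mt$score_ordinal[-n] + 1L
      ioi[-n][consec] <- (onset[-1] - onset[-n])[consec]
    }
    bad <- !is.na(ioi) & ioi <= 0
    if (any(bad)) {
      dropped <<- dropped + sum(bad)
      ioi[bad] <- NA_real_
    }

    rec <- tibble::tibble(
      hand = h,
      score_ordinal = mt$score_ordinal,
      onset_sec = onset,
      perf_dur = dur,
      velocity = as.numeric(vel),
      rDuration = log(dur / sdur),
      rIOI = log(ioi / sdur),
      Articulation = log(dur / ioi),
      Velocity = as.numeric(vel)
    )
    # deltas between consecutive matched score notes (no gap underneath)
    for (f in c("rDuration", "rIOI", "Articulation", "Velocity")) {
      dcol <- rep(NA_real_, n)
      if (n > 1) {
        ok <- mt$score_ordinal[-1] == mt$score_ordinal[-n] + 1L
        dv <- rec[[f]][-1] - rec[[f]][-n]
        dcol[-1][ok] <- dv[ok]
      }
      rec[[paste0(f, "_delta")]] <- dcol
    }
    rec
  }
  out <- rbind(one_hand(hands$rh, "RH"), one_hand(hands$lh, "LH"))
  if (dropped > 0) {
    warning(dropped, " note record(s) dropped for non-positive performed IOI")
  }
  structure(out, n_dropped = dropped)
}

#' Compute difference-between-hands (DBH) records
#'
#' For every score-simultaneous RH/LH pair in which both members are
#' matched: `duration = RH performed duration - LH performed duration`
#' (seconds), `attack_dev = RH onset - LH onset` (seconds; negative means
#' the right hand struck first), `articulation = RH Articulation - LH
#' Articulation` (log-ratio), `velocity = RH velocity - LH velocity` (MIDI
#' units). Deltas run across consecutive usable pairs.
#'
#' @param note_records Output of [compute_note_features()].
#' @param score The `piano_score` (used to pair simultaneous notes; for the
#'   built-in unison excerpts the k-th RH and k-th LH notes pair up).
#' @return Tibble with one row per usable pair: `pair_ordinal`, the four DBH
#'   values and their deltas.
#' @export
compute_dbh <- function(note_records, score) {
  rh_sc <- score_hand(score, "RH")
  lh_sc <- score_hand(score, "LH")
  # pair ordinals by shared notated onset
  pair <- merge(
    data.frame(onset = rh_sc$onset_beats, rh_ord = rh_sc$ordinal),
    data.frame(onset = lh_sc$onset_beats, lh_ord = lh_sc$ordinal),
    by = "onset"
  )
  pair <- pair[order(pair$onset), ]
  pair$pair_ordinal <- seq_len(nrow(pair)) - 1L

  rh <- note_records[note_records$hand == "RH", , drop = FALSE]
  lh <- note_records[note_records$hand == "LH", , drop = FALSE]
  ri <- match(pair$rh_ord, rh$score_ordinal)
  li <- match(pair$lh_ord, lh$score_ordinal)
  ok <- !is.na(ri) & !is.na(li)
  if (!any(ok)) {
    return(tibble::tibble(pair_ordinal = integer(0), duration = numeric(0),
                          attack_dev = numeric(0), articulation = numeric(0),
                          velocity = numeric(0), duration_delta = numeric(0),
                          attack_dev_delta = numeric(0),
                          articulation_delta = numeric(0),
                          velocity_delta = numeric(0)))
  }
  ri <- ri[ok]; li <- li[ok]
  rec <- tibble::tibble(
    pair_ordinal = pair$pair_ordinal[ok],
    duration = rh$perf_dur[ri] - lh$perf_dur[li],
    attack_dev = rh$onset_sec[ri] - lh$onset_sec[li],
    articulation = rh$Articulation[ri] - lh$Articulation[li],
    velocity = rh$velocity[ri] - lh$velocity[li]
  )
  n <- nrow(rec)
  for (f in c("duration", "attack_dev", "articulation", "velocity")) {
    dcol <- rep(NA_real_, n)
    if (n > 1) {
      okd <- rec$pair_ordinal[-1] == rec$pair_ordinal[-n] + 1L
      dv <- rec[[f]][-1] - rec[[f]][-n]
      dcol[-1][okd] <- dv[okd]
    }
    rec[[paste0(f, "_delta")]] <- dcol
  }
  rec
}

#' Aggregate note and DBH records into the 64-entry feature vector
#'
#' Per-hand mean and sample SD over usable notes; the BH statistic is the
#' arithmetic mean of the RH and LH statistics; DBH statistics are taken
#' over the pair records. Statistics with fewer than two usable records are
#' `NA`.
#'
#' @param note_records Output of [compute_note_features()].
#' @param dbh_records Output of [compute_dbh()].
#' @return Named numeric vector of length 64 in [feature_names()] order.
#' @export
aggregate_features <- function(note_records, dbh_records) {
  out <- stats::setNames(rep(NA_real_, 64L), feature_names())
  stat_of <- function(x, s) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_real_)
    if (s == "mean") mean(x) else stats::sd(x)
  }
  for (f in BASIC_FEATURES) {
    for (s in c("mean", "sd")) {
      rh <- stat_of(note_records[[f]][note_records$hand == "RH"], s)
      lh <- stat_of(note_records[[f]][note_records$hand == "LH"], s)
      out[paste0("RH_", f, "_", s)] <- rh
      out[paste0("LH_", f, "_", s)] <- lh
      out[paste0("BH_", f, "_", s)] <- (rh + lh) / 2
    }
  }
  for (f in DBH_FEATURES) {
    for (s in c("mean", "sd")) {
      out[paste0("DBH_", f, "_", s)] <- stat_of(dbh_records[[f]], s)
    }
  }
  out
}

#' Extract the full feature vector of one performance
#'
#' Convenience wrapper: hand assignment by [split_hands()], per-note
#' features, DBH records, aggregation.
#'
#' @inheritParams split_hands
#' @return Named numeric vector of length 64.
#' @export
extract_features <- function(performance, score, costs = alignment_costs()) {
  hands <- split_hands(performance, score, costs)
  notes <- compute_note_features(hands, performance, score)
  dbh <- compute_dbh(notes, score)
  aggregate_features(notes, dbh)
}

#' Element-wise average of two excerpt feature vectors
#'
#' The "all"-excerpt value of every feature is the arithmetic mean of its
#' values on the two excerpts.
#'
#' @param vec_a,vec_b Complete feature vectors from [aggregate_features()].
#' @return Named numeric vector of length 64.
#' @export
average_excerpts <- function(vec_a, vec_b) {
  stopifnot(identical(names(vec_a), names(vec_b)))
  (vec_a + vec_b) / 2
}
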