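# Calibrated synthetic performance generator. The study's recordings are
# not public, so cohorts with the same statistical structure are simulated:
# per-performer tempo scalars, autocorrelated onset jitter, hand asynchrony
# (melody lead), per-hand articulation ratios, contour-following dynamics
# with smoothness-controlled velocity noise, and occasional wrong, missed
# and extra notes. All distributions are normal, truncated at physical
# limits; the group defaults are calibrated to published expert/amateur
# summary moments in a two-level (between-performer / within-performer)
# scheme so that both the group means and both kinds of spread are
# reproduced.

#' Group-level generator parameters
#'
#' Defaults encode the study conditions for the two proficiency groups.
#' Quantities named `*_between_sd` are SDs of per-performer means across a
#' cohort; `*_within_sd` are note-level SDs within one performance.
#'
#' @param group `"expert"` or `"amateur"`.
#' @param ... Named overrides of individual parameters.
#' @return A `group_params` list with entries: `tempo_factor_mean/sd`
#'   (multiplicative per-performer tempo scalar), `ioi_jitter_sd` (s) and
#'   `jitter_ar` (AR(1) coefficient of the onset jitter),
#'   `art_ratio_lh` + `art_ratio_between_sd` (left-hand
#'   duration/IOI ratio), `dbh_duration_mean/between_sd/within_sd` (s;
#'   right-minus-left performed-duration difference),
#'   `attack_mean/between_sd/within_sd` (s; right-minus-left onset
#'   asynchrony, negative = melody lead), `vel_base_lh` and `vel_indiv_sd`
#'   (MIDI units), `vel_offset_mean/between_sd` (right-minus-left mean
#'   velocity), `vel_contour_gain` (per hand, MIDI units per SD of pitch
#'   height), `vel_dbh_sd` and `vel_dbh_delta_sd` (note-level SD of DBH
#'   velocity and of its note-to-note change), and error probabilities
#'   `error_wrong`, `error_miss`, `error_extra`. The within-performance
#'   spreads additionally carry `*_within_between_sd` /
#'   `*_sd_between_sd` parameters: each performer's own regularity is a
#'   trait drawn once per performer, which is what makes the SD-type
#'   aggregate features informative rather than constant within a group.
#' @export
group_params <- function(group = c("expert", "amateur"), ...) {
  group <- match.arg(group)
  p <- if (group == "expert") {
    list(
      tempo_factor_mean = 1.0, tempo_factor_sd = 0.05,
      ioi_jitter_sd = 0.008, ioi_jitter_between_sd = 0.002, jitter_ar = 0.3,
      art_ratio_lh = 0.88, art_ratio_between_sd = 0.04,
      dbh_duration_mean = 0.021, dbh_duration_between_sd = 0.013,
      dbh_duration_within_sd = 0.026, dbh_duration_within_between_sd = 0.008,
      attack_mean = -0.004, attack_between_sd = 0.004,
      attack_within_sd = 0.008, attack_within_between_sd = 0.002,
      vel_base_lh = 62, vel_indiv_sd = 4,
      vel_offset_mean = 11.083, vel_offset_between_sd = 3.472,
      vel_contour_gain = c(rh = 8, lh = 5),
      vel_dbh_sd = 4.601, vel_dbh_sd_between_sd = 0.640,
      vel_dbh_delta_sd = 5.482, vel_dbh_delta_sd_between_sd = 0.769,
      error_wrong = 0.002, error_miss = 0.002, error_extra = 0.002
    )
  } else {
    list(
      tempo_factor_mean = 1.0, tempo_factor_sd = 0.07,
      ioi_jitter_sd = 0.016, ioi_jitter_between_sd = 0.005, jitter_ar = 0.3,
      art_ratio_lh = 0.85, art_ratio_between_sd = 0.06,
      dbh_duration_mean = 0.009, dbh_duration_between_sd = 0.018,
      dbh_duration_within_sd = 0.049, dbh_duration_within_between_sd = 0.023,
      attack_mean = 7.906e-4, attack_between_sd = 0.005,
      attack_within_sd = 0.014, attack_within_between_sd = 0.006,
      vel_base_lh = 60, vel_indiv_sd = 5,
      vel_offset_mean = 7.521, vel_offset_between_sd = 2.606,
      vel_contour_gain = c(rh = 4, lh = 4),
      vel_dbh_sd = 5.135, vel_dbh_sd_between_sd = 0.910,
      vel_dbh_delta_sd = 7.055, vel_dbh_delta_sd_between_sd = 1.433,
      error_wrong = 0.01, error_miss = 0.01, error_extra = 0.01
    )
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  sds <- c("tempo_factor_sd", "ioi_jitter_sd", "ioi_jitter_between_sd",
           "art_ratio_between_sd", "dbh_duration_between_sd",
           "dbh_duration_within_sd", "dbh_duration_within_between_sd",
           "attack_between_sd", "attack_within_sd",
           "attack_within_between_sd", "vel_indiv_sd",
           "vel_offset_between_sd", "vel_dbh_sd", "vel_dbh_sd_between_sd",
           "vel_dbh_delta_sd", "vel_dbh_delta_sd_between_sd")
  if (any(unlist(p[sds]) < 0)) stop("SD parameters must be >= 0")
  probs <- unlist(p[c("error_wrong", "error_miss", "error_extra")])
  if (any(probs < 0 | probs > 1)) stop("error rates must lie in [0, 1]")
  p$group <- group
  structure(p, class = "group_params")
}

# Per-hand velocity-noise SD and AR coefficient implied by the DBH velocity
# calibration. The contour term contributes (gain difference)^2 to the DBH
# velocity variance; the rest is split evenly between the two hands, and
# the AR coefficient is chosen so per-hand increments reproduce the DBH
# delta SD. Infeasible per-performer draws are pulled back to the nearest
# feasible pair.
velocity_noise_spec <- function(sd_dbh, delta_dbh, gain_diff) {
  if (sd_dbh == 0) {
    if (delta_dbh > 0 || gain_diff != 0) {
      stop("vel_dbh_sd = 0 requires vel_dbh_delta_sd = 0 and equal ",
           "contour gains")
    }
    return(list(sd = 0, phi = 0))
  }
  sd_dbh <- max(sd_dbh, sqrt(gain_diff^2 + 0.09))
  var_noise <- (sd_dbh^2 - gain_diff^2) / 2
  # AR(1) feasibility requires delta^2 < 8 * var_noise (phi > -1)
  delta_dbh <- min(delta_dbh, 2.7 * sqrt(var_noise))
  inc2 <- delta_dbh^2 / 2               # per-hand increment variance
  phi <- 1 - inc2 / (2 * var_noise)
  list(sd = sqrt(var_noise), phi = phi)
}

# Truncated-normal draw for a nonnegative scale parameter; an exact zero
# mean with zero spread stays exactly zero (noise-free limits).
draw_scale <- function(mean, sd, lo) {
  if (mean == 0 && sd == 0) return(0)
  max(lo, stats::rnorm(1, mean, sd))
}

ar1_series <- function(n, sd, phi) {
  if (sd == 0 || n == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  }
  x
}

#' Simulate one performance of a unison score
#'
#' Draws performer-level traits (tempo scalar, mean asynchrony, duration
#' imbalance, velocity offset and overall loudness) from the group's
#' between-performer distributions, then renders the score note by note:
#' left-hand onsets follow the tempo-scaled score with AR(1) jitter, each
#' right-hand onset sits at its partner's onset plus an asynchrony draw,
#' durations are articulation-ratio times realized IOI, velocities follow
#' the melodic contour with autocorrelated noise, and wrong / missed /
#' extra notes are injected at the configured rates.
#'
#' @param score A unison `piano_score` (equal RH/LH note counts, shared
#'   onsets).
#' @param params A [group_params()] object.
#' @param performer_seed Seed for the performer-level draws (keep it fixed
#'   across excerpts to model one performer).
#' @param note_seed Seed for the note-level draws (vary per excerpt);
#'   defaults to `performer_seed + 1`.
#' @param performer_id Label for the result.
#' @return A `piano_performance` with a `truth_hand` column (ground-truth
#'   hand of every note, including extras).
#' @export
generate_performance <- function(score, params, performer_seed,
                                 note_seed = performer_seed + 1,
                                 performer_id = paste0("sim_", performer_seed)) {
  rh_sc <- score_hand(score, "RH")
  lh_sc <- score_hand(score, "LH")
  n <- nrow(rh_sc)
  if (n != nrow(lh_sc) || any(abs(rh_sc$onset_beats - lh_sc$onset_beats) > 1e-9)) {
    stop("generator requires a unison score (paired RH/LH onsets)")
  }
  bpm <- attr(score, "nominal_bpm")
  beat_sec <- 60 / bpm
  onset_sc <- rh_sc$onset_beats * beat_sec
  ioi_sc <- c(diff(onset_sc), rh_sc$duration_beats[n] * beat_sec)
  med_ioi <- stats::median(ioi_sc)

  gain_diff <- params$vel_contour_gain[["rh"]] - params$vel_contour_gain[["lh"]]
  draws <- with_seed(performer_seed, list(
    tf = max(0.5, stats::rnorm(1, params$tempo_factor_mean,
                               params$tempo_factor_sd)),
    attack_mu = stats::rnorm(1, params$attack_mean, params$attack_between_sd),
    dur_diff = stats::rnorm(1, params$dbh_duration_mean,
                            params$dbh_duration_between_sd),
    art_lh = min(1.15, max(0.3, stats::rnorm(1, params$art_ratio_lh,
                                             params$art_ratio_between_sd))),
    vel_offset = stats::rnorm(1, params$vel_offset_mean,
                              params$vel_offset_between_sd),
    vel_level = stats::rnorm(1, 0, params$vel_indiv_sd),
    # performer-specific within-performance spreads (regularity is itself
    # a trait that varies across performers)
    attack_sd = draw_scale(params$attack_within_sd,
                           params$attack_within_between_sd, 1e-4),
    dur_within_sd = draw_scale(params$dbh_duration_within_sd,
                               params$dbh_duration_within_between_sd, 1e-3),
    jitter_sd = draw_scale(params$ioi_jitter_sd,
                           params$ioi_jitter_between_sd, 5e-4),
    vel_dbh_sd = draw_scale(params$vel_dbh_sd,
                            params$vel_dbh_sd_between_sd, 0.3),
    vel_dbh_delta_sd = draw_scale(params$vel_dbh_delta_sd,
                                  params$vel_dbh_delta_sd_between_sd, 0.3)
  ))
  vn <- velocity_noise_spec(draws$vel_dbh_sd, draws$vel_dbh_delta_sd,
                            gain_diff)

  notes <- with_seed(note_seed, {
    jitter <- ar1_series(n, draws$jitter_sd, params$jitter_ar)
    lh_on <- 0.5 + draws$tf * onset_sc + jitter
    async <- stats::rnorm(n, draws$attack_mu, draws$attack_sd)
    rh_on <- lh_on + async

    ioi_of <- function(on) c(diff(on), draws$tf * ioi_sc[n])
    lh_ioi <- ioi_of(lh_on); rh_ioi <- ioi_of(rh_on)
    if (min(lh_ioi, rh_ioi) <= 0) {
      stop("parameters produce non-positive performed IOIs")
    }

    s_r <- draws$dur_within_sd / (sqrt(2) * med_ioi)
    clamp_ratio <- function(r) pmin(1.2, pmax(0.05, r))
    lh_ratio <- clamp_ratio(draws$art_lh + stats::rnorm(n, 0, s_r))
    rh_ratio <- clamp_ratio(draws$art_lh + draws$dur_diff / med_ioi +
                              stats::rnorm(n, 0, s_r))
    lh_dur <- lh_ratio * lh_ioi
    rh_dur <- rh_ratio * rh_ioi

    contour <- function(pitch) {
      if (stats::sd(pitch) == 0) return(rep(0, length(pitch)))
      (pitch - mean(pitch)) / stats::sd(pitch)
    }
    base <- params$vel_base_lh + draws$vel_level
    lh_vel <- base + params$vel_contour_gain[["lh"]] * contour(lh_sc$pitch) +
      ar1_series(n, vn$sd, vn$phi)
    rh_vel <- base + draws$vel_offset +
      params$vel_contour_gain[["rh"]] * contour(rh_sc$pitch) +
      ar1_series(n, vn$sd, vn$phi)

    make_hand <- function(pitch, on, dur, vel, hand) {
      df <- data.frame(pitch = pitch, onset_sec = on,
                       offset_sec = on + dur,
                       velocity = pmin(127, pmax(1, vel)),
                       truth_hand = hand)
      # wrong notes: small pitch slips that stay near the score line
      wrong <- stats::runif(nrow(df)) < params$error_wrong
      if (any(wrong)) {
        df$pitch[wrong] <- df$pitch[wrong] +
          sample(c(-2L, -1L, 1L, 2L), sum(wrong), replace = TRUE)
      }
      miss <- stats::runif(nrow(df)) < params$error_miss
      extra_src <- which(stats::runif(nrow(df)) < params$error_extra)
      extras <- if (length(extra_src)) {
        data.frame(
          pitch = df$pitch[extra_src] +
            sample(c(-2L, -1L, 1L, 2L), length(extra_src), replace = TRUE),
          onset_sec = df$onset_sec[extra_src] +
            0.5 * (df$offset_sec[extra_src] - df$onset_sec[extra_src]),
          offset_sec = NA_real_,
          velocity = pmin(127, pmax(1, df$velocity[extra_src] +
                                      stats::rnorm(length(extra_src), 0, 3))),
          truth_hand = hand
        )
      } else NULL
      if (!is.null(extras)) {
        extras$offset_sec <- extras$onset_sec +
          0.4 * (df$offset_sec[extra_src] - df$onset_sec[extra_src])
      }
      rbind(df[!miss, , drop = FALSE], extras)
    }
    rbind(
      make_hand(rh_sc$pitch, rh_on, rh_dur, rh_vel, "RH"),
      make_hand(lh_sc$pitch, lh_on, lh_dur, lh_vel, "LH")
    )
  })
  notes$pitch <- pmin(108L, pmax(21L, as.integer(round(notes$pitch))))
  piano_performance(notes, performer_id = performer_id,
                    group = params$group,
                    excerpt_id = attr(score, "excerpt_id"))
}

#' Simulate an expert/amateur cohort
#'
#' Each performer gets one seed, reused across excerpts so that
#' performer-level traits persist; note-level randomness differs per
#' excerpt. With `out_dir` set, Standard MIDI Files, a `cohort.csv`
#' manifest and a `truth_notes.csv` ground-truth table are written.
#'
#' @param n_expert,n_amateur Cohort sizes (the study recorded 34 + 34).
#' @param excerpts Named list of unison `piano_score`s (default: the two
#'   built-in excerpts).
#' @param seed Master seed; all randomness derives from it.
#' @param expert_params,amateur_params [group_params()] objects.
#' @param out_dir Optional output directory.
#' @return List with `performances` (list of `piano_performance`, one per
#'   manifest row) and `meta` (tibble: `performer_id`, `group`, `excerpt`,
#'   `file`).
#' @export
generate_cohort <- function(n_expert = 34, n_amateur = 34,
                            excerpts = list(hanon = build_hanon_score(),
                                            scale = build_scale_score()),
                            seed = 0,
                            expert_params = group_params("expert"),
                            amateur_params = group_params("amateur"),
                            out_dir = NULL) {
  stopifnot(n_expert >= 1, n_amateur >= 1)
  n_tot <- n_expert + n_amateur
  performer_seeds <- with_seed(seed, sample.int(2^31 - 10, n_tot))
  ids <- c(sprintf("expert_%02d", seq_len(n_expert)),
           sprintf("amateur_%02d", seq_len(n_amateur)))
  grp <- rep(c("expert", "amateur"), c(n_expert, n_amateur))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  performances <- list()
  meta <- list()
  truth <- list()
  for (i in seq_len(n_tot)) {
    pars <- if (grp[i] == "expert") expert_params else amateur_params
    for (e in seq_along(excerpts)) {
      exc <- names(excerpts)[e]
      perf <- generate_performance(
        excerpts[[e]], pars,
        performer_seed = performer_seeds[i],
        note_seed = performer_seeds[i] + e,
        performer_id = ids[i]
      )
      file <- NA_character_
      if (!is.null(out_dir)) {
        file <- file.path(out_dir, paste0(ids[i], "_", exc, ".mid"))
        write_smf(perf, file, bpm = attr(excerpts[[e]], "nominal_bpm"))
        truth[[length(truth) + 1L]] <-
          cbind(performer_id = ids[i], excerpt = exc, as.data.frame(perf))
      }
      performances[[length(performances) + 1L]] <- perf
      meta[[length(meta) + 1L]] <- data.frame(
        performer_id = ids[i], group = grp[i], excerpt = exc, file = file
      )
    }
  }
  meta <- tibble::as_tibble(do.call(rbind, meta))
  if (!is.null(out_dir)) {
    utils::write.csv(meta, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, truth),
                     file.path(out_dir, "truth_notes.csv"), row.names = FALSE)
  }
  list(performances = performances, meta = meta)
}
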