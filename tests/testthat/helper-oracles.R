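# Shared fixtures and independent oracles, all built in code.

# Exhaustive minimum over all order-preserving score/performance matchings,
# by direct recursion over the matching space (no memoisation): the oracle
# for the dynamic-programming aligner on toy instances.
oracle_align_cost <- function(sp, pp, costs = alignment_costs()) {
  rec <- function(i, j) {
    if (i > length(sp) && j > length(pp)) return(0)
    if (i > length(sp)) return((length(pp) - j + 1) * costs$c_gap)
    if (j > length(pp)) return((length(sp) - i + 1) * costs$c_gap)
    best <- min(costs$c_gap + rec(i + 1, j),   # score note missed
                costs$c_gap + rec(i, j + 1))   # performed note extra
    d <- abs(sp[i] - pp[j])
    if (d <= costs$sub_window) {
      best <- min(best, (if (d == 0) 0 else costs$c_sub) + rec(i + 1, j + 1))
    }
    best
  }
  rec(1, 1)
}

# Group parameters with every stochastic element switched off: the
# deterministic limit used for exactness checks.
noise_free_params <- function(group = "expert", ...) {
  group_params(group,
               tempo_factor_sd = 0, ioi_jitter_sd = 0,
               ioi_jitter_between_sd = 0,
               art_ratio_between_sd = 0,
               dbh_duration_between_sd = 0, dbh_duration_within_sd = 0,
               dbh_duration_within_between_sd = 0,
               attack_between_sd = 0, attack_within_sd = 0,
               attack_within_between_sd = 0,
               vel_indiv_sd = 0, vel_offset_between_sd = 0,
               vel_dbh_sd = 0, vel_dbh_sd_between_sd = 0,
               vel_dbh_delta_sd = 0, vel_dbh_delta_sd_between_sd = 0,
               vel_contour_gain = c(rh = 0, lh = 0),
               error_wrong = 0, error_miss = 0, error_extra = 0,
               ...)
}

# A tiny two-hand unison score for alignment toys: n paired eighth notes.
toy_unison_score <- function(rh_pitches, lh_pitches = rh_pitches - 24L) {
  n <- length(rh_pitches)
  piano_score(data.frame(
    pitch = c(rh_pitches, lh_pitches),
    onset_beats = rep((seq_len(n) - 1) * 0.5, 2),
    duration_beats = 0.5,
    hand = rep(c("RH", "LH"), each = n)
  ), excerpt_id = "toy", nominal_bpm = 120)
}

# Hand-built performance table; durations/velocities default to legato 64.
toy_performance <- function(pitch, onset, dur = 0.25, vel = 64) {
  piano_performance(data.frame(
    pitch = pitch, onset_sec = onset, offset_sec = onset + dur,
    velocity = vel
  ))
}

# Reduced-size excerpts for cohort-level tests (problem sizes documented in
# the methods vignette).
small_excerpts <- function() {
  list(hanon = build_hanon_score(n_patterns = 4),
       scale = build_scale_score(octaves = 2))
}
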