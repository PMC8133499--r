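# Symbolic scores for the two unison exercises and a tabular CSV exchange
# format. A score is a tibble of notes plus excerpt metadata; both hands are
# monophonic and, for the built-in excerpts, play the same line one or two
# octaves apart so that the k-th right-hand and k-th left-hand notes share
# their notated onset exactly.

C_MAJOR_PCS <- c(0L, 2L, 4L, 5L, 7L, 9L, 11L)
BEATS_PER_MEASURE <- 4

# C-major scale degree (0 = root) -> MIDI pitch relative to a root pitch.
degree_to_pitch <- function(degree, root) {
  root + 12L * (degree %/% 7L) + C_MAJOR_PCS[degree %% 7L + 1L]
}

# Inverse of degree_to_pitch for diatonic pitches; errors on chromatic input.
pitch_to_degree <- function(pitch, root) {
  rel <- pitch - root
  idx <- match(((rel %% 12) + 12) %% 12, C_MAJOR_PCS)
  if (anyNA(idx)) {
    stop("pitch offsets must lie in the C-major scale: ",
         paste(pitch[is.na(idx)], collapse = ", "))
  }
  7L * (rel %/% 12L) + (idx - 1L)
}

check_keyboard_range <- function(pitch) {
  if (any(pitch < 21L | pitch > 108L)) {
    stop("score exceeds the 88-key keyboard range (MIDI 21-108)",
         call. = FALSE)
  }
  invisible(pitch)
}

#' Construct a piano score object
#'
#' Assembles a validated score from a per-note table. Ordinals (0-based
#' position within each hand's stream) and measure indices are recomputed.
#'
#' @param notes Data frame with columns `pitch`, `onset_beats`,
#'   `duration_beats`, `hand` (`"RH"`/`"LH"`).
#' @param excerpt_id Excerpt label, e.g. `"hanon1"`, `"cmajor_scale"`,
#'   `"custom"`.
#' @param nominal_bpm Nominal tempo in beats per minute (quarter-note beats).
#' @param beat_unit Note value of one beat (only `"quarter"` is used).
#' @return A `piano_score`: a tibble of notes ordered by (onset, hand) with
#'   columns `pitch`, `onset_beats`, `duration_beats`, `hand`, `measure`,
#'   `ordinal`, and attributes `excerpt_id`, `nominal_bpm`, `beat_unit`.
#' @export
piano_score <- function(notes, excerpt_id = "custom", nominal_bpm = 120,
                        beat_unit = "quarter") {
  need <- c("pitch", "onset_beats", "duration_beats", "hand")
  if (!all(need %in% names(notes))) {
    stop("score table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(notes) == 0) stop("empty score", call. = FALSE)
  if (!all(notes$hand %in% c("RH", "LH"))) stop("hand must be 'RH' or 'LH'")
  if (any(notes$duration_beats <= 0)) stop("duration_beats must be > 0")
  check_keyboard_range(notes$pitch)

  notes <- notes[order(notes$onset_beats, notes$hand, method = "radix"), ]
  notes$measure <- as.integer(notes$onset_beats %/% BEATS_PER_MEASURE + 1L)
  notes$ordinal <- NA_integer_
  for (h in unique(notes$hand)) {
    idx <- which(notes$hand == h)
    ons <- notes$onset_beats[idx]
    if (any(diff(ons) <= 0)) {
      stop("within-hand onsets must strictly increase (hand ", h, ")",
           call. = FALSE)
    }
    ends <- ons + notes$duration_beats[idx]
    if (any(ons[-1] < ends[-length(ends)] - 1e-9)) {
      stop("overlapping notes within hand ", h, " (monophonic per hand)",
           call. = FALSE)
    }
    notes$ordinal[idx] <- seq_along(idx) - 1L
  }
  out <- tibble::as_tibble(notes[, c("pitch", "onset_beats", "duration_beats",
                                     "hand", "measure", "ordinal")])
  structure(out,
            excerpt_id = excerpt_id,
            nominal_bpm = nominal_bpm,
            beat_unit = beat_unit,
            class = c("piano_score", class(out)))
}

#' @export
print.piano_score <- function(x, ...) {
  cat(sprintf("<piano_score '%s'> %d notes, %g bpm (%s-note beat)\n",
              attr(x, "excerpt_id"), nrow(x), attr(x, "nominal_bpm"),
              attr(x, "beat_unit")))
  NextMethod()
}

#' Notes of one hand, ordered by ordinal
#' @param score A `piano_score`.
#' @param hand `"RH"` or `"LH"`.
#' @return Tibble of the hand's notes.
#' @export
score_hand <- function(score, hand) {
  out <- score[score$hand == hand, , drop = FALSE]
  out[order(out$ordinal), , drop = FALSE]
}

#' Nominal note duration in seconds at the score's tempo
#' @param score A `piano_score`.
#' @return Numeric vector aligned with the score rows.
#' @export
score_duration_sec <- function(score) {
  score$duration_beats * 60 / attr(score, "nominal_bpm")
}

#' Build the Hanon Exercise No. 1 score
#'
#' Repeating eight-note patterns in eighth notes, right hand starting on
#' middle C (C4) and left hand two octaves below (C2), transposed up one
#' C-major scale step per pattern; an optional descending mirror (the
#' retrograde of the ascending line) is appended.
#'
#' @param n_patterns Number of ascending eight-note patterns (>= 1).
#' @param include_descending Append the descending mirror?
#' @param bpm Nominal tempo (beats per minute); the study tempo is 120.
#' @param template Semitone offsets of one pattern relative to its root;
#'   must lie in the C-major scale.
#' @return A `piano_score` with `excerpt_id = "hanon1"`.
#' @export
build_hanon_score <- function(n_patterns = 7, include_descending = TRUE,
                              bpm = 120, template = c(0, 4, 5, 7, 9, 7, 5, 4)) {
  stopifnot(n_patterns >= 1)
  tmpl_deg <- pitch_to_degree(template, 0L)
  asc <- unlist(lapply(seq_len(n_patterns) - 1L, function(k) k + tmpl_deg))
  degrees <- if (include_descending) c(asc, rev(asc)) else asc
  rh <- degree_to_pitch(degrees, 60L)
  lh <- rh - 24L
  check_keyboard_range(c(rh, lh))
  n <- length(rh)
  onsets <- (seq_len(n) - 1L) * 0.5
  notes <- data.frame(
    pitch = c(rh, lh),
    onset_beats = c(onsets, onsets),
    duration_beats = 0.5,
    hand = rep(c("RH", "LH"), each = n)
  )
  piano_score(notes, excerpt_id = "hanon1", nominal_bpm = bpm)
}

#' Build the C-major scale score
#'
#' Sixteenth notes ascending then descending over `octaves` octaves (the top
#' note is not repeated), hands one octave apart in parallel.
#'
#' @param octaves Number of octaves (>= 1); the study uses 4.
#' @param bpm Nominal tempo (beats per minute); the study tempo is 60.
#' @param rh_start,lh_start Starting pitches (defaults C4 and C3).
#' @return A `piano_score` with `excerpt_id = "cmajor_scale"` and
#'   `2 * 7 * octaves + 1` notes per hand.
#' @export
build_scale_score <- function(octaves = 4, bpm = 60,
                              rh_start = 60L, lh_start = 48L) {
  stopifnot(octaves >= 1)
  asc <- 0:(7L * octaves)
  degrees <- c(asc, rev(asc)[-1])
  rh <- degree_to_pitch(degrees, as.integer(rh_start))
  lh <- degree_to_pitch(degrees, as.integer(lh_start))
  check_keyboard_range(c(rh, lh))
  n <- length(rh)
  onsets <- (seq_len(n) - 1L) * 0.25
  notes <- data.frame(
    pitch = c(rh, lh),
    onset_beats = c(onsets, onsets),
    duration_beats = 0.25,
    hand = rep(c("RH", "LH"), each = n)
  )
  piano_score(notes, excerpt_id = "cmajor_scale", nominal_bpm = bpm)
}

#' Read / write the tabular score format
#'
#' CSV with header `pitch,onset_beats,duration_beats,hand,measure` (UTF-8,
#' dot decimal). Ordinals are recomputed on read; a file whose notes overlap
#' within a hand is rejected.
#'
#' @param path File path.
#' @param excerpt_id,nominal_bpm Metadata to attach on read (the CSV itself
#'   carries only notes).
#' @return `read_score_csv` returns a `piano_score`; `write_score_csv`
#'   invisibly returns `path`.
#' @export
read_score_csv <- function(path, excerpt_id = "custom", nominal_bpm = 120) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pitch", "onset_beats", "duration_beats", "hand", "measure")
  if (!all(need %in% names(df))) {
    stop("score CSV must have columns ", paste(need, collapse = ","))
  }
  if (nrow(df) == 0) stop("empty score", call. = FALSE)
  piano_score(df, excerpt_id = excerpt_id, nominal_bpm = nominal_bpm)
}

#' @rdname read_score_csv
#' @param score A `piano_score` to write.
#' @export
write_score_csv <- function(score, path) {
  df <- as.data.frame(score)[, c("pitch", "onset_beats", "duration_beats",
                                 "hand", "measure")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
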