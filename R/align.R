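# Score-to-performance note matching. The cited study relied on an external
# symbolic alignment tool; because both excerpts here are monophonic per
# hand, an order-preserving pitch-sequence dynamic program with explicit
# match / substitution / gap costs is sufficient and fully testable against
# exhaustive enumeration. Onset times and velocities play no role in the
# cost, so alignment is invariant to global time shifts and dynamics.

#' Alignment cost parameters
#'
#' @param c_sub Substitution cost for a wrong pitch within `sub_window`
#'   semitones of the score pitch (beyond the window a wrong note is treated
#'   as one missed plus one extra note).
#' @param c_gap Cost of a missed score note or an extra performed note.
#' @param sub_window Substitution window in semitones.
#' @return A list of costs.
#' @export
alignment_costs <- function(c_sub = 1.0, c_gap = 0.6, sub_window = 2L) {
  stopifnot(c_sub > 0, c_gap > 0, sub_window >= 0)
  list(c_sub = c_sub, c_gap = c_gap, sub_window = sub_window)
}

pitch_cost <- function(sp, pp, costs) {
  d <- abs(sp - pp)
  if (d == 0) 0 else if (d <= costs$sub_window) costs$c_sub else Inf
}

#' Align one hand's score stream to a performed pitch sequence
#'
#' Global pairwise sequence alignment by dynamic programming, minimising
#' total cost (match 0, substitution `c_sub` within the pitch window, gap
#' `c_gap`). Ties are broken by preferring match over substitution over a
#' missed score note over an extra performed note.
#'
#' @param score_pitches Integer vector of score pitches (one hand, in order).
#' @param perf_pitches Integer vector of performed pitches (in onset order).
#' @param costs See [alignment_costs()].
#' @param hand Label stored on the result.
#' @return A `note_alignment`: tibble with columns `score_ordinal` (0-based,
#'   `NA` for extras), `perf_index` (1-based index into the performed
#'   sequence, `NA` for misses), `status` in `match`/`sub`/`missed`/`extra`,
#'   `score_pitch`, `perf_pitch`; attribute `cost` holds the total cost.
#' @export
align_hand <- function(score_pitches, perf_pitches,
                       costs = alignment_costs(), hand = "RH") {
  n <- length(score_pitches)
  m <- length(perf_pitches)
  D <- matrix(Inf, n + 1L, m + 1L)
  D[1L, ] <- (0:m) * costs$c_gap
  D[, 1L] <- (0:n) * costs$c_gap
  for (i in seq_len(n)) {
    row_prev <- D[i, ]
    row_cur <- D[i + 1L, ]
    for (j in seq_len(m)) {
      cc <- pitch_cost(score_pitches[i], perf_pitches[j], costs)
      row_cur[j + 1L] <- min(row_prev[j] + cc,      # match / substitution
                             row_prev[j + 1L] + costs$c_gap,  # score gap
                             row_cur[j] + costs$c_gap)        # perf gap
    }
    D[i + 1L, ] <- row_cur
  }

  # backtrace with fixed preference: match > substitution > missed > extra
  # (equality up to rounding noise from different summation orders)
  near <- function(a, b) is.finite(a) && is.finite(b) && abs(a - b) < 1e-9
  i <- n; j <- m
  rows <- list()
  while (i > 0L || j > 0L) {
    step <- NULL
    if (i > 0L && j > 0L) {
      cc <- pitch_cost(score_pitches[i], perf_pitches[j], costs)
      if (is.finite(cc) && near(D[i + 1L, j + 1L], D[i, j] + cc)) {
        step <- list(score_ordinal = i - 1L, perf_index = j,
                     status = if (cc == 0) "match" else "sub")
        i <- i - 1L; j <- j - 1L
      }
    }
    if (is.null(step) && i > 0L &&
        near(D[i + 1L, j + 1L], D[i, j + 1L] + costs$c_gap)) {
      step <- list(score_ordinal = i - 1L, perf_index = NA_integer_,
                   status = "missed")
      i <- i - 1L
    }
    if (is.null(step)) {
      step <- list(score_ordinal = NA_integer_, perf_index = j,
                   status = "extra")
      j <- j - 1L
    }
    rows[[length(rows) + 1L]] <- step
  }
  rows <- rev(rows)
  out <- tibble::tibble(
    score_ordinal = vapply(rows, `[[`, integer(1), "score_ordinal"),
    perf_index = vapply(rows, `[[`, integer(1), "perf_index"),
    status = vapply(rows, `[[`, character(1), "status")
  )
  out$score_pitch <- ifelse(is.na(out$score_ordinal), NA_integer_,
                            score_pitches[out$score_ordinal + 1L])
  out$perf_pitch <- ifelse(is.na(out$perf_index), NA_integer_,
                           perf_pitches[out$perf_index])
  structure(out, hand = hand, cost = D[n + 1L, m + 1L],
            class = c("note_alignment", class(out)))
}

# ---- joint two-hand assignment ---------------------------------------------

# Score events grouped by notated onset; a group holds one note per hand.
# The DP consumes groups in order but lets the two members of a simultaneous
# pair be matched in either performed order (melody lead makes the RH note
# arrive before or after its LH partner).
score_event_groups <- function(score) {
  ons <- sort(unique(score$onset_beats))
  lapply(ons, function(o) {
    g <- score[abs(score$onset_beats - o) < 1e-9, , drop = FALSE]
    g[order(g$hand, decreasing = TRUE), , drop = FALSE]  # RH first
  })
}

#' Split a performance into per-hand streams via joint score alignment
#'
#' Aligns the performed pitch sequence (in onset order) against the score
#' with both hands merged, minimising total alignment cost; each performed
#' note inherits the hand of its matched score note. Unmatched performed
#' notes are labelled `extra` and assigned the hand of the nearest-pitch
#' score candidate at their position.
#'
#' @param performance A `piano_performance`.
#' @param score A `piano_score` (two hands, monophonic per hand).
#' @param costs See [alignment_costs()].
#' @return A list with per-hand alignments `rh` and `lh` (each a
#'   `note_alignment` whose `perf_index` points into the rows of
#'   `performance`), `assignment` (tibble: one row per performed note with
#'   its assigned `hand` and `status`), and the total `cost`.
#' @export
split_hands <- function(performance, score, costs = alignment_costs()) {
  if (nrow(performance) == 0) stop("empty performance", call. = FALSE)
  groups <- score_event_groups(score)
  G <- length(groups)
  perf_pitch <- performance$pitch
  P <- length(perf_pitch)
  c_gap <- costs$c_gap

  # state s(g, m): about to finish group g; m = 0 none consumed,
  # m = 1 first member consumed, m = 2 second member consumed.
  # Linear index: (g-1)*3 + m + 1; final state = 3*G + 1.
  n_state <- 3L * G + 1L
  sid <- function(g, m) if (g > G) n_state else (g - 1L) * 3L + m + 1L

  # incoming consume-edges per state: matrix rows (s_prev, group, member,
  # member pitch); member indexes the group's note table (1 or 2)
  incoming <- vector("list", n_state)
  add_edge <- function(s_to, s_from, g, mem) {
    incoming[[s_to]] <<- rbind(incoming[[s_to]],
                               c(s_from, g, mem, groups[[g]]$pitch[mem]))
  }
  for (g in seq_len(G)) {
    if (nrow(groups[[g]]) == 2L) {
      add_edge(sid(g, 1L), sid(g, 0L), g, 1L)
      add_edge(sid(g, 2L), sid(g, 0L), g, 2L)
      add_edge(sid(g + 1L, 0L), sid(g, 1L), g, 2L)
      add_edge(sid(g + 1L, 0L), sid(g, 2L), g, 1L)
    } else {
      add_edge(sid(g + 1L, 0L), sid(g, 0L), g, 1L)
    }
  }
  # topological order over reachable states
  topo <- c(unlist(lapply(seq_len(G), function(g) {
    if (nrow(groups[[g]]) == 2L) c(sid(g, 0L), sid(g, 1L), sid(g, 2L))
    else sid(g, 0L)
  })), n_state)

  D <- matrix(Inf, P + 1L, n_state)
  D[, sid(1L, 0L)] <- (0:P) * c_gap
  # choice codes: 0 none, 1 extra, 2 miss via edge k, 3 match via edge k
  FROM <- array(0L, dim = c(P + 1L, n_state, 2L))  # [ , , 1] code, [ , , 2] edge
  w <- costs$sub_window
  c_sub <- costs$c_sub
  for (s in topo) {
    edges <- incoming[[s]]
    n_edge <- if (is.null(edges)) 0L else nrow(edges)
    col_s <- D[, s]
    for (jj in 0:P) {
      best <- col_s[jj + 1L]
      code <- 0L; eidx <- 0L
      if (n_edge > 0L) {
        for (k in seq_len(n_edge)) {
          sp <- edges[k, 1L]
          if (jj > 0L) {
            d <- abs(edges[k, 4L] - perf_pitch[jj])
            if (d <= w) {
              cand <- D[jj, sp] + if (d == 0L) 0 else c_sub
              if (cand < best) { best <- cand; code <- 3L; eidx <- k }
            }
          }
          cand <- D[jj + 1L, sp] + c_gap   # missed score note
          if (cand < best) { best <- cand; code <- 2L; eidx <- k }
        }
      }
      if (jj > 0L) {
        cand <- col_s[jj] + c_gap          # extra performed note
        if (cand < best) { best <- cand; code <- 1L; eidx <- 0L }
      }
      col_s[jj + 1L] <- best
      FROM[jj + 1L, s, 1L] <- code
      FROM[jj + 1L, s, 2L] <- eidx
    }
    D[, s] <- col_s
  }

  total_cost <- D[P + 1L, n_state]
  # backtrace
  s <- n_state; jj <- P
  matches <- list(); missed <- list(); extras <- integer(0)
  while (!(s == sid(1L, 0L) && jj == 0L)) {
    code <- FROM[jj + 1L, s, 1L]
    if (code == 0L) {           # only reachable along initial extras column
      extras <- c(extras, jj); jj <- jj - 1L
      next
    }
    if (code == 1L) {
      extras <- c(extras, jj); jj <- jj - 1L
    } else {
      e <- incoming[[s]][FROM[jj + 1L, s, 2L], ]
      row <- groups[[e[2L]]][e[3L], , drop = FALSE]
      if (code == 3L) {
        matches[[length(matches) + 1L]] <-
          data.frame(hand = row$hand, score_ordinal = row$ordinal,
                     score_pitch = row$pitch, perf_index = jj,
                     status = if (row$pitch == perf_pitch[jj]) "match" else "sub")
        jj <- jj - 1L
      } else {
        missed[[length(missed) + 1L]] <-
          data.frame(hand = row$hand, score_ordinal = row$ordinal,
                     score_pitch = row$pitch, perf_index = NA_integer_,
                     status = "missed")
      }
      s <- e[1L]
    }
  }
  matched <- if (length(matches)) do.call(rbind, matches) else NULL
  missed <- if (length(missed)) do.call(rbind, missed) else NULL

  # extras inherit the hand of the nearest-pitch score candidate
  extra_rows <- NULL
  if (length(extras)) {
    all_sc <- as.data.frame(score)
    extra_rows <- do.call(rbind, lapply(extras, function(jx) {
      d <- abs(all_sc$pitch - perf_pitch[jx])
      cand <- all_sc[which(d == min(d)), , drop = FALSE]
      data.frame(hand = cand$hand[1], score_ordinal = NA_integer_,
                 score_pitch = NA_integer_, perf_index = jx,
                 status = "extra")
    }))
  }

  per_hand <- function(h) {
    rows <- rbind(
      if (!is.null(matched)) matched[matched$hand == h, , drop = FALSE],
      if (!is.null(missed)) missed[missed$hand == h, , drop = FALSE],
      if (!is.null(extra_rows)) extra_rows[extra_rows$hand == h, , drop = FALSE]
    )
    key <- ifelse(is.na(rows$score_ordinal),
                  rows$perf_index * 1e-6 + 1e6, rows$score_ordinal)
    rows <- rows[order(key), , drop = FALSE]
    out <- tibble::as_tibble(rows[, c("score_ordinal", "perf_index", "status",
                                      "score_pitch")])
    out$perf_pitch <- ifelse(is.na(out$perf_index), NA_integer_,
                             perf_pitch[out$perf_index])
    structure(out, hand = h, cost = NA_real_,
              class = c("note_alignment", class(out)))
  }

  assignment <- tibble::tibble(
    perf_index = seq_len(P),
    hand = NA_character_,
    status = NA_character_
  )
  fill <- rbind(matched, extra_rows)
  if (!is.null(fill)) {
    assignment$hand[fill$perf_index] <- fill$hand
    assignment$status[fill$perf_index] <- fill$status
  }

  list(rh = per_hand("RH"), lh = per_hand("LH"),
       assignment = assignment, cost = total_cost)
}

#' Write an alignment report CSV
#'
#' One row per score note and extra performed note:
#' `hand,score_ordinal,status,perf_onset_sec,perf_pitch,score_pitch`.
#'
#' @param hands Result of [split_hands()].
#' @param performance The aligned `piano_performance`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment_csv <- function(hands, performance, path) {
  rows <- rbind(
    cbind(hand = "RH", as.data.frame(hands$rh)),
    cbind(hand = "LH", as.data.frame(hands$lh))
  )
  rows$perf_onset_sec <- ifelse(is.na(rows$perf_index), NA_real_,
                                performance$onset_sec[rows$perf_index])
  utils::write.csv(
    rows[, c("hand", "score_ordinal", "status", "perf_onset_sec",
             "perf_pitch", "score_pitch")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
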