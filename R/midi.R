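# Standard MIDI File (SMF) input/output and the timed performed-note record.
# Only note-on/note-off and set-tempo events matter for the analysis; pedal
# and other controllers are ignored. Note-on with velocity 0 is treated as
# note-off, and overlapping same-pitch notes are resolved first-in-first-out.

#' Construct a performance object
#'
#' @param notes Data frame with columns `pitch`, `onset_sec`, `offset_sec`,
#'   `velocity` and optionally `source_track` and `truth_hand` (synthetic
#'   ground truth only).
#' @param performer_id,group,excerpt_id Metadata labels; `group` is one of
#'   `"expert"`, `"amateur"`, `"unknown"`.
#' @return A `piano_performance`: a tibble of notes sorted by
#'   (`onset_sec`, `pitch`).
#' @export
piano_performance <- function(notes, performer_id = "anonymous",
                              group = "unknown", excerpt_id = "unknown") {
  need <- c("pitch", "onset_sec", "offset_sec", "velocity")
  if (!all(need %in% names(notes))) {
    stop("performance table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(notes) > 0) {
    if (any(notes$offset_sec <= notes$onset_sec)) {
      stop("offset_sec must exceed onset_sec for every note")
    }
    if (any(notes$velocity < 1 | notes$velocity > 127)) {
      stop("velocity must lie in [1, 127]")
    }
  }
  if (is.null(notes$source_track)) {
    notes$source_track <- rep(1L, nrow(notes))
  }
  notes <- notes[order(notes$onset_sec, notes$pitch, method = "radix"), ]
  out <- tibble::as_tibble(notes)
  structure(out,
            performer_id = performer_id,
            group = match.arg(group, c("expert", "amateur", "unknown")),
            excerpt_id = excerpt_id,
            class = c("piano_performance", class(out)))
}

#' @export
print.piano_performance <- function(x, ...) {
  cat(sprintf("<piano_performance '%s'> %s, excerpt '%s', %d notes\n",
              attr(x, "performer_id"), attr(x, "group"),
              attr(x, "excerpt_id"), nrow(x)))
  NextMethod()
}

# ---- binary helpers ---------------------------------------------------------

vlq_encode <- function(x) {
  x <- as.integer(x)
  bytes <- as.raw(x %% 128L)
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(as.raw(bitwOr(x %% 128L, 128L)), bytes)
    x <- x %/% 128L
  }
  bytes
}

uint_be <- function(x, width) {
  out <- raw(width)
  for (i in seq_len(width)) {
    out[width - i + 1L] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

read_uint_be <- function(raw, from, width) {
  v <- 0
  for (i in seq_len(width)) v <- v * 256 + as.integer(raw[from + i - 1L])
  v
}

#' Write a performance as a Standard MIDI File
#'
#' Writes a format-1 file with a single track carrying a set-tempo event and
#' the note events on channel 1. Onset/offset rounding error is at most half
#' a tick.
#'
#' @param performance A `piano_performance`.
#' @param path Output file path.
#' @param ppq Pulses (ticks) per quarter note.
#' @param bpm Tempo written to the file, beats per minute.
#' @return Invisibly, `path`.
#' @export
write_smf <- function(performance, path, ppq = 480L, bpm = 120) {
  notes <- as.data.frame(performance)
  if (nrow(notes) > 0 && any(notes$velocity < 1)) {
    stop("velocity 0 is reserved for note-off; refusing to write")
  }
  us_per_qn <- round(60e6 / bpm)
  sec_to_tick <- function(s) as.integer(round(s * ppq * 1e6 / us_per_qn))

  ev <- NULL
  if (nrow(notes) > 0) {
    ev <- rbind(
      data.frame(tick = sec_to_tick(notes$onset_sec), on = 1L,
                 pitch = notes$pitch, vel = as.integer(round(notes$velocity))),
      data.frame(tick = sec_to_tick(notes$offset_sec), on = 0L,
                 pitch = notes$pitch, vel = 0L)
    )
    # offsets before onsets at equal tick so re-struck notes stay paired
    ev <- ev[order(ev$tick, ev$on, ev$pitch), ]
  }

  body <- list(vlq_encode(0L), as.raw(c(0xFF, 0x51, 0x03)), uint_be(us_per_qn, 3L))
  last <- 0L
  if (!is.null(ev)) {
    for (i in seq_len(nrow(ev))) {
      body[[length(body) + 1L]] <- vlq_encode(ev$tick[i] - last)
      last <- ev$tick[i]
      status <- if (ev$on[i] == 1L) 0x90 else 0x80
      body[[length(body) + 1L]] <-
        as.raw(c(status, ev$pitch[i], if (ev$on[i] == 1L) ev$vel[i] else 64L))
    }
  }
  body[[length(body) + 1L]] <- c(vlq_encode(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  track <- do.call(c, body)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MThd"), con)
  writeBin(c(uint_be(6L, 4L), uint_be(1L, 2L), uint_be(1L, 2L),
             uint_be(as.integer(ppq), 2L)), con)
  writeBin(charToRaw("MTrk"), con)
  writeBin(c(uint_be(length(track), 4L), track), con)
  invisible(path)
}

#' Read a Standard MIDI File into a performance
#'
#' Supports SMF format 0 and 1 with metrical timing. Note-on/note-off pairs
#' are resolved per pitch in FIFO order; note-on with velocity 0 counts as
#' note-off; all set-tempo events are honoured when converting ticks to
#' seconds.
#'
#' @param path SMF file path.
#' @param performer_id,group,excerpt_id Metadata attached to the result.
#' @return A `piano_performance`.
#' @export
read_smf <- function(path, performer_id = basename(path), group = "unknown",
                     excerpt_id = "unknown") {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 14 || rawToChar(raw[1:4]) != "MThd") {
    stop("not a Standard MIDI File: ", path)
  }
  format <- read_uint_be(raw, 9L, 2L)
  ntrk <- read_uint_be(raw, 11L, 2L)
  division <- read_uint_be(raw, 13L, 2L)
  if (!format %in% c(0, 1)) stop("only SMF format 0/1 supported, got ", format)
  if (division >= 32768) stop("SMPTE time division is not supported")

  pos <- 15L
  events <- vector("list", ntrk)
  tempos <- list(data.frame(tick = 0, us = 500000))
  for (tr in seq_len(ntrk)) {
    if (rawToChar(raw[pos:(pos + 3L)]) != "MTrk") stop("missing MTrk chunk")
    len <- read_uint_be(raw, pos + 4L, 4L)
    p <- pos + 8L
    end <- p + len
    tick <- 0
    status <- 0L
    ons <- list(); offs <- list()
    while (p < end) {
      # variable-length delta time
      dt <- 0
      repeat {
        b <- as.integer(raw[p]); p <- p + 1L
        dt <- dt * 128 + (b %% 128L)
        if (b < 128L) break
      }
      tick <- tick + dt
      b <- as.integer(raw[p])
      if (b >= 128L) { status <- b; p <- p + 1L } # else running status
      if (status == 255L) {                        # meta event
        type <- as.integer(raw[p]); p <- p + 1L
        mlen <- 0
        repeat {
          bb <- as.integer(raw[p]); p <- p + 1L
          mlen <- mlen * 128 + (bb %% 128L)
          if (bb < 128L) break
        }
        if (type == 0x51 && mlen == 3) {
          us <- read_uint_be(raw, p, 3L)
          tempos[[length(tempos) + 1L]] <- data.frame(tick = tick, us = us)
        }
        p <- p + mlen
      } else if (status %in% c(0xF0, 0xF7)) {      # sysex
        mlen <- 0
        repeat {
          bb <- as.integer(raw[p]); p <- p + 1L
          mlen <- mlen * 128 + (bb %% 128L)
          if (bb < 128L) break
        }
        p <- p + mlen
      } else {
        hi <- status %/% 16L
        if (hi == 9L) {                            # note on
          pitch <- as.integer(raw[p]); vel <- as.integer(raw[p + 1L]); p <- p + 2L
          if (vel > 0) ons[[length(ons) + 1L]] <- c(tick, pitch, vel)
          else offs[[length(offs) + 1L]] <- c(tick, pitch)
        } else if (hi == 8L) {                     # note off
          pitch <- as.integer(raw[p]); p <- p + 2L
          offs[[length(offs) + 1L]] <- c(tick, pitch)
        } else if (hi %in% c(12L, 13L)) {          # 1 data byte messages
          p <- p + 1L
        } else {                                   # 2 data byte messages
          p <- p + 2L
        }
      }
    }
    events[[tr]] <- list(ons = ons, offs = offs)
    pos <- end
  }

  tempo_map <- do.call(rbind, tempos)
  tempo_map <- tempo_map[!duplicated(tempo_map$tick, fromLast = TRUE), ]
  tempo_map <- tempo_map[order(tempo_map$tick), ]
  # cumulative seconds at each tempo change
  tsec <- c(0, cumsum(diff(tempo_map$tick) *
                        tempo_map$us[-nrow(tempo_map)] / (1e6 * division)))
  tick_to_sec <- function(tick) {
    i <- findInterval(tick, tempo_map$tick)
    tsec[i] + (tick - tempo_map$tick[i]) * tempo_map$us[i] / (1e6 * division)
  }

  notes <- list()
  dangling <- integer(0)
  for (tr in seq_along(events)) {
    ons <- events[[tr]]$ons; offs <- events[[tr]]$offs
    if (length(ons) == 0) next
    onm <- do.call(rbind, ons)
    offm <- if (length(offs)) do.call(rbind, offs) else
      matrix(numeric(0), ncol = 2)
    for (pc in unique(onm[, 2])) {
      q_on <- onm[onm[, 2] == pc, , drop = FALSE]
      q_off <- offm[offm[, 2] == pc, , drop = FALSE]
      n <- min(nrow(q_on), nrow(q_off))
      if (nrow(q_on) > nrow(q_off)) dangling <- c(dangling, rep(pc, nrow(q_on) - n))
      if (n > 0) {
        notes[[length(notes) + 1L]] <- data.frame(
          pitch = pc,
          onset_sec = tick_to_sec(q_on[seq_len(n), 1]),
          offset_sec = tick_to_sec(q_off[seq_len(n), 1]),
          velocity = q_on[seq_len(n), 3],
          source_track = tr
        )
      }
    }
  }
  if (length(dangling)) {
    stop("dangling note-on events at end of file for pitches: ",
         paste(sort(unique(dangling)), collapse = ", "))
  }
  notes <- if (length(notes)) do.call(rbind, notes) else
    data.frame(pitch = integer(0), onset_sec = numeric(0),
               offset_sec = numeric(0), velocity = integer(0),
               source_track = integer(0))
  piano_performance(notes, performer_id = performer_id, group = group,
                    excerpt_id = excerpt_id)
}
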