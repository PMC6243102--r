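# Minimal Standard MIDI File (format 0/1) support: note on/off round-tripping
# in the beats domain. Tempo meta events are deliberately ignored -- onsets are
# metrical, ticks / ticks-per-quarter -- and channel 10 (percussion) is
# skipped on read. Grace flags and slur groups have no SMF representation and
# are dropped on write / absent on read.

uint_be <- function(x, n_bytes) {
  as.raw((x %/% 256^((n_bytes - 1):0)) %% 256)
}

varint_encode <- function(x) {
  if (x == 0) return(as.raw(0))
  bytes <- integer(0)
  while (x > 0) {
    bytes <- c(x %% 128, bytes)
    x <- x %/% 128
  }
  as.raw(c(bytes[-length(bytes)] + 128L, bytes[length(bytes)]))
}

#' Write a notes table as a Standard MIDI File
#'
#' Format-0 single-track SMF with one note-on/note-off pair per note on
#' channel 1. Beat positions are quantised to `ticks_per_quarter`; onsets that
#' are exact multiples of `1/ticks_per_quarter` beat round-trip through
#' [read_notes()] without loss.
#'
#' @param notes A notes tibble; pitches must be valid MIDI (0-127).
#' @param path Output path.
#' @param ticks_per_quarter Tick resolution (default 960).
#' @return `path`, invisibly.
#' @export
write_midi <- function(notes, path, ticks_per_quarter = 960L) {
  stopifnot(all(notes$pitch >= 0L), all(notes$pitch <= 127L))
  on_t <- round(notes$onset * ticks_per_quarter)
  off_t <- round((notes$onset + notes$duration) * ticks_per_quarter)
  off_t <- pmax(off_t, on_t + 1L)
  ev <- tibble(
    tick = c(on_t, off_t),
    kind = rep(c(1L, 0L), each = nrow(notes)),  # offs sort before ons at a tick
    pitch = rep(notes$pitch, 2L)
  ) |>
    dplyr::arrange(.data$tick, .data$kind, .data$pitch)
  body <- raw(0)
  last <- 0
  chunks <- vector("list", nrow(ev) + 1L)
  for (i in seq_len(nrow(ev))) {
    delta <- ev$tick[i] - last
    last <- ev$tick[i]
    status <- if (ev$kind[i] == 1L) 0x90 else 0x80
    chunks[[i]] <- c(varint_encode(delta),
                     as.raw(c(status, ev$pitch[i], if (ev$kind[i] == 1L) 64 else 0)))
  }
  chunks[[nrow(ev) + 1L]] <- as.raw(c(0x00, 0xFF, 0x2F, 0x00))  # end of track
  track <- do.call(c, chunks)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("MThd"), uint_be(6, 4), uint_be(0, 2), uint_be(1, 2),
             uint_be(ticks_per_quarter, 2),
             charToRaw("MTrk"), uint_be(length(track), 4), track), con)
  invisible(path)
}

read_midi <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw_all <- readBin(path, "raw", file.info(path)$size)
  rd_int <- function(pos, n) sum(as.integer(raw_all[pos:(pos + n - 1)]) * 256^((n - 1):0))
  if (length(raw_all) < 14 || rawToChar(raw_all[1:4]) != "MThd") {
    abort(paste0("Unparseable MIDI at ", path, ": byte 1, missing MThd header."))
  }
  fmt <- rd_int(9, 2)
  ntrk <- rd_int(11, 2)
  division <- rd_int(13, 2)
  if (fmt > 1L) abort(paste0(path, ": only SMF format 0/1 supported."))
  if (division >= 0x8000) abort(paste0(path, ": SMPTE time division unsupported."))
  pos <- 15
  ons <- list()  # per (channel, pitch) FIFO of pending note-on ticks
  notes <- list()
  for (trk in seq_len(ntrk)) {
    if (pos + 7 > length(raw_all) || rawToChar(raw_all[pos:(pos + 3)]) != "MTrk") {
      abort(sprintf("Unparseable MIDI at %s: byte %d, expected MTrk.", path, pos))
    }
    len <- rd_int(pos + 4, 4)
    end <- pos + 8 + len
    p <- pos + 8
    tick <- 0
    status <- NULL
    while (p < end) {
      # variable-length delta time
      delta <- 0
      repeat {
        b <- as.integer(raw_all[p]); p <- p + 1
        delta <- delta * 128 + (b %% 128)
        if (b < 128) break
      }
      tick <- tick + delta
      b <- as.integer(raw_all[p])
      if (b >= 128) { status <- b; p <- p + 1 }
      if (is.null(status)) {
        abort(sprintf("Unparseable MIDI at %s: byte %d, running status without status.",
                      path, p))
      }
      hi <- status %/% 16
      ch <- status %% 16
      if (hi == 8 || hi == 9) {
        pitch <- as.integer(raw_all[p]); vel <- as.integer(raw_all[p + 1]); p <- p + 2
        if (ch != 9) {  # skip percussion channel 10
          key <- paste0(ch, ":", pitch)
          if (hi == 9 && vel > 0) {
            ons[[key]] <- c(ons[[key]], tick)
          } else {
            if (is.null(ons[[key]]) || length(ons[[key]]) == 0) {
              abort(sprintf("%s: unmatched note-off (pitch %d, byte %d).",
                            path, pitch, p))
            }
            notes[[length(notes) + 1L]] <- c(ons[[key]][1], tick, pitch)
            ons[[key]] <- ons[[key]][-1]
          }
        }
      } else if (hi %in% c(10, 11, 14)) {
        p <- p + 2
      } else if (hi %in% c(12, 13)) {
        p <- p + 1
      } else if (status == 0xFF) {
        p <- p + 1  # meta type
        mlen <- 0
        repeat {
          b2 <- as.integer(raw_all[p]); p <- p + 1
          mlen <- mlen * 128 + (b2 %% 128)
          if (b2 < 128) break
        }
        p <- p + mlen
        status <- NULL
      } else if (status %in% c(0xF0, 0xF7)) {
        slen <- 0
        repeat {
          b2 <- as.integer(raw_all[p]); p <- p + 1
          slen <- slen * 128 + (b2 %% 128)
          if (b2 < 128) break
        }
        p <- p + slen
        status <- NULL
      } else {
        abort(sprintf("Unparseable MIDI at %s: byte %d, status 0x%X.", path, p, status))
      }
    }
    pos <- end
  }
  if (any(lengths(ons) > 0)) {
    abort(paste0(path, ": unbalanced note-on without note-off."))
  }
  if (length(notes) == 0) {
    return(tibble(onset = numeric(), duration = numeric(), pitch = integer(),
                  is_grace = logical(), slur_group = integer()))
  }
  mat <- do.call(rbind, notes)
  tibble(
    onset = mat[, 1] / division,
    duration = pmax(mat[, 2] - mat[, 1], 1) / division,
    pitch = as.integer(mat[, 3]),
    is_grace = FALSE,
    slur_group = NA_integer_
  )
}
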