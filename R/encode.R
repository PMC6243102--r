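#' Relative n-gram encodings of a skyline melody
#'
#' Re-encode a monophonic melody line into the overlapping n-gram windows of
#' one of four relative spectro-temporal sequence types:
#'
#' * `"pitch"` -- pitch only. Each window of `order + 1` consecutive notes is
#'   re-zeroed so its first pitch is 0 and every other token is the signed
#'   semitone offset from that first pitch. Transposition cancels exactly.
#' * `"rhythm"` -- onsets only. Each window of `order + 1` consecutive
#'   inter-onset intervals (IOIs, so `order + 2` notes) is expressed as ratios
#'   to the window's first IOI (first token 1). Tempo cancels exactly.
#' * `"pitch_rhythm"` -- pitch tokens as in `"pitch"`, paired with the
#'   window's `order` IOIs. For `order >= 2` the IOIs are ratios to the
#'   window's first IOI; at order 1 a single IOI has nothing to be a ratio of,
#'   so it is taken as a ratio to the crotchet (quarter note = 1 beat).
#' * `"rhythm_pitch"` -- IOI-ratio tokens as in `"rhythm"` (windows of
#'   `order + 2` notes), paired with all `order + 2` re-zeroed pitch tokens.
#'
#' In every type the *continuation* is the window's final token (final
#' pitch/rhythm pair for the joint types) and the *context* is everything that
#' precedes it; windows overlap with stride 1. Rhythm ratios are rounded to 3
#' decimals before tokenisation, so 1/3 becomes `0.333`.
#'
#' @param melody A melody tibble as returned by [extract_melody()]: columns
#'   `onset` and `pitch`, plus optional piece identifier columns that are
#'   carried through. Multiple pieces (a `piece_id` column) are encoded
#'   independently.
#' @param type One of `"pitch"`, `"rhythm"`, `"pitch_rhythm"`,
#'   `"rhythm_pitch"`.
#' @param order Markov order, an integer from 1 to 6.
#'
#' @return A tibble with the piece identifier columns of `melody` plus
#'   `sequence_type`, `order`, `context`, `continuation` and `pattern`
#'   (the full serialised window, e.g. `"[0, -1, -2] with [1, 0.5]"`).
#'   Melodies shorter than one window yield zero rows.
#' @examples
#' m <- tibble::tibble(onset = c(0, 1, 1.5), pitch = c(60, 59, 58))
#' encode_windows(m, "pitch_rhythm", 2)$pattern  # "[0, -1, -2] with [1, 0.5]"
#' @export
encode_windows <- function(melody, type = c("pitch", "rhythm", "pitch_rhythm",
                                            "rhythm_pitch"), order = 1L) {
  type <- match.arg(type)
  stopifnot(is.data.frame(melody), all(c("onset", "pitch") %in% names(melody)))
  order <- as.integer(order)
  if (length(order) != 1L || is.na(order) || order < 1L || order > 6L) {
    abort("`order` must be a single integer between 1 and 6.")
  }
  ids <- id_cols(melody)
  if ("piece_id" %in% ids && dplyr::n_distinct(melody$piece_id) > 1L) {
    out <- melody |>
      dplyr::group_by(.data$piece_id) |>
      dplyr::group_split() |>
      purrr::map(encode_windows, type = type, order = order) |>
      purrr::list_rbind()
    return(out)
  }
  if (is.unsorted(melody$onset, strictly = TRUE)) {
    abort("`melody` onsets must be strictly increasing within a piece.")
  }
  enc <- switch(type,
    pitch        = encode_pitch_core(melody$pitch, order),
    rhythm       = encode_rhythm_core(melody$onset, order),
    pitch_rhythm = encode_pitch_rhythm_core(melody$pitch, melody$onset, order),
    rhythm_pitch = encode_rhythm_pitch_core(melody$pitch, melody$onset, order)
  )
  n_win <- length(enc$context)
  meta <- dplyr::slice_head(dplyr::select(melody, dplyr::all_of(ids)), n = 1L)
  out <- tibble(
    sequence_type = rep(type, n_win),
    order = rep(order, n_win),
    context = enc$context,
    continuation = enc$continuation,
    pattern = enc$pattern
  )
  if (length(ids) && n_win > 0L) {
    out <- dplyr::bind_cols(meta[rep(1L, n_win), , drop = FALSE], out)
  } else if (length(ids)) {
    out <- dplyr::bind_cols(meta[0L, , drop = FALSE], out)
  }
  out
}

#' @rdname encode_windows
#' @export
encode_pitch <- function(melody, order = 1L) encode_windows(melody, "pitch", order)

#' @rdname encode_windows
#' @export
encode_rhythm <- function(melody, order = 1L) encode_windows(melody, "rhythm", order)

#' @rdname encode_windows
#' @export
encode_pitch_rhythm <- function(melody, order = 1L) {
  encode_windows(melody, "pitch_rhythm", order)
}

#' @rdname encode_windows
#' @export
encode_rhythm_pitch <- function(melody, order = 1L) {
  encode_windows(melody, "rhythm_pitch", order)
}

empty_enc <- list(context = character(), continuation = character(),
                  pattern = character())

# rows = windows of `width` consecutive values, oldest first
slide_mat <- function(x, width) {
  m <- stats::embed(x, width)
  m[, width:1, drop = FALSE]
}

pitch_token_mat <- function(pitch, width) {
  m <- slide_mat(as.numeric(pitch), width)
  m <- m - m[, 1L]
  apply(m, 2L, format_pitch_token)
}

ratio_token_mat <- function(ioi, width) {
  m <- slide_mat(ioi, width)
  m <- m / m[, 1L]
  apply(m, 2L, format_ratio_token)
}

as_mat <- function(x, ncol) {
  if (is.matrix(x)) x else matrix(x, ncol = ncol)
}

encode_pitch_core <- function(pitch, n) {
  if (length(pitch) < n + 1L) return(empty_enc)
  tok <- as_mat(pitch_token_mat(pitch, n + 1L), n + 1L)
  ctx <- do.call(bracket, asplit(tok[, seq_len(n), drop = FALSE], 2L))
  list(context = ctx,
       continuation = tok[, n + 1L],
       pattern = do.call(bracket, asplit(tok, 2L)))
}

check_iois <- function(ioi) {
  if (any(ioi <= 0)) {
    warn("Non-positive inter-onset intervals encountered; affected windows dropped.")
  }
  ioi
}

encode_rhythm_core <- function(onset, n) {
  d <- check_iois(diff(onset))
  if (length(d) < n + 1L) return(empty_enc)
  keep <- rowSums(slide_mat(d, n + 1L) <= 0) == 0
  tok <- as_mat(ratio_token_mat(d, n + 1L), n + 1L)[keep, , drop = FALSE]
  if (nrow(tok) == 0L) return(empty_enc)
  ctx <- do.call(bracket, asplit(tok[, seq_len(n), drop = FALSE], 2L))
  list(context = ctx,
       continuation = tok[, n + 1L],
       pattern = do.call(bracket, asplit(tok, 2L)))
}

encode_pitch_rhythm_core <- function(pitch, onset, n) {
  if (length(pitch) < n + 1L) return(empty_enc)
  p <- as_mat(pitch_token_mat(pitch, n + 1L), n + 1L)
  d <- check_iois(diff(onset))
  if (n == 1L) {
    # a single IOI has no in-window reference; use the crotchet (1 beat)
    r <- matrix(format_ratio_token(d), ncol = 1L)
  } else {
    r <- as_mat(ratio_token_mat(d, n), n)[seq_len(nrow(p)), , drop = FALSE]
  }
  pctx <- do.call(bracket, asplit(p[, seq_len(n), drop = FALSE], 2L))
  rctx <- if (n == 1L) rep("[]", nrow(p)) else {
    do.call(bracket, asplit(r[, seq_len(n - 1L), drop = FALSE], 2L))
  }
  list(
    context = paste(pctx, "with", rctx),
    continuation = paste(p[, n + 1L], "with", r[, n]),
    pattern = paste(do.call(bracket, asplit(p, 2L)), "with",
                    do.call(bracket, asplit(r, 2L)))
  )
}

encode_rhythm_pitch_core <- function(pitch, onset, n) {
  d <- check_iois(diff(onset))
  if (length(d) < n + 1L) return(empty_enc)
  keep <- rowSums(slide_mat(d, n + 1L) <= 0) == 0
  r <- as_mat(ratio_token_mat(d, n + 1L), n + 1L)[keep, , drop = FALSE]
  p <- as_mat(pitch_token_mat(pitch, n + 2L), n + 2L)[keep, , drop = FALSE]
  if (nrow(r) == 0L) return(empty_enc)
  rctx <- do.call(bracket, asplit(r[, seq_len(n), drop = FALSE], 2L))
  pctx <- do.call(bracket, asplit(p[, seq_len(n + 1L), drop = FALSE], 2L))
  list(
    context = paste(rctx, "with", pctx),
    continuation = paste(r[, n + 1L], "with", p[, n + 2L]),
    pattern = paste(do.call(bracket, asplit(r, 2L)), "with",
                    do.call(bracket, asplit(p, 2L)))
  )
}
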