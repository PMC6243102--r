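#' Specify a synthetic "musician": a seeded Markov melody generator
#'
#' A musician spec bundles everything needed to sample improvised-sounding
#' pieces with known ground truth: an order-`g` Markov chain over
#' pitch-interval tokens, an i.i.d. distribution over inter-onset-interval
#' (IOI) tokens in beats, decoration rates (chords below the melody, flagged
#' grace notes), per-piece transposition and tempo scaling, and an optional
#' linear chronological drift of selected transition probabilities.
#'
#' @param musician_id Non-empty identifier string.
#' @param intervals Integer alphabet of pitch-interval tokens (semitones).
#' @param tp Transition matrix: one row per interval `g`-tuple context (in
#'   [context_keys()] order), one column per interval; rows sum to 1. Build
#'   with [peaked_tp()] or [signature_tp()].
#' @param order Generator order `g` (number of conditioning intervals), 1-6.
#' @param ioi_values,ioi_probs IOI token values in beats and their sampling
#'   probabilities. Defaults cover common subdivisions from semiquaver to
#'   dotted minim with mass concentrated on quavers and crotchets; thirds are
#'   exact (`1/3`, `2/3`) so that ratio tokens collide as intended.
#' @param chord_prob Per-note probability of adding 1-2 lower chord tones at
#'   the same onset.
#' @param grace_prob Per-note probability of inserting a flagged grace note
#'   just before the melody note.
#' @param transposition Semitone offset(s) added to all pitches; scalar or one
#'   value per chronological index.
#' @param tempo_scale Multiplier(s) on all onsets; scalar or one value per
#'   chronological index.
#' @param drift Optional tibble with columns `context` (comma-joined interval
#'   context key), `interval` and `slope`: the named transition's probability
#'   changes by `slope` per unit chronological index (from index 1), the
#'   context's remaining mass being rescaled proportionally.
#' @param start_pitch MIDI pitch of the first note before transposition.
#' @return An object of class `musician_spec`.
#' @export
musician_spec <- function(musician_id, intervals, tp, order,
                          ioi_values = c(1/4, 1/3, 1/2, 2/3, 1, 3/2, 2, 3),
                          ioi_probs = c(.05, .10, .25, .10, .25, .10, .10, .05),
                          chord_prob = 0, grace_prob = 0,
                          transposition = 0L, tempo_scale = 1,
                          drift = NULL, start_pitch = 66L) {
  stopifnot(is.character(musician_id), nzchar(musician_id),
            length(intervals) >= 2, !anyDuplicated(intervals),
            order >= 1, order <= 6,
            length(ioi_values) == length(ioi_probs), all(ioi_values > 0),
            all(ioi_probs >= 0), chord_prob >= 0, chord_prob <= 1,
            grace_prob >= 0, grace_prob <= 1, all(tempo_scale > 0))
  m <- length(intervals)
  tp <- as.matrix(tp)
  if (nrow(tp) != m^order || ncol(tp) != m) {
    abort(sprintf("`tp` must be %d x %d for order %d over %d intervals.",
                  m^order, m, order, m))
  }
  if (any(tp < 0) || any(abs(rowSums(tp) - 1) > 1e-9)) {
    abort("`tp` rows must be non-negative and sum to 1.")
  }
  rownames(tp) <- context_keys(intervals, order)
  colnames(tp) <- as.character(intervals)
  if (!is.null(drift)) {
    stopifnot(is.data.frame(drift),
              all(c("context", "interval", "slope") %in% names(drift)),
              all(drift$context %in% rownames(tp)),
              all(as.character(drift$interval) %in% colnames(tp)))
  }
  structure(
    list(musician_id = musician_id, intervals = as.integer(intervals),
         tp = tp, order = as.integer(order),
         ioi_values = ioi_values, ioi_probs = ioi_probs / sum(ioi_probs),
         chord_prob = chord_prob, grace_prob = grace_prob,
         transposition = as.integer(transposition), tempo_scale = tempo_scale,
         drift = drift, start_pitch = as.integer(start_pitch)),
    class = "musician_spec"
  )
}

#' @export
print.musician_spec <- function(x, ...) {
  cat(sprintf(
    "<musician_spec '%s'> order-%d Markov over %d intervals; chords %.0f%%, graces %.0f%%%s\n",
    x$musician_id, x$order, length(x$intervals),
    100 * x$chord_prob, 100 * x$grace_prob,
    if (is.null(x$drift)) "" else sprintf("; %d drifting pattern(s)", nrow(x$drift))
  ))
  invisible(x)
}

#' Enumerate interval-context keys
#'
#' All `length(intervals)^order` ordered `g`-tuples over the interval
#' alphabet, as comma-joined keys, with the first position varying fastest.
#' This is the canonical row order of a generator transition matrix.
#'
#' @inheritParams musician_spec
#' @return Character vector of context keys, e.g. `"-1,2"`.
#' @export
context_keys <- function(intervals, order) {
  g <- do.call(expand.grid, rep(list(intervals), order))
  apply(as.matrix(g), 1L, paste, collapse = ",")
}

context_tuples <- function(intervals, order) {
  as.matrix(do.call(expand.grid, rep(list(intervals), order)))
}

#' Simple generator transition matrices
#'
#' `peaked_tp()` gives every context a single dominant continuation holding
#' probability `peak`, the rest uniform; the dominant interval rotates with
#' the context (index-sum modulo alphabet size) so the chain mixes and the
#' marginal stays near-uniform. `signature_tp()` mixes a shared baseline
#' distribution with a musician-specific deterministic "signature" map:
#' `P(next | ctx) = (1 - weight) * base_probs + weight * [next == f(ctx)]`,
#' where `f` rotates by `shift`. Specs built with equal `base_probs` but
#' different `shift` share low-order statistics while differing in the
#' structure only visible at window order `order + 1` and beyond.
#'
#' @inheritParams musician_spec
#' @param peak Probability of each context's dominant continuation.
#' @param base_probs Shared baseline distribution over `intervals`.
#' @param weight Mixing weight of the signature map, in `[0, 1]`.
#' @param shift Integer rotation identifying the musician's signature.
#' @return A row-stochastic matrix suitable for [musician_spec()].
#' @export
peaked_tp <- function(intervals, order, peak = 0.6) {
  m <- length(intervals)
  stopifnot(peak > 0, peak < 1, m >= 2)
  tup <- context_tuples(intervals, order)
  idx0 <- matrix(match(tup, intervals) - 1L, nrow = nrow(tup))
  dom <- (rowSums(idx0)) %% m + 1L
  tp <- matrix((1 - peak) / (m - 1), nrow = m^order, ncol = m)
  tp[cbind(seq_along(dom), dom)] <- peak
  tp
}

#' @rdname peaked_tp
#' @export
signature_tp <- function(intervals, order, base_probs, weight = 0.6, shift = 0L) {
  m <- length(intervals)
  stopifnot(length(base_probs) == m, all(base_probs >= 0),
            abs(sum(base_probs) - 1) < 1e-9, weight >= 0, weight <= 1)
  tup <- context_tuples(intervals, order)
  idx0 <- matrix(match(tup, intervals) - 1L, nrow = nrow(tup))
  sig <- (rowSums(idx0) + shift) %% m + 1L
  tp <- matrix(rep((1 - weight) * base_probs, each = m^order), nrow = m^order)
  tp[cbind(seq_along(sig), sig)] <- tp[cbind(seq_along(sig), sig)] + weight
  tp
}

#' Generator table after chronological drift
#'
#' The transition matrix a spec actually uses at a given chronological index:
#' each drifting pattern's probability is moved linearly
#' (`p + slope * (index - 1)`, clamped to `[0, 0.99]`) and the context's other
#' continuations are rescaled proportionally to keep the row stochastic.
#'
#' @param spec A [musician_spec()].
#' @param chronological_index Positive integer (1 = earliest piece).
#' @return A row-stochastic matrix like `spec$tp`.
#' @export
drifted_tp <- function(spec, chronological_index = 1L) {
  tp <- spec$tp
  if (is.null(spec$drift)) return(tp)
  for (i in seq_len(nrow(spec$drift))) {
    ctx <- spec$drift$context[i]
    col <- as.character(spec$drift$interval[i])
    p_new <- min(max(tp[ctx, col] + spec$drift$slope[i] * (chronological_index - 1),
                     0), 0.99)
    rest <- setdiff(colnames(tp), col)
    old_rest <- sum(tp[ctx, rest])
    tp[ctx, rest] <- if (old_rest > 0) tp[ctx, rest] * (1 - p_new) / old_rest else
      (1 - p_new) / length(rest)
    tp[ctx, col] <- p_new
  }
  tp
}

stationary_contexts <- function(tp, intervals, order) {
  m <- length(intervals)
  n_ctx <- nrow(tp)
  # context (i1..ig) --j--> (i2..ig, j); index arithmetic matches the
  # expand.grid enumeration (first position varying fastest)
  idx <- seq_len(n_ctx) - 1L
  Tm <- matrix(0, n_ctx, n_ctx)
  for (j in seq_len(m)) {
    tgt <- idx %/% m + (j - 1L) * m^(order - 1L) + 1L
    Tm[cbind(seq_len(n_ctx), tgt)] <- Tm[cbind(seq_len(n_ctx), tgt)] + tp[, j]
  }
  pi_vec <- rep(1 / n_ctx, n_ctx)
  for (it in 1:2000) {
    nxt <- as.vector(pi_vec %*% Tm)
    if (max(abs(nxt - pi_vec)) < 1e-14) { pi_vec <- nxt; break }
    pi_vec <- nxt
  }
  pi_vec / sum(pi_vec)
}

#' Ground-truth conditional entropy of a generator
#'
#' The conditional entropy, in bits, of the next interval given the last
#' `order` intervals under the generator's stationary context distribution:
#' the value the plug-in entropy of an encoded pitch stream (at window order
#' `order + 1`) converges to as piece length grows.
#'
#' @inheritParams drifted_tp
#' @return Entropy in bits.
#' @export
spec_entropy <- function(spec, chronological_index = 1L) {
  tp <- drifted_tp(spec, chronological_index)
  pi_ctx <- stationary_contexts(tp, spec$intervals, spec$order)
  row_h <- apply(tp, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  sum(pi_ctx * row_h)
}

#' Ground-truth TP table in encoded-window coordinates
#'
#' Translate a generator's interval transition matrix into the serialised
#' `(context, continuation)` vocabulary produced by
#' `encode_windows(type = "pitch", order = spec$order + 1)`: a window of
#' `order + 2` notes whose context covers exactly the generator's `order`
#' conditioning intervals. Used to compare pipeline estimates against truth.
#'
#' @inheritParams drifted_tp
#' @return A tibble with `context`, `continuation`, `pattern`, `tp_true` and
#'   `context_prob` (stationary probability of the context).
#' @export
spec_tp_table <- function(spec, chronological_index = 1L) {
  tp <- drifted_tp(spec, chronological_index)
  pi_ctx <- stationary_contexts(tp, spec$intervals, spec$order)
  tup <- context_tuples(spec$intervals, spec$order)
  cs <- apply(tup, 1L, cumsum)
  cs <- if (is.matrix(cs)) t(cs) else matrix(cs, ncol = 1L)
  ctx_tokens <- cbind(0L, cs)
  tok <- apply(ctx_tokens, 2L, format_pitch_token)
  if (!is.matrix(tok)) tok <- matrix(tok, nrow = 1L)
  ctx_str <- do.call(bracket, asplit(tok, 2L))
  purrr::map(seq_along(spec$intervals), function(j) {
    cont <- ctx_tokens[, ncol(ctx_tokens)] + spec$intervals[j]
    tibble(
      context = ctx_str,
      continuation = format_pitch_token(cont),
      tp_true = tp[, j],
      context_prob = pi_ctx
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(pattern = paste0(sub("\\]$", "", .data$context), ", ",
                                   .data$continuation, "]"),
                  .after = "continuation")
}

#' Sample one synthetic piece with ground truth
#'
#' Draw interval and IOI tokens from the (possibly drifted) generator,
#' integrate them into absolute pitches and beat onsets, then decorate with
#' chords, grace notes, transposition and tempo scaling. Both the decorated
#' polyphonic notes table and the clean monophonic truth line are returned;
#' with decoration rates at zero, [extract_melody()] of the notes reproduces
#' the truth line exactly.
#'
#' @inheritParams drifted_tp
#' @param length Number of melody notes `L` (must be at least `order + 2`).
#' @param seed Optional integer seed for this piece.
#' @param fold Length-2 numeric range into which absolute pitches are folded
#'   by octave shifts (keeps long walks within a playable register), or
#'   `NULL` to disable. Folding perturbs the few windows that straddle a fold,
#'   so disable it for asymptotic parameter-recovery studies.
#' @return A list with `notes` (decorated piece), `truth` (clean melody
#'   tibble), `intervals` and `iois` (the sampled tokens) and `tp` (the
#'   drifted transition matrix actually used).
#' @export
sample_piece <- function(spec, chronological_index = 1L, length = 500L,
                         seed = NULL, fold = c(24L, 108L)) {
  stopifnot(inherits(spec, "musician_spec"))
  if (length < spec$order + 2L) {
    abort(sprintf("`length` must be at least order + 2 = %d.", spec$order + 2L))
  }
  if (!is.null(seed)) set.seed(seed)
  tp <- drifted_tp(spec, chronological_index)
  m <- length(spec$intervals)
  g <- spec$order
  marginal <- colMeans(tp)
  n_int <- length - 1L
  ints_idx <- integer(n_int)
  u <- stats::runif(n_int)
  cum_marg <- cumsum(marginal)
  state <- 0L  # base-m encoding of last g interval indices (oldest fastest)
  tp_cum <- t(apply(tp, 1L, cumsum))
  for (t in seq_len(n_int)) {
    if (t <= g) {
      j <- findInterval(u[t], cum_marg) + 1L  # warm-up: marginal draws
    } else {
      j <- findInterval(u[t], tp_cum[state + 1L, ]) + 1L
    }
    j <- min(j, m)
    ints_idx[t] <- j
    if (t == g) {
      state <- sum((ints_idx[1:g] - 1L) * m^(0:(g - 1L)))
    } else if (t > g) {
      state <- (state %/% m) + (j - 1L) * m^(g - 1L)
    }
  }
  ints <- spec$intervals[ints_idx]

  # integrate pitches, folding by octaves into the playable range
  pitches <- integer(length)
  pitches[1] <- spec$start_pitch
  if (is.null(fold)) {
    pitches <- spec$start_pitch + c(0L, cumsum(ints))
  } else {
    for (t in 2:length) {
      p <- pitches[t - 1L] + ints[t - 1L]
      while (p > fold[2]) p <- p - 12L
      while (p < fold[1]) p <- p + 12L
      pitches[t] <- p
    }
  }
  transpo <- rep_len(spec$transposition, max(chronological_index, 1L))[chronological_index]
  tempo <- rep_len(spec$tempo_scale, max(chronological_index, 1L))[chronological_index]
  pitches <- pitches + transpo

  iois <- sample(spec$ioi_values, n_int, replace = TRUE, prob = spec$ioi_probs)
  onsets <- cumsum(c(0, iois)) * tempo
  durs <- c(iois, 1) * tempo
  truth <- tibble(onset = onsets, pitch = as.integer(pitches))

  notes <- tibble(onset = onsets, duration = durs,
                  pitch = as.integer(pitches),
                  is_grace = FALSE, slur_group = NA_integer_)
  if (spec$chord_prob > 0) {
    at <- which(stats::runif(length) < spec$chord_prob)
    if (length(at) > 0) {
      chords <- purrr::map(at, function(t) {
        k <- sample(1:2, 1L)
        below <- sample(3:10, k)
        tibble(onset = onsets[t], duration = durs[t],
               pitch = as.integer(pmax(pitches[t] - below, 0L)),
               is_grace = FALSE, slur_group = NA_integer_)
      }) |> purrr::list_rbind()
      notes <- dplyr::bind_rows(notes, chords)
    }
  }
  if (spec$grace_prob > 0) {
    at <- which(stats::runif(length) < spec$grace_prob)
    at <- at[at > 1L]  # need room before the note
    if (length(at) > 0) {
      graces <- tibble(
        onset = onsets[at] - 0.05 * tempo,
        duration = 0.05 * tempo,
        pitch = as.integer(pitches[at] + sample(c(-2L, -1L, 1L, 2L),
                                                length(at), replace = TRUE)),
        is_grace = TRUE, slur_group = NA_integer_
      )
      notes <- dplyr::bind_rows(notes, graces)
    }
  }
  notes <- dplyr::arrange(notes, .data$onset, dplyr::desc(.data$pitch))
  list(notes = notes, truth = truth, intervals = ints, iois = iois, tp = tp)
}

#' Generate a full synthetic corpus with ground truth
#'
#' Sample `pieces_per_musician` chronologically indexed pieces for each
#' musician spec. Per-piece RNG substreams are derived deterministically from
#' `seed` and the musician/piece indices, so the same seed always yields the
#' same corpus regardless of evaluation order.
#'
#' @param specs List of [musician_spec()]s with distinct ids.
#' @param pieces_per_musician Number of pieces per musician (default 7).
#' @param length Notes per piece.
#' @param seed Integer master seed.
#' @param fold Passed to [sample_piece()].
#' @return An object of class `improv_corpus`: a list with `notes` (all
#'   decorated notes with `piece_id`, `musician_id`, `chronological_index`),
#'   `truth` (the clean melody lines, same identifiers), `manifest`, `specs`,
#'   and `ground_truth` (per musician and index: the drifted generator matrix
#'   and its conditional entropy).
#' @export
make_corpus <- function(specs, pieces_per_musician = 7L, length = 500L,
                        seed = 1L, fold = c(24L, 108L)) {
  ids <- purrr::map_chr(specs, "musician_id")
  if (anyDuplicated(ids)) abort("Musician ids must be distinct.")
  rows <- tidyr::expand_grid(m = seq_along(specs), c = seq_len(pieces_per_musician))
  pieces <- purrr::pmap(rows, function(m, c) {
    piece_seed <- (seed + 7919L * m + 104729L * c) %% 2147483647L
    s <- specs[[m]]
    smp <- sample_piece(s, chronological_index = c, length = length,
                        seed = piece_seed, fold = fold)
    pid <- sprintf("%s_p%02d", s$musician_id, c)
    list(
      notes = dplyr::mutate(smp$notes, piece_id = pid, musician_id = s$musician_id,
                            chronological_index = c, .before = 1L),
      truth = dplyr::mutate(smp$truth, piece_id = pid, musician_id = s$musician_id,
                            chronological_index = c, .before = 1L),
      tp = smp$tp, musician_id = s$musician_id, chronological_index = c
    )
  })
  manifest <- dplyr::bind_cols(
    tibble(piece_id = purrr::map_chr(pieces, ~ .x$notes$piece_id[1])),
    rows |> dplyr::transmute(musician_id = ids[.data$m], chronological_index = .data$c)
  )
  ground_truth <- purrr::map(pieces, function(p) {
    list(musician_id = p$musician_id, chronological_index = p$chronological_index,
         tp = p$tp)
  })
  structure(
    list(notes = purrr::list_rbind(purrr::map(pieces, "notes")),
         truth = purrr::list_rbind(purrr::map(pieces, "truth")),
         manifest = manifest, specs = setNames(specs, ids),
         ground_truth = ground_truth, seed = seed),
    class = "improv_corpus"
  )
}

#' @export
print.improv_corpus <- function(x, ...) {
  cat(sprintf("<improv_corpus> %d musicians x %d pieces, %d notes total (seed %d)\n",
              length(x$specs), nrow(x$manifest) / length(x$specs),
              nrow(x$notes), x$seed))
  invisible(x)
}

#' Study-condition specs: shared shallow statistics, distinct deep signatures
#'
#' Three musician specs over a six-interval alphabet that share their
#' first-order (marginal) pitch statistics and their entire rhythm
#' distribution, but carry musician-specific third-order interval signatures
#' (visible to the pipeline from window order 4 upward). This mirrors a
#' corpus in which shallow statistics are a shared style and individuality
#' lives in deeper implicit structure: PCA on order-1 TP vectors should show
#' one dominant common component, while order-4 pitch TP vectors separate the
#' musicians and the (shared) rhythm streams never do.
#'
#' @param weight Signature mixing weight (default 0.6).
#' @param chord_prob,grace_prob Decoration rates shared by the three specs.
#' @return List of three [musician_spec()]s.
#' @export
hierarchy_specs <- function(weight = 0.6, chord_prob = 0.15, grace_prob = 0.05) {
  intervals <- c(-4L, -2L, -1L, 1L, 2L, 4L)
  base <- c(.28, .22, .18, .14, .10, .08)
  purrr::map2(c("evans_like", "hancock_like", "tyner_like"), c(0L, 2L, 4L),
    function(id, shift) {
      musician_spec(
        musician_id = id, intervals = intervals,
        tp = signature_tp(intervals, order = 3L, base_probs = base,
                          weight = weight, shift = shift),
        order = 3L, chord_prob = chord_prob, grace_prob = grace_prob,
        transposition = c(0L, 2L, -1L, 3L, 0L, -2L, 1L),
        tempo_scale = c(1, 1.25, 0.75, 1, 1.5, 1, 1.25)
      )
    })
}
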