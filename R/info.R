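#' Information content of a transition probability
#'
#' The surprisal of an observed continuation, `-log2(tp)` bits: 0 bits for a
#' certain transition, 1 bit for a coin flip, large for rare transitions.
#'
#' @param tp Probabilities in `(0, 1]`. Zero is an error: an observed pattern
#'   always has positive maximum-likelihood probability.
#' @return Information content in bits, `>= 0`.
#' @examples
#' information_content(c(1, 0.5, 0.25))  # 0 1 2
#' @export
information_content <- function(tp) {
  if (any(!is.finite(tp)) || any(tp <= 0) || any(tp > 1)) {
    abort("`tp` must lie in (0, 1]; information content is undefined at 0.")
  }
  -log2(tp)
}

#' Plug-in conditional entropy of a transition-probability table
#'
#' The average uncertainty of the continuation given the context,
#' `H = -sum_i sum_j P(a_i) P(b_j | a_i) log2 P(b_j | a_i)` bits, with the
#' context marginal `P(a_i)` taken as the empirical window frequency
#' (context count / total windows). Equivalently, H is the count-weighted mean
#' information content of the observed windows. `0 * log 0` is treated as 0.
#'
#' @param tp A TP tibble from [estimate_tp()]. Each piece-level table present
#'   (distinct piece identifier / `sequence_type` / `order` group) yields one
#'   entropy row. An empty table is an error.
#' @return A tibble with the identifier columns plus `sequence_type`, `order`,
#'   `n_windows`, `n_contexts` and `entropy` (bits).
#' @examples
#' m <- tibble::tibble(onset = 0:5, pitch = c(60, 62, 60, 62, 60, 63))
#' conditional_entropy(estimate_tp(encode_pitch(m, 1)))
#' @export
conditional_entropy <- function(tp) {
  stopifnot(is.data.frame(tp))
  req <- c("sequence_type", "order", "context", "count", "tp")
  if (!all(req %in% names(tp))) {
    abort("`tp` must come from estimate_tp() (missing columns).")
  }
  if (nrow(tp) == 0L) abort("Cannot compute entropy of an empty TP table.")
  ids <- id_cols(tp)
  tp |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(ids, "sequence_type", "order")))) |>
    dplyr::summarise(
      n_windows = sum(.data$count),
      n_contexts = dplyr::n_distinct(.data$context),
      entropy = sum(.data$count * -log2(.data$tp)) / sum(.data$count),
      .groups = "drop"
    )
}

#' Conditional-entropy profile of a corpus
#'
#' Convenience wrapper computing [conditional_entropy()] for every piece of a
#' corpus across sequence types and Markov orders: melody extraction,
#' encoding, TP estimation and entropy in one call.
#'
#' @param notes A corpus notes tibble (see [read_corpus()]) with a `piece_id`
#'   column.
#' @param types Sequence types to profile (default all four).
#' @param orders Markov orders to profile (default 1:6).
#' @return A tibble of entropy records: one row per piece, sequence type and
#'   order; combinations where a piece is too short for a single window are
#'   absent.
#' @export
entropy_profile <- function(notes,
                            types = c("pitch", "rhythm", "pitch_rhythm",
                                      "rhythm_pitch"),
                            orders = 1:6) {
  melody <- extract_melody(notes)
  tidyr::expand_grid(.type = types, .order = orders) |>
    purrr::pmap(function(.type, .order) {
      w <- encode_windows(melody, .type, .order)
      if (nrow(w) == 0L) return(NULL)
      conditional_entropy(estimate_tp(w))
    }) |>
    purrr::list_rbind()
}
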