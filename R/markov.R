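#' Maximum-likelihood transition probabilities from n-gram windows
#'
#' Tally the windows of one `(sequence_type, order)` stream and convert the
#' counts into conditional transition probabilities (TPs): for each context,
#' `tp = count / sum(count over that context's continuations)`. Estimation is
#' pure maximum likelihood -- no smoothing -- so only observed patterns appear
#' and per-context probabilities sum to one exactly. When the windows carry a
#' `piece_id` column, each piece gets its own table.
#'
#' @param windows A window tibble from [encode_windows()]. All rows must share
#'   one `sequence_type` and one `order`; mixing streams is an error.
#'
#' @return A TP tibble with the piece identifier columns plus
#'   `sequence_type`, `order`, `context`, `continuation`, `pattern`, `count`
#'   and `tp`, ordered lexicographically by pattern within piece. An empty
#'   window stream yields an empty table.
#' @examples
#' m <- tibble::tibble(onset = 0:3, pitch = c(60, 62, 62, 64))
#' estimate_tp(encode_pitch(m, 1))
#' @export
estimate_tp <- function(windows) {
  stopifnot(is.data.frame(windows))
  req <- c("sequence_type", "order", "context", "continuation", "pattern")
  if (!all(req %in% names(windows))) {
    abort("`windows` must come from encode_windows() (missing columns).")
  }
  if (dplyr::n_distinct(windows$sequence_type) > 1L ||
      dplyr::n_distinct(windows$order) > 1L) {
    abort("`windows` mixes sequence types or orders; estimate one stream at a time.")
  }
  ids <- id_cols(windows)
  windows |>
    dplyr::count(dplyr::across(dplyr::all_of(
      c(ids, "sequence_type", "order", "context", "continuation", "pattern")
    )), name = "count") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(ids, "context")))) |>
    dplyr::mutate(tp = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::across(dplyr::all_of(ids)),
                   lex_order_key(.data$pattern))
}

# helper giving arrange() a radix-ordered key
lex_order_key <- function(x) match(x, lex_sort(unique(x)))

#' Musician-level mean transition probabilities
#'
#' Average per-piece TPs over each musician's pieces on the union vocabulary:
#' a pattern absent from a piece contributes 0 for that piece. The result is a
#' mean of probabilities, not itself a probability table -- per-context sums
#' need not be 1 -- which is the quantity the downstream top-k selection and
#' chronological regressions operate on.
#'
#' @param tp A TP tibble from [estimate_tp()] covering one
#'   `(sequence_type, order)` stream, with `piece_id` and `musician_id`
#'   columns.
#' @return A tibble with `musician_id`, `sequence_type`, `order`, `context`,
#'   `continuation`, `pattern`, `mean_tp` and `n_pieces`.
#' @export
average_tp <- function(tp) {
  stopifnot(is.data.frame(tp),
            all(c("piece_id", "musician_id", "pattern", "tp") %in% names(tp)))
  if (nrow(tp) == 0L) abort("Cannot average an empty TP table.")
  check_single_stream(tp)
  n_pieces <- tp |>
    dplyr::distinct(.data$musician_id, .data$piece_id) |>
    dplyr::count(.data$musician_id, name = "n_pieces")
  tp |>
    dplyr::group_by(.data$musician_id, .data$sequence_type, .data$order,
                    .data$context, .data$continuation, .data$pattern) |>
    dplyr::summarise(sum_tp = sum(.data$tp), .groups = "drop") |>
    dplyr::left_join(n_pieces, by = "musician_id") |>
    dplyr::mutate(mean_tp = .data$sum_tp / .data$n_pieces, sum_tp = NULL) |>
    dplyr::arrange(.data$musician_id, lex_order_key(.data$pattern))
}

check_single_stream <- function(tp) {
  if (dplyr::n_distinct(tp$sequence_type) > 1L || dplyr::n_distinct(tp$order) > 1L) {
    abort("Expected a single (sequence_type, order) stream.")
  }
  invisible(tp)
}

#' Piece-by-pattern transition-probability matrix
#'
#' Align per-piece TP tables of one `(sequence_type, order)` stream onto the
#' sorted union vocabulary of `(context, continuation)` patterns. Patterns a
#' piece never produced are structural zeros. The column order is
#' lexicographic on the serialised pattern, so the matrix is identical across
#' runs and platforms. This wide matrix is the input to [tp_pca()].
#'
#' @param tp A TP tibble from [estimate_tp()] with at least two pieces.
#' @return A wide tibble: one row per piece with its identifier columns, then
#'   one numeric column per pattern.
#' @export
align_tp_matrix <- function(tp) {
  stopifnot(is.data.frame(tp), "piece_id" %in% names(tp))
  check_single_stream(tp)
  if (dplyr::n_distinct(tp$piece_id) < 2L) {
    abort("Need at least 2 pieces to align a TP matrix.")
  }
  ids <- id_cols(tp)
  vocab <- lex_sort(unique(tp$pattern))
  tp |>
    dplyr::mutate(pattern = factor(.data$pattern, levels = vocab)) |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(ids), names_from = "pattern",
                       values_from = "tp", values_fill = 0,
                       names_expand = TRUE) |>
    dplyr::arrange(.data$piece_id)
}

#' Highest-probability transitional patterns per musician
#'
#' Select each musician's `k` patterns with the highest mean TP -- the
#' transitions the musician is most likely to produce, used as the dependent
#' variables of the mixed ANOVA and as candidate predictors of the
#' chronological regressions. Ties are broken lexicographically on the
#' serialised pattern so the selection is deterministic.
#'
#' @param mean_tp Output of [average_tp()].
#' @param k Number of patterns to keep per musician (default 5).
#' @return `mean_tp` filtered to at most `k` rows per musician, with a `rank`
#'   column; mean TPs are non-increasing within musician. If a musician has
#'   fewer than `k` patterns all are returned with a warning.
#' @export
top_patterns <- function(mean_tp, k = 5L) {
  stopifnot(is.data.frame(mean_tp),
            all(c("musician_id", "pattern", "mean_tp") %in% names(mean_tp)))
  if (nrow(mean_tp) == 0L) abort("Empty mean TP table.")
  short <- mean_tp |>
    dplyr::count(.data$musician_id) |>
    dplyr::filter(.data$n < k)
  if (nrow(short) > 0L) {
    warn(paste0("Fewer than k = ", k, " patterns for musician(s): ",
                paste(short$musician_id, collapse = ", ")))
  }
  mean_tp |>
    dplyr::group_by(.data$musician_id) |>
    dplyr::arrange(dplyr::desc(.data$mean_tp), lex_order_key(.data$pattern),
                   .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Logit transform of transition probabilities
#'
#' `log(p / (1 - p))` after clamping `p` into `[eps, 1 - eps]`, the
#' normalising transform applied to TPs before ANOVA. Clamping keeps the
#' structural zeros (patterns absent from a piece) finite.
#'
#' @param p Probabilities in `[0, 1]`.
#' @param eps Clamping bound; default `1e-6`.
#' @return `log(p/(1-p))`, finite for all inputs in `[0, 1]`.
#' @examples
#' logit_tp(c(0, 0.5, 0.8))
#' @export
logit_tp <- function(p, eps = 1e-6) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), eps > 0, eps < 0.5)
  qlogis(pmin(pmax(p, eps), 1 - eps))
}
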