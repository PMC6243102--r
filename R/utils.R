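# Token serialisation shared by the encoders, TP tables and artifact writers.
# Rhythm ratios are rounded to 3 decimals *before* serialisation so that, e.g.,
# 1/3 and 2/6 collide into the same token ("0.333"), and printed without
# trailing zeros ("0.5", "1", "2", "0.333").

format_ratio_token <- function(x) {
  s <- sprintf("%.3f", round(x, 3))
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

format_pitch_token <- function(x) {
  format(as.integer(round(x)), trim = TRUE, scientific = FALSE)
}

# "[0, -1, -2]" -- the bracketed list style used throughout the output tables.
bracket <- function(...) {
  cols <- list(...)
  inner <- do.call(paste, c(cols, list(sep = ", ")))
  paste0("[", inner, "]")
}

# Locale-independent lexicographic order used for vocabulary alignment and
# deterministic tie-breaking.
lex_sort <- function(x) sort(x, method = "radix")
lex_order <- function(x) order(x, method = "radix")

# Columns of a window/TP tibble that identify the piece; carried through
# group-wise operations when present.
id_cols <- function(df) {
  intersect(c("piece_id", "musician_id", "chronological_index"), names(df))
}

`%||%` <- rlang::`%||%`
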