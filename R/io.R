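#' Read symbolic music into a notes table
#'
#' Read one piece from a Standard MIDI File or a note-list CSV into the tidy
#' notes representation used throughout the package: one row per note with
#' `onset` and `duration` in beats (quarter note = 1), `pitch` as a MIDI
#' semitone integer, an `is_grace` flag and an optional `slur_group` id
#' (notes sharing an id are one slurred unit). Onsets are expressed in beats,
#' never seconds, so tempo metadata cannot leak into the rhythm encodings.
#'
#' The CSV dialect is comma-separated UTF-8 with header
#' `onset,duration,pitch,is_grace,slur_group`; the last two columns may be
#' omitted and default to `FALSE` / none. CSV values are taken verbatim. MIDI
#' ticks are converted to beats with the file's ticks-per-quarter; channel 10
#' (percussion) is skipped and all remaining channels are merged, since the
#' skyline reduction treats the texture as one stream.
#'
#' @param path File path.
#' @param format `"csv"`, `"midi"`, or `"auto"` (by file extension).
#' @return A notes tibble sorted by (onset ascending, pitch descending).
#'   Identical `(onset, pitch)` duplicates are dropped with a warning.
#' @export
read_notes <- function(path, format = c("auto", "csv", "midi")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("mid", "midi", "smf")) "midi" else "csv"
  }
  notes <- switch(format, csv = read_notes_csv(path), midi = read_midi(path))
  validate_notes(notes, path)
}

read_notes_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  df <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_guess())),
    error = function(e) abort(paste0("Unparseable CSV at ", path, ": ",
                                     conditionMessage(e)))
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    abort(sprintf("Unparseable CSV at %s: line %d, %s", path,
                  probs$row[1] + 1L, probs$expected[1]))
  }
  need <- c("onset", "duration", "pitch")
  if (!all(need %in% names(df))) {
    abort(paste0("CSV ", path, " must have columns onset,duration,pitch",
                 " (optionally is_grace,slur_group)."))
  }
  tibble(
    onset = as.numeric(df$onset),
    duration = as.numeric(df$duration),
    pitch = as.integer(df$pitch),
    is_grace = if ("is_grace" %in% names(df)) {
      dplyr::coalesce(as.logical(df$is_grace), FALSE)
    } else rep(FALSE, nrow(df)),
    slur_group = if ("slur_group" %in% names(df)) {
      as.integer(df$slur_group)
    } else rep(NA_integer_, nrow(df))
  )
}

validate_notes <- function(notes, path = "<notes>") {
  bad <- which(!is.finite(notes$onset) | notes$onset < 0)
  if (length(bad)) abort(sprintf("%s: onset must be >= 0 (row %d).", path, bad[1]))
  bad <- which(!is.finite(notes$duration) | notes$duration <= 0)
  if (length(bad)) abort(sprintf("%s: duration must be > 0 (row %d).", path, bad[1]))
  bad <- which(is.na(notes$pitch) | notes$pitch < 0L | notes$pitch > 127L)
  if (length(bad)) abort(sprintf("%s: pitch must be a MIDI integer 0-127 (row %d).",
                                 path, bad[1]))
  dup <- duplicated(notes[, c("onset", "pitch")])
  if (any(dup)) {
    warn(sprintf("%s: %d duplicate (onset, pitch) note(s) dropped.",
                 path, sum(dup)))
    notes <- notes[!dup, ]
  }
  dplyr::arrange(notes, .data$onset, dplyr::desc(.data$pitch))
}

#' Write a notes table as a note-list CSV
#'
#' @param notes A notes tibble (identifier columns, if any, are dropped).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_notes_csv <- function(notes, path) {
  out <- notes |>
    dplyr::select("onset", "duration", "pitch", "is_grace", "slur_group") |>
    dplyr::mutate(dplyr::across(c("onset", "duration"),
                                ~ sprintf("%.17g", .x)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a corpus manifest
#'
#' A manifest is a JSON array of objects with fields `path`, `piece_id`,
#' `musician_id` and `chronological_index` (1 = the musician's earliest
#' piece). Every referenced file must exist (relative paths are resolved
#' against the manifest's directory), ids must be non-empty, and the
#' chronological index must be unique within each musician.
#'
#' @param path Manifest JSON path.
#' @return A manifest tibble with absolute `path` plus the id columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("No such manifest: ", path))
  df <- as_tibble(jsonlite::fromJSON(path))
  need <- c("path", "piece_id", "musician_id", "chronological_index")
  if (!all(need %in% names(df))) {
    abort(paste0("Manifest must have fields: ", paste(need, collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  df$path <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                    file.path(base, df$path))
  if (any(!nzchar(df$piece_id)) || any(!nzchar(df$musician_id))) {
    abort("Manifest ids must be non-empty.")
  }
  if (anyDuplicated(df$piece_id)) abort("Manifest piece_ids must be unique.")
  missing <- df$path[!file.exists(df$path)]
  if (length(missing)) {
    abort(paste0("Manifest references missing file(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- df |>
    dplyr::count(.data$musician_id, .data$chronological_index) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort("chronological_index must be unique within each musician.")
  }
  df$chronological_index <- as.integer(df$chronological_index)
  df
}

#' Read all pieces of a manifest into one corpus notes table
#'
#' @param manifest A manifest tibble from [read_manifest()], or a path to a
#'   manifest JSON.
#' @return A notes tibble with `piece_id`, `musician_id` and
#'   `chronological_index` columns prepended.
#' @export
read_corpus <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  purrr::pmap(manifest, function(path, piece_id, musician_id,
                                 chronological_index, ...) {
    read_notes(path) |>
      dplyr::mutate(piece_id = piece_id, musician_id = musician_id,
                    chronological_index = chronological_index, .before = 1L)
  }) |>
    purrr::list_rbind()
}

#' Write a synthetic corpus to disk as CSV pieces plus a manifest
#'
#' @param corpus An `improv_corpus` from [make_corpus()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"midi"` piece files.
#' @return The manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir, format = c("csv", "midi")) {
  format <- match.arg(format)
  stopifnot(inherits(corpus, "improv_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") "csv" else "mid"
  manifest <- corpus$manifest |>
    dplyr::mutate(path = paste0(.data$piece_id, ".", ext), .before = 1L)
  for (pid in manifest$piece_id) {
    notes <- dplyr::filter(corpus$notes, .data$piece_id == pid)
    f <- file.path(dir, paste0(pid, ".", ext))
    if (format == "csv") write_notes_csv(notes, f) else write_midi(notes, f)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

# full-precision TSV: doubles serialised with %.17g round-trip exactly
write_tsv_exact <- function(df, path) {
  dbl <- names(df)[vapply(df, is.double, logical(1))]
  out <- dplyr::mutate(df, dplyr::across(dplyr::all_of(dbl),
                                         ~ sprintf("%.17g", .x)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write / read a transition-probability table as TSV
#'
#' Fixed column order `piece_id, musician_id, order, sequence_type, context,
#' continuation, count, tp` (identifier columns absent from the table are
#' written empty). Probabilities are serialised at full precision, so
#' re-reading reproduces the table exactly.
#'
#' @param tp A TP tibble from [estimate_tp()].
#' @param path Output path.
#' @return `write_tp_table()` returns `path` invisibly; `read_tp_table()`
#'   returns the TP tibble.
#' @export
write_tp_table <- function(tp, path) {
  cols <- c("piece_id", "musician_id", "order", "sequence_type",
            "context", "continuation", "count", "tp")
  for (c in setdiff(cols, names(tp))) tp[[c]] <- NA_character_
  write_tsv_exact(dplyr::select(tp, dplyr::all_of(cols)), path)
}

#' @rdname write_tp_table
#' @export
read_tp_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    piece_id = readr::col_character(),
                    musician_id = readr::col_character(),
                    order = readr::col_integer(),
                    sequence_type = readr::col_character(),
                    context = readr::col_character(),
                    continuation = readr::col_character(),
                    count = readr::col_integer(),
                    tp = readr::col_double()
                  ))
}

#' Write per-piece records (entropies, chronologies, loadings) as TSV
#'
#' A thin full-precision TSV writer for the package's tabular outputs;
#' doubles survive a write/read round trip exactly.
#'
#' @param records Any tibble of per-piece records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  write_tsv_exact(records, path)
}
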