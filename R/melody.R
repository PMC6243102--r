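#' Skyline melody extraction
#'
#' Reduce a polyphonic notes table to the monophonic line of highest pitches:
#' the single pitch "playable at a given point in time". The reduction
#' (1) drops grace notes, (2) collapses each slurred group to its first note
#' (a slurred group is counted as one event), and (3) keeps, at each distinct
#' onset, only the highest pitch among the notes attacked at that onset.
#' A held lower note does not suppress a later higher attack, and a new lower
#' attack under a held higher note is kept as its own event: only attacks
#' compete. Durations and rests play no further role downstream -- the
#' encoders use onsets only.
#'
#' @param notes A notes tibble as returned by [read_notes()] or
#'   [read_corpus()]: columns `onset`, `duration`, `pitch`, `is_grace`,
#'   `slur_group`, plus optional piece identifier columns. Multiple pieces
#'   (a `piece_id` column) are reduced independently.
#'
#' @return A tibble with the piece identifier columns plus `onset` and
#'   `pitch`, ordered by onset, strictly one event per onset. A piece with no
#'   surviving notes yields zero rows.
#' @examples
#' notes <- tibble::tibble(
#'   onset = c(0, 0, 0), duration = 1, pitch = c(60, 64, 67),
#'   is_grace = FALSE, slur_group = NA_integer_
#' )
#' extract_melody(notes)  # the chord reduces to its top note, pitch 67
#' @export
extract_melody <- function(notes) {
  stopifnot(is.data.frame(notes), all(c("onset", "pitch") %in% names(notes)))
  if (!"is_grace" %in% names(notes)) notes$is_grace <- FALSE
  if (!"slur_group" %in% names(notes)) notes$slur_group <- NA_integer_
  ids <- id_cols(notes)
  grp <- if ("piece_id" %in% ids) "piece_id" else character()

  kept <- notes |>
    dplyr::filter(!dplyr::coalesce(.data$is_grace, FALSE)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)), .data$onset,
                   dplyr::desc(.data$pitch))
  if (nrow(kept) == 0L) {
    return(tibble(!!!setNames(rep(list(character(0)), length(ids)), ids),
                  onset = numeric(0), pitch = integer(0)))
  }

  # one counted event per slurred group: its first note (earliest onset,
  # highest pitch on a tie)
  slurred <- !is.na(kept$slur_group)
  if (any(slurred)) {
    first_of_slur <- kept[slurred, ] |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "slur_group")))) |>
      dplyr::slice_head(n = 1L) |>
      dplyr::ungroup()
    kept <- dplyr::bind_rows(kept[!slurred, ], first_of_slur)
  }

  kept |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(ids, "onset")))) |>
    dplyr::summarise(pitch = max(.data$pitch), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(grp)), .data$onset) |>
    dplyr::select(dplyr::all_of(ids), "onset", "pitch")
}
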