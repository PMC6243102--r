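#' Pipeline configuration
#'
#' Validated bundle of the analysis parameters: which Markov orders and
#' sequence types to run, the number of top patterns per musician (`k`), the
#' logit clamping bound, the stepwise thresholds and collinearity gates, and
#' the RNG seed recorded with the artifacts.
#'
#' @param orders Subset of 1:6 (default all).
#' @param types Subset of the four sequence types (default all).
#' @param k Top patterns per musician (default 5).
#' @param eps Logit clamping bound (default 1e-6).
#' @param p_enter,p_remove,vif_max,ci_max Stepwise thresholds and gates.
#' @param seed Integer seed recorded in the resolved config.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(orders = 1:6,
                            types = c("pitch", "rhythm", "pitch_rhythm",
                                      "rhythm_pitch"),
                            k = 5L, eps = 1e-6,
                            p_enter = 0.05, p_remove = 0.10,
                            vif_max = 2, ci_max = 20, seed = 1L) {
  orders <- as.integer(orders)
  stopifnot(length(orders) >= 1L, all(orders %in% 1:6),
            all(types %in% c("pitch", "rhythm", "pitch_rhythm", "rhythm_pitch")),
            k >= 1L, eps > 0, eps < 0.5,
            p_enter > 0, p_enter < 1, p_remove >= p_enter, p_remove < 1,
            vif_max > 1, ci_max > 1)
  structure(list(orders = sort(unique(orders)), types = unique(types),
                 k = as.integer(k), eps = eps, p_enter = p_enter,
                 p_remove = p_remove, vif_max = vif_max, ci_max = ci_max,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path JSON file with any subset of the [pipeline_config()] fields.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw_cfg <- jsonlite::fromJSON(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw_cfg), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, raw_cfg)
}

#' Run the full corpus analysis pipeline
#'
#' One deterministic pass from a corpus manifest to a directory of tabular
#' artifacts: skyline melodies (`melodies/`), per-piece TP tables (`tp/`),
#' conditional entropies (`entropy.tsv`), piece-level PCA loadings and
#' variance summaries (`pca/`), mixed ANOVAs on logit TPs of the musicians'
#' pooled top-k patterns (`anova/`), and the chronological stepwise
#' regressions on TPs and on entropies (`regression/`), plus `run.log` and
#' `config.resolved.json`. Re-running with the same inputs and config
#' reproduces every artifact byte for byte.
#'
#' PCA and ANOVA need at least 2 musicians and 3 pieces; with fewer the
#' stages are skipped with a logged warning rather than failing.
#'
#' @param manifest Path to a manifest JSON, a manifest tibble
#'   ([read_manifest()]), or an `improv_corpus` (analysed in memory).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; contents overwritten).
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (missing(out_dir)) abort("`out_dir` is required.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("melodies", "tp", "pca", "anova", "regression")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  log_lines <- character(0)
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", "pipeline", sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_msg("stage '%s' FAILED: %s", name, conditionMessage(e))
      writeLines(log_lines, file.path(out_dir, "run.log"))
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  notes <- stage("ingest", {
    if (inherits(manifest, "improv_corpus")) {
      manifest$notes
    } else {
      read_corpus(manifest)
    }
  })
  log_msg("ingest: %d notes, %d pieces, %d musicians", nrow(notes),
          dplyr::n_distinct(notes$piece_id), dplyr::n_distinct(notes$musician_id))

  melodies <- stage("melody", extract_melody(notes))
  log_msg("melody: %d events after skyline reduction", nrow(melodies))
  for (pid in unique(melodies$piece_id)) {
    write_records(
      melodies |> dplyr::filter(.data$piece_id == pid) |>
        dplyr::select("onset", "pitch"),
      file.path(out_dir, "melodies", paste0(pid, ".tsv"))
    )
  }

  n_musicians <- dplyr::n_distinct(notes$musician_id)
  multi <- n_musicians >= 2L && dplyr::n_distinct(notes$piece_id) >= 3L
  if (!multi) {
    log_msg("WARNING: fewer than 2 musicians or 3 pieces; PCA/ANOVA skipped")
  }

  entropy_all <- list()
  for (type in config$types) {
    for (ord in config$orders) {
      tag <- sprintf("%s_%d", type, ord)
      tp <- stage(paste0("tp/", tag), {
        w <- encode_windows(melodies, type, ord)
        if (nrow(w) == 0L) NULL else estimate_tp(w)
      })
      if (is.null(tp)) {
        log_msg("tp %s: no windows (pieces too short); skipped", tag)
        next
      }
      write_tp_table(tp, file.path(out_dir, "tp", paste0(tag, ".tsv")))
      log_msg("tp %s: %d patterns over %d pieces", tag, nrow(tp),
              dplyr::n_distinct(tp$piece_id))

      entropy_all[[tag]] <- conditional_entropy(tp)

      if (multi) {
        stage(paste0("pca/", tag), {
          mat <- align_tp_matrix(tp)
          p <- tryCatch(tp_pca(mat), error = function(e) {
            log_msg("pca %s skipped: %s", tag, conditionMessage(e)); NULL
          })
          if (!is.null(p)) {
            write_records(tidy(p), file.path(out_dir, "pca",
                                             paste0("loadings_", tag, ".tsv")))
            write_records(
              tibble(component = seq_along(p$eigenvalues),
                     eigenvalue = p$eigenvalues, var_pct = p$var_pct,
                     cum_pct = p$cum_pct, retained = p$retained),
              file.path(out_dir, "pca", paste0("variance_", tag, ".tsv"))
            )
          }
        })

        stage(paste0("anova/", tag), {
          av_data <- anova_data_topk(tp, k = config$k, eps = config$eps)
          a <- tryCatch(tp_anova(av_data), error = function(e) {
            log_msg("anova %s skipped: %s", tag, conditionMessage(e)); NULL
          })
          if (!is.null(a)) {
            write_records(tidy(a), file.path(out_dir, "anova",
                                             paste0("effects_", tag, ".tsv")))
            if (nrow(a$posthoc)) {
              write_records(a$posthoc, file.path(out_dir, "anova",
                                                 paste0("posthoc_", tag, ".tsv")))
            }
          }
        })
      }

      stage(paste0("regression/tp_", tag), {
        reg <- regress_tp_chronology(tp, k = config$k,
                                     p_enter = config$p_enter,
                                     p_remove = config$p_remove,
                                     vif_max = config$vif_max,
                                     ci_max = config$ci_max)
        if (nrow(reg)) {
          write_records(reg, file.path(out_dir, "regression",
                                       paste0("tp_", tag, ".tsv")))
        }
      })
    }
  }

  entropy_tbl <- purrr::list_rbind(entropy_all)
  if (!"chronological_index" %in% names(entropy_tbl)) {
    chron <- notes |>
      dplyr::distinct(.data$piece_id, .data$musician_id, .data$chronological_index)
    entropy_tbl <- dplyr::left_join(entropy_tbl, chron,
                                    by = c("piece_id", "musician_id"))
  }
  entropy_tbl <- dplyr::relocate(entropy_tbl, "chronological_index",
                                 .after = "musician_id")
  write_records(entropy_tbl, file.path(out_dir, "entropy.tsv"))
  log_msg("entropy: %d records", nrow(entropy_tbl))

  stage("regression/entropy", {
    reg <- regress_entropy_chronology(entropy_tbl,
                                      p_enter = config$p_enter,
                                      p_remove = config$p_remove,
                                      vif_max = config$vif_max,
                                      ci_max = config$ci_max)
    if (nrow(reg)) {
      write_records(reg, file.path(out_dir, "regression", "entropy.tsv"))
    }
  })

  cfg <- unclass(config)
  jsonlite::write_json(cfg, file.path(out_dir, "config.resolved.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("done")
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Balanced ANOVA input from a TP table
#'
#' Build the dependent-variable set of the mixed ANOVA: the union of all
#' musicians' top-`k` mean-TP patterns (deduplicated), with every piece
#' contributing a logit-transformed TP for every pattern -- a pattern absent
#' from a piece enters as `logit_tp(0, eps)` -- so the within-subject factor
#' is fully crossed.
#'
#' @param tp A TP tibble from [estimate_tp()] with piece and musician ids.
#' @param k Top patterns per musician (default 5).
#' @param eps Logit clamping bound.
#' @return A long tibble with `piece_id`, `musician_id`, `pattern`, `tp` and
#'   `logit_tp`, suitable for [tp_anova()].
#' @export
anova_data_topk <- function(tp, k = 5L, eps = 1e-6) {
  top <- suppressWarnings(top_patterns(average_tp(tp), k = k))
  pats <- unique(top$pattern)
  pieces <- dplyr::distinct(tp, .data$piece_id, .data$musician_id,
                            dplyr::across(dplyr::any_of("chronological_index")))
  tidyr::expand_grid(piece_id = pieces$piece_id, pattern = pats) |>
    dplyr::left_join(pieces, by = "piece_id") |>
    dplyr::left_join(dplyr::select(tp, "piece_id", "pattern", "tp"),
                     by = c("piece_id", "pattern")) |>
    dplyr::mutate(tp = dplyr::coalesce(.data$tp, 0),
                  logit_tp = logit_tp(.data$tp, eps = eps))
}

# Per-musician stepwise regression of chronological index on top-k pattern TPs.
regress_tp_chronology <- function(tp, k = 5L, ...) {
  top <- suppressWarnings(top_patterns(average_tp(tp), k = k))
  purrr::map(unique(tp$musician_id), function(mus) {
    pats <- top$pattern[top$musician_id == mus]
    sub <- tp |> dplyr::filter(.data$musician_id == mus)
    if (!"chronological_index" %in% names(sub)) return(NULL)
    pieces <- dplyr::distinct(sub, .data$piece_id, .data$chronological_index)
    wide <- sub |>
      dplyr::filter(.data$pattern %in% pats) |>
      tidyr::pivot_wider(id_cols = "piece_id",
                         names_from = "pattern", values_from = "tp",
                         values_fill = 0) |>
      dplyr::right_join(pieces, by = "piece_id")
    for (p in setdiff(pats, names(wide))) wide[[p]] <- 0
    wide <- dplyr::mutate(wide, dplyr::across(dplyr::all_of(pats),
                                              ~ dplyr::coalesce(.x, 0)))
    if (nrow(wide) < 3L) return(NULL)
    if (!isTRUE(all.equal(sort(wide$chronological_index),
                          as.numeric(seq_len(nrow(wide)))))) {
      return(NULL)
    }
    fitted <- stepwise_tp(wide, "chronological_index", pats, ...)
    if (nrow(fitted$selected) == 0L) return(NULL)
    dplyr::bind_cols(tibble(musician_id = mus), tidy(fitted),
                     glance(fitted)[, c("adj_r_squared", "statistic", "p.value")] |>
                       dplyr::rename(model_F = "statistic", model_p = "p.value"))
  }) |> purrr::list_rbind()
}

# Per-musician, per-sequence-type stepwise regression of chronological index
# on the conditional entropies across the available orders.
regress_entropy_chronology <- function(entropy_tbl, ...) {
  combos <- dplyr::distinct(entropy_tbl, .data$musician_id, .data$sequence_type)
  purrr::pmap(combos, function(musician_id, sequence_type) {
    sub <- entropy_tbl |>
      dplyr::filter(.data$musician_id == !!musician_id,
                    .data$sequence_type == !!sequence_type)
    wide <- sub |>
      dplyr::mutate(ord = paste0("H_order_", .data$order)) |>
      tidyr::pivot_wider(id_cols = c("piece_id", "chronological_index"),
                         names_from = "ord", values_from = "entropy")
    preds <- grep("^H_order_", names(wide), value = TRUE)
    wide <- wide[stats::complete.cases(wide), ]
    if (nrow(wide) < 3L || length(preds) == 0L) return(NULL)
    if (!isTRUE(all.equal(sort(wide$chronological_index),
                          as.numeric(seq_len(nrow(wide)))))) {
      return(NULL)  # some pieces too short at this type: no full chronology
    }
    fitted <- stepwise_tp(wide, "chronological_index", preds, ...)
    if (nrow(fitted$selected) == 0L) return(NULL)
    dplyr::bind_cols(tibble(musician_id = musician_id,
                            sequence_type = sequence_type),
                     tidy(fitted))
  }) |> purrr::list_rbind()
}
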