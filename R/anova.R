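#' Mixed-design ANOVA on logit transition probabilities
#'
#' A split-plot ANOVA with musicians as the between-subjects factor, pieces
#' as subjects, and transitional pattern as the within-subjects factor; the
#' dependent variable is the logit-transformed TP of each pattern in each
#' piece (structural zeros enter as `logit_tp(0)`). Sphericity of the
#' within-subject covariance is tested with Mauchly's test; when violated
#' (p < 0.05) the within-effect degrees of freedom are Greenhouse-Geisser
#' corrected. Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`. Significant effects are followed by
#' Bonferroni-corrected pairwise post-hoc comparisons: musicians overall (on
#' per-piece means), musicians within each pattern, and patterns within each
#' musician (paired across pieces).
#'
#' @param data Long tibble with one row per piece x pattern.
#' @param value,subject,between,within Column names (strings) of the
#'   dependent variable, subject id, between factor and within factor.
#'   Defaults `"logit_tp"`, `"piece_id"`, `"musician_id"`, `"pattern"`.
#' @param posthoc Run the pairwise comparisons (default TRUE).
#' @return An object of class `tp_anova`: `effects` (F, df, corrected df, p,
#'   partial eta squared per effect), `mauchly`, `posthoc`, and the design
#'   sizes. `tidy()` returns the effects table, `glance()` a one-row summary,
#'   `autoplot()` the musician-by-pattern interaction means.
#' @export
tp_anova <- function(data, value = "logit_tp", subject = "piece_id",
                     between = "musician_id", within = "pattern",
                     posthoc = TRUE) {
  stopifnot(is.data.frame(data),
            all(c(value, subject, between, within) %in% names(data)))
  d <- tibble(
    y = as.numeric(data[[value]]),
    subject = as.character(data[[subject]]),
    between = as.character(data[[between]]),
    within = as.character(data[[within]])
  )
  if (any(!is.finite(d$y))) abort("Non-finite values in the dependent variable.")
  cells <- d |> dplyr::count(.data$subject, .data$within)
  full <- tidyr::expand_grid(subject = unique(d$subject),
                             within = unique(d$within))
  missing <- dplyr::anti_join(full, cells, by = c("subject", "within"))
  if (any(cells$n > 1L) || nrow(missing) > 0L) {
    msg <- if (nrow(missing) > 0L) {
      paste0("Unbalanced design; missing cells: ",
             paste(utils::head(paste0(missing$subject, ":", missing$within), 5L),
                   collapse = ", "))
    } else "Unbalanced design: duplicated subject x within cells."
    abort(msg)
  }

  wide <- d |>
    tidyr::pivot_wider(id_cols = c("subject", "between"),
                       names_from = "within", values_from = "y")
  lev_w <- lex_sort(unique(d$within))
  Y <- as.matrix(wide[, lev_w, drop = FALSE])
  grp <- factor(wide$between)
  n_subj <- nrow(Y); k <- length(lev_w)

  if (max(Y) - min(Y) < 1e-12) {
    # degenerate: no variance anywhere; all effects null by convention
    effects <- tibble(
      effect = c(between, within, paste0(between, ":", within)),
      df1 = c(nlevels(grp) - 1, k - 1, (nlevels(grp) - 1) * (k - 1)),
      df2 = c(n_subj - nlevels(grp), rep((n_subj - nlevels(grp)) * (k - 1), 2)),
      statistic = 0, p.value = 1, partial_eta_sq = 0,
      gg_applied = FALSE, gg_epsilon = NA_real_,
      df1_corrected = NA_real_, df2_corrected = NA_real_
    )
    res <- list(effects = effects, mauchly = tibble(), posthoc = tibble(),
                n_subjects = n_subj, n_within = k, levels_between = levels(grp))
    return(structure(res, class = "tp_anova"))
  }

  idata <- data.frame(W = factor(lev_w, levels = lev_w))
  # sum-to-zero contrasts so type-3 tests are the classical balanced-design ones
  mlm <- lm(Y ~ grp, contrasts = list(grp = "contr.sum"))
  av <- car::Anova(mlm, idata = idata, idesign = ~W, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  rn <- rownames(ut)
  pick <- function(nm) which(rn == nm)
  eff_rows <- c(grp = pick("grp"), W = pick("W"), `grp:W` = pick("grp:W"))
  adj <- s$pval.adjustments
  sph <- s$sphericity.tests

  effects <- purrr::imap(eff_rows, function(i, nm) {
    ss <- ut[i, "Sum Sq"]; sse <- ut[i, "Error SS"]
    df1 <- ut[i, "num Df"]; df2 <- ut[i, "den Df"]
    is_within <- nm %in% c("W", "grp:W")
    mau_p <- if (is_within && !is.null(sph) && nm %in% rownames(sph)) {
      sph[nm, "p-value"]
    } else NA_real_
    gg <- is_within && !is.na(mau_p) && mau_p < 0.05
    eps <- if (is_within && !is.null(adj) && nm %in% rownames(adj)) {
      adj[nm, "GG eps"]
    } else NA_real_
    p <- if (gg) adj[nm, "Pr(>F[GG])"] else ut[i, "Pr(>F)"]
    tibble(
      effect = c(grp = between, W = within,
                 `grp:W` = paste0(between, ":", within))[[nm]],
      df1 = df1, df2 = df2,
      statistic = ut[i, "F value"],
      p.value = p,
      partial_eta_sq = ss / (ss + sse),
      gg_applied = gg,
      gg_epsilon = eps,
      df1_corrected = if (gg) eps * df1 else df1,
      df2_corrected = if (gg) eps * df2 else df2
    )
  }) |> purrr::list_rbind()

  mauchly <- if (!is.null(sph)) {
    tibble(effect = rownames(sph), statistic = sph[, "Test statistic"],
           p.value = sph[, "p-value"])
  } else tibble()

  ph <- if (posthoc) {
    anova_posthoc(d, between = between, within = within)
  } else tibble()

  cellmeans <- d |>
    dplyr::group_by(.data$between, .data$within) |>
    dplyr::summarise(mean = mean(.data$y),
                     se = sd(.data$y) / sqrt(dplyr::n()), .groups = "drop")

  structure(
    list(effects = effects, mauchly = mauchly, posthoc = ph,
         cellmeans = cellmeans,
         n_subjects = n_subj, n_within = k, levels_between = levels(grp)),
    class = "tp_anova"
  )
}

# Bonferroni-corrected pairwise comparisons; each `family` is corrected as a
# whole across all its pairs.
anova_posthoc <- function(d, between, within) {
  out <- list()
  # musicians overall, on per-subject means
  sm <- d |>
    dplyr::group_by(.data$subject, .data$between) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  groups <- sort(unique(sm$between))
  if (length(groups) >= 2L) {
    prs <- utils::combn(groups, 2L, simplify = FALSE)
    out$between <- purrr::map(prs, function(pr) {
      a <- sm$y[sm$between == pr[1]]; b <- sm$y[sm$between == pr[2]]
      tt <- stats::t.test(a, b, var.equal = TRUE)
      tibble(family = "between", level = NA_character_,
             group1 = pr[1], group2 = pr[2],
             estimate = mean(a) - mean(b), statistic = unname(tt$statistic),
             p.value = tt$p.value)
    }) |> purrr::list_rbind()
  }
  # musicians within each pattern
  if (length(groups) >= 2L) {
    out$interaction <- purrr::map(sort(unique(d$within)), function(w) {
      dd <- d[d$within == w, ]
      purrr::map(utils::combn(groups, 2L, simplify = FALSE), function(pr) {
        a <- dd$y[dd$between == pr[1]]; b <- dd$y[dd$between == pr[2]]
        tt <- stats::t.test(a, b, var.equal = TRUE)
        tibble(family = "between_within_pattern", level = w,
               group1 = pr[1], group2 = pr[2],
               estimate = mean(a) - mean(b), statistic = unname(tt$statistic),
               p.value = tt$p.value)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }
  # patterns within each musician (paired across that musician's pieces)
  pats <- sort(unique(d$within))
  if (length(pats) >= 2L) {
    out$within <- purrr::map(groups, function(g) {
      dd <- d[d$between == g, ] |>
        tidyr::pivot_wider(id_cols = "subject", names_from = "within",
                           values_from = "y")
      purrr::map(utils::combn(pats, 2L, simplify = FALSE), function(pr) {
        a <- dd[[pr[1]]]; b <- dd[[pr[2]]]
        if (sd(a - b) < 1e-12) return(NULL)
        tt <- stats::t.test(a, b, paired = TRUE)
        tibble(family = "within_musician", level = g,
               group1 = pr[1], group2 = pr[2],
               estimate = mean(a - b), statistic = unname(tt$statistic),
               p.value = tt$p.value)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }
  res <- purrr::list_rbind(purrr::compact(out))
  if (nrow(res) == 0L) return(res)
  res |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p.adjusted = pmin(.data$p.value * dplyr::n(), 1)) |>
    dplyr::ungroup()
}

#' @export
print.tp_anova <- function(x, ...) {
  cat(sprintf("<tp_anova> %d subjects, %d within levels, between groups: %s\n",
              x$n_subjects, x$n_within, paste(x$levels_between, collapse = ", ")))
  print(as.data.frame(x$effects[, c("effect", "df1_corrected", "df2_corrected",
                                    "statistic", "p.value", "partial_eta_sq")]),
        digits = 4)
  invisible(x)
}

#' @rdname tp_anova
#' @param x,object A `tp_anova` object.
#' @param ... Unused.
#' @export
tidy.tp_anova <- function(x, ...) x$effects

#' @rdname tp_anova
#' @export
glance.tp_anova <- function(x, ...) {
  i <- which(grepl(":", x$effects$effect))
  tibble(
    n_subjects = x$n_subjects, n_within = x$n_within,
    interaction_F = x$effects$statistic[i],
    interaction_p = x$effects$p.value[i],
    interaction_partial_eta_sq = x$effects$partial_eta_sq[i],
    n_posthoc_significant = if (nrow(x$posthoc)) {
      sum(x$posthoc$p.adjusted < 0.05)
    } else 0L
  )
}

#' @rdname tp_anova
#' @export
autoplot.tp_anova <- function(object, ...) {
  d <- object$cellmeans
  if (is.null(d) || nrow(d) == 0L) {
    abort("No cell means stored (degenerate fit).")
  }
  ggplot2::ggplot(d, ggplot2::aes(.data$within, .data$mean,
                                  colour = .data$between,
                                  group = .data$between)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::labs(x = "Pattern", y = "Mean logit TP", colour = "Musician") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
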