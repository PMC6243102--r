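# Independent brute-force oracles. These deliberately re-derive every quantity
# with plain loops and base R, sharing no code path with the package internals
# beyond the token-formatting conventions they restate inline.

orc_ratio <- function(x) {
  s <- sprintf("%.3f", round(x, 3))
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}
orc_pitch <- function(x) as.character(as.integer(round(x)))
orc_br <- function(v) paste0("[", paste(v, collapse = ", "), "]")

# enumerate every window of a melody by explicit indexing
oracle_windows <- function(onset, pitch, type, n) {
  rows <- list()
  add <- function(ctx, cont, pat) {
    rows[[length(rows) + 1L]] <<- data.frame(context = ctx, continuation = cont,
                                             pattern = pat)
  }
  L <- length(pitch)
  d <- diff(onset)
  if (type == "pitch") {
    if (L >= n + 1) for (i in 1:(L - n)) {
      w <- pitch[i:(i + n)] - pitch[i]
      add(orc_br(orc_pitch(w[1:n])), orc_pitch(w[n + 1]), orc_br(orc_pitch(w)))
    }
  } else if (type == "rhythm") {
    if (length(d) >= n + 1) for (i in 1:(length(d) - n)) {
      w <- d[i:(i + n)] / d[i]
      add(orc_br(orc_ratio(w[1:n])), orc_ratio(w[n + 1]), orc_br(orc_ratio(w)))
    }
  } else if (type == "pitch_rhythm") {
    if (L >= n + 1) for (i in 1:(L - n)) {
      p <- pitch[i:(i + n)] - pitch[i]
      r <- if (n == 1) d[i] else d[i:(i + n - 1)] / d[i]
      ctx <- paste(orc_br(orc_pitch(p[1:n])), "with",
                   if (n == 1) "[]" else orc_br(orc_ratio(r[1:(n - 1)])))
      add(ctx, paste(orc_pitch(p[n + 1]), "with", orc_ratio(r[n])),
          paste(orc_br(orc_pitch(p)), "with", orc_br(orc_ratio(r))))
    }
  } else if (type == "rhythm_pitch") {
    if (length(d) >= n + 1) for (i in 1:(length(d) - n)) {
      r <- d[i:(i + n)] / d[i]
      p <- pitch[i:(i + n + 1)] - pitch[i]
      add(paste(orc_br(orc_ratio(r[1:n])), "with", orc_br(orc_pitch(p[1:(n + 1)]))),
          paste(orc_ratio(r[n + 1]), "with", orc_pitch(p[n + 2])),
          paste(orc_br(orc_ratio(r)), "with", orc_br(orc_pitch(p))))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(context = character(), continuation = character(),
                      pattern = character()))
  }
  do.call(rbind, rows)
}

# dictionary-count conditional probabilities
oracle_tp <- function(context, continuation) {
  key <- paste(context, continuation, sep = "\t")
  cnt <- table(key)
  parts <- strsplit(names(cnt), "\t", fixed = TRUE)
  ctx <- vapply(parts, `[[`, "", 1L)
  cont <- vapply(parts, `[[`, "", 2L)
  ctx_tot <- tapply(as.vector(cnt), ctx, sum)
  data.frame(context = ctx, continuation = cont, count = as.vector(cnt),
             tp = as.vector(cnt) / as.vector(ctx_tot[ctx]),
             stringsAsFactors = FALSE)
}

# explicit double sum of Eq.-style conditional entropy over a count table
oracle_entropy <- function(tp_tbl) {
  total <- sum(tp_tbl$count)
  H <- 0
  for (a in unique(tp_tbl$context)) {
    sub <- tp_tbl[tp_tbl$context == a, ]
    p_a <- sum(sub$count) / total
    inner <- 0
    for (j in seq_len(nrow(sub))) {
      p <- sub$tp[j]
      if (p > 0) inner <- inner - p * log2(p)
    }
    H <- H + p_a * inner
  }
  H
}

# per-onset scan skyline oracle: among notes attacked at each onset (graces
# dropped, slur groups collapsed to their first note), keep the max pitch
oracle_skyline <- function(notes) {
  notes <- notes[!notes$is_grace, ]
  if (any(!is.na(notes$slur_group))) {
    keep <- rep(TRUE, nrow(notes))
    for (g in unique(stats::na.omit(notes$slur_group))) {
      idx <- which(!is.na(notes$slur_group) & notes$slur_group == g)
      first <- idx[order(notes$onset[idx], -notes$pitch[idx])][1]
      keep[setdiff(idx, first)] <- FALSE
    }
    notes <- notes[keep, ]
  }
  ons <- sort(unique(notes$onset))
  data.frame(
    onset = ons,
    pitch = vapply(ons, function(o) max(notes$pitch[notes$onset == o]), numeric(1))
  )
}

# hand sums of squares for the balanced split-plot design
oracle_splitplot_ss <- function(y, group, subject, within) {
  gm <- mean(y)
  a <- length(unique(group)); k <- length(unique(within))
  subj <- unique(subject)
  s <- length(subj) / a
  subj_mean <- tapply(y, subject, mean)
  subj_grp <- tapply(group, subject, function(g) g[1])
  grp_mean <- tapply(y, group, mean)
  w_mean <- tapply(y, within, mean)
  cell_mean <- tapply(y, list(group, within), mean)
  ss_between <- k * s * sum((grp_mean - gm)^2)
  ss_subj <- k * sum((subj_mean - grp_mean[subj_grp[names(subj_mean)]])^2)
  ss_within <- a * s * sum((w_mean - gm)^2)
  dev <- sweep(sweep(cell_mean, 1L, grp_mean[rownames(cell_mean)]),
               2L, w_mean[colnames(cell_mean)]) + gm
  ss_inter <- s * sum(dev^2)
  # residual: y - cell - subj + group
  resid <- y - cell_mean[cbind(group, within)] - subj_mean[subject] +
    grp_mean[group]
  list(between = ss_between, subj_error = ss_subj,
       within = ss_within, interaction = ss_inter,
       within_error = sum(resid^2))
}

# random test melodies: strictly increasing onsets on common subdivisions,
# bounded random-walk pitches
rand_melody <- function(L, ioi_pool = c(0.25, 1/3, 0.5, 2/3, 1, 1.5, 2)) {
  iois <- sample(ioi_pool, L - 1, replace = TRUE)
  steps <- sample(c(-5:-1, 0:7), L - 1, replace = TRUE)
  tibble::tibble(
    onset = cumsum(c(0, iois)),
    pitch = as.integer(60 + cumsum(c(0, steps)) %% 24)
  )
}

expect_same_windows <- function(got, want) {
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$context, want$context)
  expect_equal(got$continuation, want$continuation)
  expect_equal(got$pattern, want$pattern)
}
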