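win_tbl <- function(context, continuation) {
  tibble::tibble(sequence_type = "pitch", order = 1L, context = context,
                 continuation = continuation,
                 pattern = paste0(sub("\\]$", "", context), ", ", continuation, "]"))
}

test_that("TPs are per-context relative frequencies", {
  tp <- estimate_tp(win_tbl(rep("[0]", 3), c("1", "1", "2")))
  expect_equal(tp$tp[tp$continuation == "1"], 2 / 3)
  expect_equal(tp$tp[tp$continuation == "2"], 1 / 3)
  expect_equal(tp$count, c(2L, 1L))

  single <- estimate_tp(win_tbl("[0]", "5"))
  expect_equal(single$tp, 1)
})

test_that("estimate_tp equals the dictionary-count oracle on random streams", {
  set.seed(11)
  for (rep in 1:10) {
    m <- rand_melody(sample(50:300, 1))
    n <- sample(1:4, 1)
    type <- sample(c("pitch", "rhythm", "pitch_rhythm", "rhythm_pitch"), 1)
    w <- encode_windows(m, type, n)
    got <- estimate_tp(w)
    want <- oracle_tp(w$context, w$continuation)
    j <- merge(got, want, by = c("context", "continuation"))
    expect_equal(nrow(j), nrow(got))
    expect_equal(nrow(j), nrow(want))
    expect_equal(j$count.x, j$count.y)
    expect_equal(j$tp.x, j$tp.y)
    # per-context normalisation
    sums <- tapply(got$tp, got$context, sum)
    expect_true(all(abs(sums - 1) < 1e-9))
  }
})

test_that("mixing streams or empty inputs are handled per contract", {
  w1 <- win_tbl("[0]", "1")
  w2 <- dplyr::mutate(w1, order = 2L)
  expect_error(estimate_tp(dplyr::bind_rows(w1, w2)), "mixes")
  empty <- win_tbl(character(), character())
  expect_equal(nrow(estimate_tp(empty)), 0)
})

test_that("adding an observation of a pattern never decreases its TP", {
  set.seed(12)
  ctx <- sample(c("[0]", "[1]", "[2]"), 60, replace = TRUE)
  cont <- sample(c("1", "2", "3"), 60, replace = TRUE)
  w <- win_tbl(ctx, cont)
  tp1 <- estimate_tp(w)
  w2 <- dplyr::bind_rows(w, win_tbl("[0]", "2"))
  tp2 <- estimate_tp(w2)
  v1 <- tp1$tp[tp1$context == "[0]" & tp1$continuation == "2"]
  v2 <- tp2$tp[tp2$context == "[0]" & tp2$continuation == "2"]
  expect_gte(v2, if (length(v1)) v1 else 0)
})

test_that("musician means treat absent patterns as zero", {
  tp <- dplyr::bind_rows(
    dplyr::mutate(estimate_tp(win_tbl("[0]", "1")), piece_id = "p1",
                  musician_id = "m"),
    dplyr::mutate(estimate_tp(win_tbl("[0]", "2")), piece_id = "p2",
                  musician_id = "m")
  )
  avg <- average_tp(tp)
  expect_equal(sort(avg$mean_tp), c(0.5, 0.5))  # tp 1 in one piece, 0 in other
  expect_equal(avg$n_pieces, c(2L, 2L))

  # identical tables average to themselves
  tp_same <- dplyr::bind_rows(
    dplyr::mutate(estimate_tp(win_tbl(rep("[0]", 2), c("1", "2"))),
                  piece_id = "p1", musician_id = "m"),
    dplyr::mutate(estimate_tp(win_tbl(rep("[0]", 2), c("1", "2"))),
                  piece_id = "p2", musician_id = "m")
  )
  expect_equal(sort(average_tp(tp_same)$mean_tp), c(0.5, 0.5))
})

test_that("musician means equal a brute-force mean over the union vocabulary", {
  set.seed(13)
  tabs <- lapply(1:7, function(i) {
    m <- rand_melody(60)
    dplyr::mutate(estimate_tp(encode_pitch(m, 2)),
                  piece_id = paste0("p", i), musician_id = "m")
  })
  tp <- dplyr::bind_rows(tabs)
  avg <- average_tp(tp)
  vocab <- unique(tp$pattern)
  want <- vapply(vocab, function(pat) {
    vals <- vapply(tabs, function(t) {
      v <- t$tp[t$pattern == pat]
      if (length(v)) v else 0
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(avg$mean_tp[match(vocab, avg$pattern)], unname(want))
})

test_that("TP matrices align pieces on the sorted union vocabulary", {
  tp <- dplyr::bind_rows(
    dplyr::mutate(estimate_tp(win_tbl("[0]", "1")), piece_id = "p1",
                  musician_id = "m"),
    dplyr::mutate(estimate_tp(win_tbl("[1]", "2")), piece_id = "p2",
                  musician_id = "m")
  )
  mat <- align_tp_matrix(tp)
  patt_cols <- setdiff(names(mat), c("piece_id", "musician_id"))
  expect_equal(patt_cols, sort(patt_cols, method = "radix"))
  X <- as.matrix(mat[patt_cols])
  expect_equal(unname(X), matrix(c(1, 0, 0, 1), 2))  # disjoint patterns
  # column sums equal pattern-wise sums
  set.seed(14)
  tp_rand <- dplyr::bind_rows(lapply(1:5, function(i) {
    dplyr::mutate(estimate_tp(encode_pitch(rand_melody(40), 1)),
                  piece_id = paste0("p", i), musician_id = "m")
  }))
  mat2 <- align_tp_matrix(tp_rand)
  cols <- setdiff(names(mat2), c("piece_id", "musician_id"))
  want <- tapply(tp_rand$tp, tp_rand$pattern, sum)
  expect_equal(unname(colSums(mat2[cols])[names(want)]),
               as.vector(want))
})

test_that("top-k selection ranks by mean TP with lexicographic tie-break", {
  avg <- tibble::tibble(
    musician_id = "m", sequence_type = "pitch", order = 1L,
    context = "[0]", continuation = c("1", "2", "3"),
    pattern = c("[0, 1]", "[0, 2]", "[0, 3]"),
    mean_tp = c(0.5, 0.3, 0.1), n_pieces = 7L
  )
  top <- top_patterns(avg, k = 2)
  expect_equal(top$pattern, c("[0, 1]", "[0, 2]"))
  expect_equal(top$rank, 1:2)

  ties <- dplyr::mutate(avg, mean_tp = 0.2)
  expect_equal(top_patterns(ties, k = 2)$pattern, c("[0, 1]", "[0, 2]"))

  expect_warning(top_patterns(avg, k = 5), "Fewer than")
})

test_that("logit transform is symmetric, closed-form, and clamped", {
  expect_equal(logit_tp(0.5), 0)
  expect_equal(logit_tp(0.8), log(4))
  expect_equal(logit_tp(0), log(1e-6 / (1 - 1e-6)))  # finite, large negative
  expect_equal(logit_tp(1), -logit_tp(0))
  expect_true(is.finite(logit_tp(0, eps = 1e-9)))
})
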