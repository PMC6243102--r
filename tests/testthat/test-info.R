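test_that("information content is -log2(tp) with the documented edge cases", {
  expect_equal(information_content(1), 0)
  expect_equal(information_content(0.5), 1)
  expect_equal(information_content(0.25), 2)
  expect_error(information_content(0), "undefined")
  expect_error(information_content(1.5))
})

test_that("entropy of hand-built tables matches closed forms", {
  det <- tibble::tibble(sequence_type = "pitch", order = 1L,
                        context = c("[0]", "[1]"), continuation = "1",
                        count = c(3L, 5L), tp = 1)
  expect_equal(conditional_entropy(det)$entropy, 0)

  unif4 <- tibble::tibble(sequence_type = "pitch", order = 1L, context = "[0]",
                          continuation = as.character(1:4), count = 2L, tp = 0.25)
  expect_equal(conditional_entropy(unif4)$entropy, 2)

  # one deterministic context, one uniform-over-2 context, equal mass
  half <- tibble::tibble(sequence_type = "pitch", order = 1L,
                         context = c("[a]", "[b]", "[b]"),
                         continuation = c("x", "y", "z"),
                         count = c(4L, 2L, 2L), tp = c(1, 0.5, 0.5))
  expect_equal(conditional_entropy(half)$entropy, 0.5)

  expect_error(conditional_entropy(det[0, ]), "empty")
})

test_that("plug-in entropy equals the brute-force double sum and the mean
           per-window information content", {
  set.seed(21)
  for (rep in 1:8) {
    m <- rand_melody(sample(80:250, 1))
    type <- sample(c("pitch", "rhythm", "pitch_rhythm", "rhythm_pitch"), 1)
    w <- encode_windows(m, type, sample(1:3, 1))
    tp <- estimate_tp(w)
    H <- conditional_entropy(tp)$entropy
    expect_equal(H, oracle_entropy(tp), tolerance = 1e-12)
    # identity: H = mean over windows of I(window)
    per_win <- dplyr::left_join(w, tp,
                                by = c("sequence_type", "order", "context",
                                       "continuation", "pattern"))
    expect_equal(H, mean(information_content(per_win$tp)), tolerance = 1e-9)
  }
})

test_that("entropy is invariant to token relabeling", {
  set.seed(22)
  m <- rand_melody(100)
  tp <- estimate_tp(encode_pitch(m, 2))
  h0 <- conditional_entropy(tp)$entropy
  perm <- tp
  key <- unique(perm$continuation)
  perm$continuation <- setNames(sample(key), key)[perm$continuation]
  expect_equal(conditional_entropy(perm)$entropy, h0)
})

test_that("i.i.d. uniform data approaches log2(m) bits", {
  set.seed(23)
  steps <- sample(c(-2L, -1L, 1L, 2L), 20000, replace = TRUE)
  m <- tibble::tibble(onset = seq_len(20001) - 1, pitch = 60L + cumsum(c(0L, steps)))
  tp <- estimate_tp(encode_pitch(m, 1))
  expect_equal(conditional_entropy(tp)$entropy, 2, tolerance = 0.01)
})

test_that("entropy_profile covers pieces x types x orders", {
  set.seed(24)
  notes <- dplyr::bind_rows(lapply(1:2, function(i) {
    m <- rand_melody(40)
    tibble::tibble(piece_id = paste0("p", i), musician_id = "m",
                   chronological_index = i, onset = m$onset, duration = 0.5,
                   pitch = m$pitch, is_grace = FALSE, slur_group = NA_integer_)
  }))
  prof <- entropy_profile(notes, types = c("pitch", "rhythm"), orders = 1:2)
  expect_equal(nrow(prof), 2 * 2 * 2)
  expect_true(all(prof$entropy >= 0))
})
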