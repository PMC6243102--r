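four <- c(-2L, -1L, 1L, 2L)

test_that("undecorated samples reproduce their truth line exactly", {
  sp <- musician_spec("m", four, peaked_tp(four, 2), order = 2)
  s <- sample_piece(sp, 1, length = 200, seed = 1)
  mel <- extract_melody(s$notes)
  expect_equal(mel$onset, s$truth$onset)
  expect_equal(mel$pitch, s$truth$pitch)
})

test_that("decorations never leak into the skyline truth line", {
  sp <- musician_spec("m", four, peaked_tp(four, 2), order = 2,
                      chord_prob = 0.4, grace_prob = 0.15,
                      transposition = 3L, tempo_scale = 1.25)
  s <- sample_piece(sp, 1, length = 400, seed = 2)
  mel <- extract_melody(s$notes)
  expect_equal(mel$onset, s$truth$onset)
  expect_equal(mel$pitch, s$truth$pitch)
  expect_gt(nrow(s$notes), nrow(s$truth))  # decorations actually happened
  expect_gt(sum(s$notes$is_grace), 0)
})

test_that("decorations leave estimated TP tables unchanged for the invariant streams", {
  plain <- musician_spec("m", four, peaked_tp(four, 2), order = 2)
  fancy <- musician_spec("m", four, peaked_tp(four, 2), order = 2,
                         chord_prob = 0.3, grace_prob = 0.1,
                         transposition = -4L, tempo_scale = 0.75)
  s1 <- sample_piece(plain, 1, length = 500, seed = 33)
  s2 <- sample_piece(fancy, 1, length = 500, seed = 33)
  for (cfg in list(list("pitch", 3L), list("rhythm", 2L),
                   list("rhythm_pitch", 2L), list("pitch_rhythm", 2L))) {
    t1 <- estimate_tp(encode_windows(extract_melody(s1$notes), cfg[[1]], cfg[[2]]))
    t2 <- estimate_tp(encode_windows(extract_melody(s2$notes), cfg[[1]], cfg[[2]]))
    expect_equal(t1, t2, info = cfg[[1]])
  }
})

test_that("a deterministic generator yields zero conditional entropy", {
  det <- musician_spec("m", four, peaked_tp(four, 2, peak = 1 - 1e-12), order = 2)
  expect_equal(spec_entropy(det), 0, tolerance = 1e-9)
  s <- sample_piece(det, 1, length = 300, seed = 3, fold = NULL)
  tp <- estimate_tp(encode_pitch(s$truth, 3))
  expect_equal(conditional_entropy(tp)$entropy, 0, tolerance = 1e-9)
})

test_that("a uniform generator's estimated entropy approaches log2(m)", {
  unif <- musician_spec("m", four, matrix(0.25, 16, 4), order = 2)
  expect_equal(spec_entropy(unif), 2, tolerance = 1e-12)
  s <- sample_piece(unif, 1, length = 20000, seed = 4, fold = NULL)
  tp <- estimate_tp(encode_pitch(s$truth, 3))
  expect_equal(conditional_entropy(tp)$entropy, 2, tolerance = 0.02)
})

test_that("drift moves the named pattern linearly and renormalizes the context", {
  dr <- tibble::tibble(context = "-2", interval = -1L, slope = 0.05)
  sp <- musician_spec("m", four, peaked_tp(four, 1, peak = 0.4), order = 1,
                      drift = dr)
  t1 <- drifted_tp(sp, 1)
  t7 <- drifted_tp(sp, 7)
  expect_equal(t1["-2", "-1"], sp$tp["-2", "-1"])  # index 1: no change
  expect_equal(t7["-2", "-1"], sp$tp["-2", "-1"] + 0.05 * 6, tolerance = 1e-12)
  expect_equal(unname(rowSums(t7)), rep(1, 4), tolerance = 1e-12)
  # untouched contexts identical
  expect_equal(t7["1", ], sp$tp["1", ])
})

test_that("corpora are reproducible from the seed and carry ground truth", {
  specs <- list(
    musician_spec("a", four, peaked_tp(four, 1), order = 1),
    musician_spec("b", four, peaked_tp(four, 1), order = 1)
  )
  c1 <- make_corpus(specs, pieces_per_musician = 3, length = 100, seed = 9)
  c2 <- make_corpus(specs, pieces_per_musician = 3, length = 100, seed = 9)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$truth, c2$truth)
  c3 <- make_corpus(specs, pieces_per_musician = 3, length = 100, seed = 10)
  expect_false(identical(c1$notes, c3$notes))

  expect_equal(nrow(c1$manifest), 6)
  expect_setequal(unique(c1$manifest$musician_id), c("a", "b"))
  expect_equal(length(c1$ground_truth), 6)
  expect_error(make_corpus(list(specs[[1]], specs[[1]])), "distinct")
})

test_that("pipeline TP estimates converge to the generator tables", {
  sp <- musician_spec("m", four, peaked_tp(four, 2, peak = 0.7), order = 2)
  s <- sample_piece(sp, 1, length = 50000, seed = 17, fold = NULL)
  est <- estimate_tp(encode_pitch(s$truth, 3))
  truth <- spec_tp_table(sp)
  j <- dplyr::inner_join(est, truth, by = c("context", "continuation"))
  heavy <- j[j$context_prob >= 0.01, ]
  expect_gt(nrow(heavy), 30)
  expect_lt(max(abs(heavy$tp - heavy$tp_true)), 0.03)
  # estimated entropy near the stationary generator entropy
  expect_equal(conditional_entropy(est)$entropy, spec_entropy(sp),
               tolerance = 0.02)
})

test_that("pitch folding keeps corpus pieces inside the playable range", {
  sp <- musician_spec("m", c(-7L, -3L, 3L, 7L), peaked_tp(c(-7L, -3L, 3L, 7L), 1),
                      order = 1)
  s <- sample_piece(sp, 1, length = 3000, seed = 5)
  expect_true(all(s$truth$pitch >= 24 & s$truth$pitch <= 108))
  expect_error(sample_piece(sp, 1, length = 2), "at least")
})
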