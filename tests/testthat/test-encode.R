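mel <- function(onset, pitch) tibble::tibble(onset = onset, pitch = pitch)

test_that("pitch windows are re-zeroed semitone offsets", {
  w <- encode_pitch(mel(0:2, c(60, 59, 57)), 2)
  expect_equal(w$pattern, "[0, -1, -3]")
  expect_equal(w$context, "[0, -1]")
  expect_equal(w$continuation, "-3")

  w <- encode_pitch(mel(0:1, c(60, 60)), 1)
  expect_equal(w$pattern, "[0, 0]")  # repeated-note token

  long <- mel(0:4, c(60, 64, 64, 62, 65))
  expect_equal(nrow(encode_pitch(long, 2)), 3)      # L - n windows
  expect_equal(nrow(encode_pitch(long, 4)), 1)
  expect_equal(nrow(encode_pitch(long, 5)), 0)      # too short
})

test_that("rhythm windows are IOI ratios to the window's first IOI", {
  w <- encode_rhythm(mel(c(0, 1, 2, 4), c(60, 60, 60, 60)), 2)
  expect_equal(w$pattern, "[1, 1, 2]")
  w <- encode_rhythm(mel(c(0, 1, 1 + 1/3), c(60, 60, 60)), 1)
  expect_equal(w$pattern, "[1, 0.333]")  # 3-decimal rounding collides thirds
  long <- mel(cumsum(c(0, rep(0.5, 6))), rep(60, 7))
  expect_equal(nrow(encode_rhythm(long, 2)), 7 - 2 - 1)  # L - n - 1 windows
})

test_that("joint windows pair the pitch and rhythm tokens positionally", {
  w <- encode_pitch_rhythm(mel(c(0, 0.5), c(60, 61)), 1)
  expect_equal(w$pattern, "[0, 1] with [0.5]")  # order-1 crotchet ratio
  w <- encode_pitch_rhythm(mel(c(0, 1, 1.5), c(60, 59, 58)), 2)
  expect_equal(w$pattern, "[0, -1, -2] with [1, 0.5]")
  expect_equal(w$context, "[0, -1] with [1]")
  expect_equal(w$continuation, "-2 with 0.5")

  w <- encode_rhythm_pitch(mel(c(0, 1, 2), c(60, 64, 66)), 1)
  expect_equal(w$pattern, "[1, 1] with [0, 4, 6]")
  w <- encode_rhythm_pitch(mel(0:3, c(60, 59, 57, 56)), 2)
  expect_equal(w$pattern, "[1, 1, 1] with [0, -1, -3, -4]")
  expect_equal(w$continuation, "1 with -4")
})

test_that("window streams equal brute-force enumeration on random melodies", {
  set.seed(101)
  for (rep in 1:25) {
    m <- rand_melody(sample(8:40, 1))
    for (type in c("pitch", "rhythm", "pitch_rhythm", "rhythm_pitch")) {
      n <- sample(1:6, 1)
      got <- encode_windows(m, type, n)
      want <- oracle_windows(m$onset, m$pitch, type, n)
      expect_same_windows(got, want)
    }
  }
  # the large-melody cases
  big <- rand_melody(500)
  expect_same_windows(encode_pitch(big, 3),
                      oracle_windows(big$onset, big$pitch, "pitch", 3))
  expect_same_windows(encode_rhythm(big, 4),
                      oracle_windows(big$onset, big$pitch, "rhythm", 4))
  mid <- rand_melody(300)
  expect_same_windows(encode_pitch_rhythm(mid, 3),
                      oracle_windows(mid$onset, mid$pitch, "pitch_rhythm", 3))
  expect_same_windows(encode_rhythm_pitch(mid, 2),
                      oracle_windows(mid$onset, mid$pitch, "rhythm_pitch", 2))
})

test_that("transposition and tempo invariances hold", {
  set.seed(7)
  m <- rand_melody(60)
  for (type in c("pitch", "rhythm", "pitch_rhythm", "rhythm_pitch")) {
    for (n in c(1, 3)) {
      base <- encode_windows(m, type, n)
      up <- encode_windows(dplyr::mutate(m, pitch = pitch + 7L), type, n)
      expect_identical(base$pattern, up$pattern)
    }
  }
  scaled <- dplyr::mutate(m, onset = onset * 1.75)
  for (type in c("rhythm", "rhythm_pitch")) {
    expect_identical(encode_windows(m, type, 2)$pattern,
                     encode_windows(scaled, type, 2)$pattern)
  }
  # joint pitch-led stream: invariant from order 2, crotchet-scaled at order 1
  expect_identical(encode_pitch_rhythm(m, 2)$pattern,
                   encode_pitch_rhythm(scaled, 2)$pattern)
  o1 <- encode_pitch_rhythm(m, 1)
  o1s <- encode_pitch_rhythm(scaled, 1)
  expect_false(identical(o1$pattern, o1s$pattern))
  expect_identical(o1$context, o1s$context)  # the pitch part is unchanged
})

test_that("first tokens are the relative-encoding anchors", {
  set.seed(8)
  m <- rand_melody(40)
  expect_true(all(startsWith(encode_pitch(m, 3)$pattern, "[0, ")))
  expect_true(all(startsWith(encode_rhythm(m, 3)$pattern, "[1, ")))
  expect_true(all(startsWith(encode_rhythm_pitch(m, 2)$pattern, "[1, ")))
  expect_true(all(grepl("with \\[0, ", encode_rhythm_pitch(m, 2)$pattern)))
})

test_that("multi-piece melodies are encoded independently per piece", {
  m2 <- dplyr::bind_rows(
    dplyr::mutate(mel(0:3, c(60, 62, 64, 65)), piece_id = "a"),
    dplyr::mutate(mel(0:2, c(50, 55, 60)), piece_id = "b")
  )
  w <- encode_pitch(m2, 1)
  expect_equal(as.integer(table(w$piece_id)[c("a", "b")]), c(3L, 2L))
  # same as encoding each piece alone
  expect_equal(w$pattern[w$piece_id == "b"],
               encode_pitch(mel(0:2, c(50, 55, 60)), 1)$pattern)
})
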