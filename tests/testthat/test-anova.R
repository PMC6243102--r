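mk_long <- function(Y, groups) {
  k <- ncol(Y)
  tibble::tibble(
    piece_id = rep(paste0("p", seq_len(nrow(Y))), k),
    musician_id = rep(groups, k),
    pattern = rep(paste0("pat", seq_len(k)), each = nrow(Y)),
    logit_tp = as.vector(Y)
  )
}

test_that("identical values everywhere give null effects", {
  Y <- matrix(1.7, 9, 3)
  a <- tp_anova(mk_long(Y, rep(c("A", "B", "C"), each = 3)))
  expect_equal(tidy(a)$statistic, rep(0, 3))
  expect_equal(tidy(a)$p.value, rep(1, 3))
})

test_that("sums of squares match hand-computed split-plot decomposition", {
  set.seed(41)
  groups <- rep(c("A", "B", "C"), each = 3)
  Y <- matrix(rnorm(27), 9, 3) + outer(as.integer(factor(groups)), 1:3)
  d <- mk_long(Y, groups)
  a <- tp_anova(d, posthoc = FALSE)
  ss <- oracle_splitplot_ss(d$logit_tp, d$musician_id, d$piece_id, d$pattern)
  eff <- tidy(a)
  pes <- function(e, err) e / (e + err)
  expect_equal(eff$partial_eta_sq[eff$effect == "musician_id"],
               pes(ss$between, ss$subj_error), tolerance = 1e-9)
  expect_equal(eff$partial_eta_sq[eff$effect == "pattern"],
               pes(ss$within, ss$within_error), tolerance = 1e-9)
  expect_equal(eff$partial_eta_sq[eff$effect == "musician_id:pattern"],
               pes(ss$interaction, ss$within_error), tolerance = 1e-9)
  # F ratios recomputed from the same sums of squares
  a_n <- 3; s_n <- 3; k_n <- 3
  F_between <- (ss$between / (a_n - 1)) / (ss$subj_error / (a_n * (s_n - 1)))
  expect_equal(eff$statistic[eff$effect == "musician_id"], F_between,
               tolerance = 1e-9)
  F_inter <- (ss$interaction / ((a_n - 1) * (k_n - 1))) /
    (ss$within_error / (a_n * (s_n - 1) * (k_n - 1)))
  expect_equal(eff$statistic[eff$effect == "musician_id:pattern"], F_inter,
               tolerance = 1e-9)
})

test_that("Greenhouse-Geisser correction engages when sphericity fails", {
  set.seed(42)
  n <- 24
  # strongly correlated within-subject columns with unequal variances
  base <- rnorm(n)
  Y <- cbind(base + rnorm(n, sd = 0.1), base * 3 + rnorm(n, sd = 0.1),
             rnorm(n, sd = 2), base + (1:n) / 8)
  a <- tp_anova(mk_long(Y, rep(c("A", "B"), each = 12)))
  eff <- tidy(a)
  wr <- eff[eff$effect == "pattern", ]
  expect_true(nrow(a$mauchly) > 0)
  if (any(a$mauchly$p.value < 0.05)) {
    expect_true(wr$gg_applied)
    expect_lt(wr$df1_corrected, wr$df1)       # corrected dfs shrink
    expect_gt(wr$gg_epsilon, 1 / (ncol(Y) - 1))  # epsilon lower bound
  }
})

test_that("an injected musician-by-pattern interaction is detected with high power", {
  set.seed(43)
  reps <- 150
  hits <- 0
  for (r in seq_len(reps)) {
    groups <- rep(c("A", "B", "C"), each = 7)
    Y <- matrix(rnorm(21 * 5), 21, 5)
    # crossed interaction: musician A trades pattern 1 against pattern 2,
    # each displaced by d = 1.5 within-cell standard deviations
    Y[groups == "A", 1] <- Y[groups == "A", 1] + 1.5
    Y[groups == "A", 2] <- Y[groups == "A", 2] - 1.5
    a <- tp_anova(mk_long(Y, groups), posthoc = FALSE)
    p <- tidy(a)$p.value[tidy(a)$effect == "musician_id:pattern"]
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / reps, 0.8)
})

test_that("unbalanced designs are rejected with the missing cells named", {
  d <- mk_long(matrix(rnorm(12), 4, 3), rep(c("A", "B"), each = 2))
  expect_error(tp_anova(d[-1, ]), "missing cells")
})

test_that("post-hoc tables are Bonferroni-corrected per family", {
  set.seed(44)
  groups <- rep(c("A", "B", "C"), each = 7)
  Y <- matrix(rnorm(21 * 3), 21, 3)
  Y[groups == "A", ] <- Y[groups == "A", ] + 2
  a <- tp_anova(mk_long(Y, groups))
  ph <- a$posthoc
  expect_true(all(ph$p.adjusted >= ph$p.value - 1e-12))
  expect_true(all(ph$p.adjusted <= 1))
  fam <- ph[ph$family == "between", ]
  expect_equal(nrow(fam), 3)  # three musician pairs
  expect_equal(fam$p.adjusted, pmin(fam$p.value * 3, 1))
  # the shifted group separates from both others overall
  expect_true(all(fam$p.adjusted[fam$group1 == "A" | fam$group2 == "A"] < 0.05))
})
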