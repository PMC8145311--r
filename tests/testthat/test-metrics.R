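test_that("Welch t agrees with stats::t.test on 1000 random instances", {
  set.seed(101)
  for (i in 1:1000) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(3:12, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    got <- welch_t(x, y, tails = "two")
    ref <- t.test(x, y, var.equal = FALSE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch t handles identical and degenerate inputs deterministically", {
  x <- c(1, 2, 3, 4)
  same <- welch_t(x, x, tails = "one")
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  # zero variance in both samples
  expect_equal(welch_t(c(1, 1), c(1, 1))$p, 1)
  expect_equal(welch_t(c(2, 2), c(1, 1))$p, 0)
  expect_error(welch_t(1, c(1, 2)), "length >= 2")
})

test_that("summary-mode Welch t reproduces the frozen formula oracle", {
  # independently computed from se2 = sd_a^2/n_a + sd_b^2/n_b and
  # Welch-Satterthwaite df, for means 62.73/28.07, SDs 7.34/6.85, n 16/14
  got <- welch_t_summary(62.73, 7.34, 16, 28.07, 6.85, 14, tails = "one")
  expect_equal(got$t, 13.3715472337, tolerance = 1e-10)
  expect_equal(got$df, 27.8662458324, tolerance = 1e-10)
  expect_equal(got$p, 1.203063e-13 / 2, tolerance = 1e-5)
  # summary mode equals vector mode on matching data
  set.seed(2)
  x <- rnorm(9); y <- rnorm(7, 1)
  expect_equal(welch_t_summary(mean(x), sd(x), 9, mean(y), sd(y), 7)$p,
               welch_t(x, y)$p, tolerance = 1e-12)
})

test_that("Welch p for fully separated small samples sits near the exact permutation bound", {
  x <- c(10, 11, 12, 13); y <- c(1, 2, 3, 4)
  # exact permutation test at n = 4 + 4: enumerate all 70 group splits
  pooled <- c(x, y)
  splits <- combn(8, 4)
  diffs <- apply(splits, 2, function(ix) mean(pooled[ix]) - mean(pooled[-ix]))
  obs <- mean(x) - mean(y)
  perm_p <- mean(diffs >= obs)
  expect_equal(perm_p, 1 / 70)           # observed split is the most extreme
  w <- welch_t(x, y, tails = "one")
  expect_lt(w$p, 0.05)                   # both reject
  expect_lt(w$p, perm_p)                 # t-model extrapolates beyond 1/70
})

test_that("Cohen's d reproduces the published summary-table effect sizes", {
  expect_equal(round_half_up(cohens_d(62.73, 7.34, 28.07, 6.85), 2), 4.88)
  expect_equal(round_half_up(cohens_d(64.12, 4.17, 26.78, 6.13), 2), 7.12)
  expect_equal(cohens_d(5, 1, 5, 2), 0)
  # antisymmetric under group swap
  expect_equal(cohens_d(3, 1, 7, 2), -cohens_d(7, 2, 3, 1))
  expect_error(cohens_d(1, 0, 2, 0), "undefined")
})

test_that("power via the noncentral t is calibrated, monotone, and matches power.t.test", {
  expect_equal(power_estimate(0, 10, 12), 0.05, tolerance = 1e-6)
  grid <- seq(0, 3, by = 0.25)
  pw <- vapply(grid, power_estimate, numeric(1), n_a = 8, n_b = 10)
  expect_true(all(diff(pw) >= 0))
  for (d in c(0.3, 0.8, 1.5))
    expect_equal(power_estimate(d, 12, 12),
                 power.t.test(n = 12, delta = d, sd = 1,
                              strict = TRUE)$power,
                 tolerance = 1e-6)
})

test_that("self-computed cut-off lines coincide for all valid inputs", {
  got <- cutoff_lines(63.67, 5.01, 37.29, 5.86)
  expect_equal(round_half_up(got$multiplier, 2), 2.43)
  expect_equal(got$cutoff_a, got$cutoff_b, tolerance = 1e-12)
  expect_equal(cutoff_lines(1, 1, 0, 1)$multiplier, 0.5)
  set.seed(33)
  for (i in 1:200) {
    mns <- sort(runif(2, 0, 100)); sds <- runif(2, 0.01, 20)
    cl <- cutoff_lines(mns[2], sds[1], mns[1], sds[2])
    expect_equal(cl$multiplier * (sds[1] + sds[2]), mns[2] - mns[1],
                 tolerance = 1e-10)
    expect_equal(cl$cutoff_a, cl$cutoff_b, tolerance = 1e-10)
  }
  expect_error(cutoff_lines(5, 0, 3, 0), "> 0")
  expect_error(cutoff_lines(3, 1, 5, 1), "higher-mean")
})

test_that("a reused multiplier on randomized statistics crosses the lines", {
  cl <- cutoff_lines(50, 6, 45, 6, multiplier = 2.43)
  expect_equal(cl$cutoff_a, 50 - 2.43 * 6)   # 35.42
  expect_equal(cl$cutoff_b, 45 + 2.43 * 6)   # 59.58
  expect_lt(cl$cutoff_a, cl$cutoff_b)        # crossed, dual-count regime
})

test_that("confusion metrics count coincident, crossed, and gap regimes correctly", {
  cls <- data.frame(
    sample_id = sprintf("s%d", 1:6),
    true_group = rep(c("A", "B"), each = 3),
    n_peaks = 10,
    pct_a = c(80, 70, 60, 40, 30, 20))
  cls$pct_b <- 100 - cls$pct_a

  # coincident cut-off at 50: perfect separation
  cm <- confusion_metrics(cls, 50, 50, "A")
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(3, 0, 3, 0))
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$efficiency, 1)

  # sample exactly on a coincident line counts once, as correct
  tie <- cls; tie$pct_a[3] <- 50; tie$pct_a[4] <- 50
  cmt <- confusion_metrics(tie, 50, 50, "A")
  expect_equal(c(cmt$tp, cmt$fn, cmt$tn, cmt$fp), c(3, 0, 3, 0))

  # crossed lines: an A sample between them is TP and FN at once
  cmx <- confusion_metrics(cls, 35, 65, "A")
  expect_equal(cmx$tp, 3)              # 80, 70, 60 all >= 35
  expect_equal(cmx$fn, 1)              # 60 also <= 65
  expect_equal(cmx$tn, 3)
  expect_equal(cmx$fp, 1)              # 40 >= 35
  expect_gte(cmx$tp + cmx$fn, 3)
  expect_gte(cmx$tn + cmx$fp, 3)

  # uncrossed coincident lines partition each group exactly
  expect_equal(cm$tp + cm$fn, 3)
  expect_equal(cm$tn + cm$fp, 3)

  # empty classification list
  cm0 <- confusion_metrics(cls[0, ], 50, 50, "A")
  expect_equal(cm0$tp + cm0$fn + cm0$tn + cm0$fp, 0)
  expect_true(is.na(cm0$sensitivity))
})

test_that("summarize_comparison assembles all distribution-level statistics", {
  co <- separated_cohort(seed = 77)
  cls <- run_loocv(co)
  st <- summarize_comparison(cls)
  expect_equal(st$n_a, 6); expect_equal(st$n_b, 6)
  expect_equal(st$cutoff_a, st$cutoff_b, tolerance = 1e-10)
  expect_equal(st$effect_d,
               cohens_d(st$mean_a, st$sd_a, st$mean_b, st$sd_b))
  w <- welch_t(cls$pct_a[cls$true_group == "A"],
               cls$pct_a[cls$true_group == "B"])
  expect_equal(st$p_value, w$p)
  expect_equal(st$sensitivity, 1)
  expect_equal(st$specificity, 1)
})
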