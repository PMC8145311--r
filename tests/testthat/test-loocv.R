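test_that("peak selection retains the planted m/z with the Welch-oracle p value", {
  # one planted column; every other column identical across the two groups
  base <- matrix(rep(c(1, 2, 3, 4), 3), nrow = 4)    # same in both groups
  m <- rbind(cbind(planted = c(10, 10, 10, 10), base),
             cbind(planted = c(20, 20, 20, 21), base))
  colnames(m) <- as.character(c(685, 700, 701, 702))
  co <- matrix_cohort(m, rep(c("A", "B"), each = 4))
  pcvs <- select_significant_peaks(co, alpha = 0.05, floor_fraction = 0.003)
  expect_equal(pcvs$mz, 685L)
  # independent oracle: R's Welch t.test, one-tailed = two-tailed / 2
  tt <- t.test(c(10, 10, 10, 10), c(20, 20, 20, 21), var.equal = FALSE)
  expect_equal(pcvs$p_value, tt$p.value / 2, tolerance = 1e-12)
  expect_equal(pcvs$direction, "B")
  expect_equal(pcvs$pcv, (10 + 20.25) / 2)
  expect_equal(pcvs$mean_a, 10)
  expect_equal(pcvs$mean_b, 20.25)
})

test_that("the relative-abundance floor excludes trace peaks regardless of p", {
  set.seed(3)
  noise <- matrix(rlnorm(8 * 5, log(100), 0.1), 8)   # abundant, no group effect
  trace <- c(rep(0.10, 4), rep(0.20, 4)) * (1 + rnorm(8, 0, 1e-3))
  m <- cbind(noise, trace)                            # trace max mean ~0.2% of ~100
  colnames(m) <- as.character(500:505)
  co <- matrix_cohort(m, rep(c("A", "B"), each = 4))
  pcvs <- select_significant_peaks(co)
  expect_false(505L %in% pcvs$mz)
  # with the floor disabled the same peak is retained
  pcvs2 <- select_significant_peaks(co, floor_fraction = 0)
  expect_true(505L %in% pcvs2$mz)
})

test_that("classification uses strict 'above the PCV' with ties to the opposite group", {
  pcv_df <- data.frame(mz = c(500L, 600L), p_value = 0.01,
                       mean_a = c(10, 2), mean_b = c(4, 8),
                       direction = c("A", "B"), pcv = c(7, 5))
  pcvs <- seroclass:::new_pcv_set(pcv_df, "x", "A", "B", 0.05, 0.003)

  # areas equal to mean_a everywhere -> all peaks classified to A
  full_a <- classify_sample(peak_areas("s", c(500, 600), c(10, 2)), pcvs)
  expect_equal(full_a$pct_a, 100)    # 10 > 7 -> A; 2 <= 5 -> opposite of B = A

  # area exactly at the pcv of an A-direction peak counts for B
  tie <- classify_sample(peak_areas("s", c(500, 600), c(7, 2)), pcvs)
  expect_equal(tie$pct_a, 50)
  expect_equal(tie$pct_a + tie$pct_b, 100)

  # absent peak = area 0 (below both PCVs here)
  absent <- classify_sample(peak_areas("s", integer(0), numeric(0)), pcvs)
  expect_equal(absent$pct_a, 50)     # 0 <= 7 -> B; 0 <= 5 -> A

  expect_error(classify_sample(peak_areas("s", 500, 1), pcvs[0, ]), "empty")
})

test_that("classification matches the per-peak comparison oracle on random instances", {
  set.seed(17)
  for (i in 1:300) {
    n_pk <- sample(3:25, 1)
    mzs <- sort(sample(400:800, n_pk))
    ma <- rlnorm(n_pk, 2, 1); mb <- rlnorm(n_pk, 2, 1)
    pcv_df <- data.frame(mz = mzs, p_value = 0.01, mean_a = ma, mean_b = mb,
                         direction = ifelse(ma > mb, "A", "B"),
                         pcv = (ma + mb) / 2)
    pcvs <- seroclass:::new_pcv_set(pcv_df, "x", "A", "B", 0.05, 0.003)
    have <- sort(sample(mzs, sample(0:n_pk, 1)))
    areas <- rlnorm(length(have), 2, 1)
    got <- classify_sample(peak_areas("s", have, areas), pcvs)
    expect_equal(got$pct_a, oracle_classify(areas, have, pcv_df, "A", "B"))
  }
})

test_that("LOOCV classifies every sample once from the other N-1 samples", {
  co <- separated_cohort()
  cls <- run_loocv(co)
  expect_equal(nrow(cls), 12)
  expect_setequal(cls$sample_id, co$metadata$sample_id)
  expect_length(attr(cls, "fold_peaks"), 12)
  # a strongly separated cohort ranks every A above every B
  expect_gt(min(cls$pct_a[cls$true_group == "A"]),
            max(cls$pct_a[cls$true_group == "B"]))
  expect_equal(cls$pct_a + cls$pct_b, rep(100, 12))
})

test_that("LOOCV folds are independent of the left-out sample's own areas", {
  co <- separated_cohort(seed = 9)
  id1 <- co$metadata$sample_id[1]
  fold_before <- select_significant_peaks(cohort_subset(co, id1, drop = TRUE))
  co2 <- co
  co2$areas[1, ] <- co2$areas[1, ] * 10 + 1   # distort the left-out sample
  fold_after <- select_significant_peaks(cohort_subset(co2, id1, drop = TRUE))
  expect_identical(as.data.frame(fold_before), as.data.frame(fold_after))
})

test_that("LOOCV is invariant to sample order and m/z column order", {
  co <- separated_cohort(seed = 12)
  cls <- run_loocv(co)
  perm <- sample(nrow(co$metadata))
  cperm <- sample(ncol(co$areas))
  co2 <- cohort(co$metadata[perm, ], co$areas[perm, cperm], "A", "B")
  cls2 <- run_loocv(co2)
  idx <- match(cls$sample_id, cls2$sample_id)
  expect_equal(cls$pct_a, cls2$pct_a[idx])
  expect_equal(cls$n_peaks, cls2$n_peaks[idx])
})

test_that("relabeling the groups mirrors the classification percentages", {
  co <- separated_cohort(seed = 21)             # continuous data: tie-free
  cls <- run_loocv(co)
  swapped <- cohort(co$metadata, co$areas, label_a = "B", label_b = "A")
  cls_sw <- run_loocv(swapped)
  idx <- match(cls$sample_id, cls_sw$sample_id)
  expect_equal(cls_sw$pct_a[idx], 100 - cls$pct_a, tolerance = 1e-12)
})

test_that("the full-cohort PCV set equals selection with nothing left out", {
  co <- separated_cohort(seed = 30)
  full <- build_full_pcv_set(co)
  sel <- select_significant_peaks(co)
  expect_identical(as.data.frame(full), as.data.frame(sel))
  expect_setequal(attr(full, "left_in_ids"), co$metadata$sample_id)
})

test_that("degenerate groups are rejected and zero-variance contrasts handled", {
  m <- matrix(1:8, nrow = 4)
  colnames(m) <- c("500", "501")
  expect_error(run_loocv(matrix_cohort(m, c("A", "A", "A", "B"))),
               "at least 2 samples")
  # zero variance in both groups, unequal means -> retained with p = 0
  m2 <- cbind(`500` = c(1, 1, 1, 2, 2, 2),
              `501` = c(0.5, 1, 1.5, 0.7, 1.2, 0.9))
  co2 <- matrix_cohort(m2, rep(c("A", "B"), each = 3))
  pcvs <- select_significant_peaks(co2)
  expect_true(500L %in% pcvs$mz)
  expect_equal(pcvs$p_value[pcvs$mz == 500L], 0)
  # identical area matrices in both groups -> nothing selected
  m3 <- rbind(m, m)
  co3 <- matrix_cohort(m3, rep(c("A", "B"), each = 4))
  expect_equal(nrow(select_significant_peaks(co3)), 0)
})

test_that("null cohorts show no systematic group bias in % classified", {
  diffs <- vapply(1:8, function(s) {
    co <- as_cohort(simulate_cohort(synth_params(
      n_a = 8, n_b = 8, mz_lo = 400, mz_hi = 799, n_discriminatory = 0,
      effect_delta = 0, peak_density = 0.2, seed = s)))
    cls <- run_loocv(co)
    mean(cls$pct_a[cls$true_group == "mildAD"]) -
      mean(cls$pct_a[cls$true_group == "control"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 10)        # centered difference
  expect_true(any(diffs > 0) && any(diffs < 0))  # no systematic sign
})
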