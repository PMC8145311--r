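# Independent brute-force oracles and small fixture builders.  Each oracle
# re-derives the expected result by direct per-element computation, kept
# deliberately separate from the package's vectorized implementations.

# Per-point accumulation loop for nominal binning.
oracle_bin <- function(mz, intensity, mz_lo, mz_hi) {
  out <- numeric(mz_hi - mz_lo + 1L)
  for (k in seq_along(mz)) {
    key <- floor(mz[k] + 0.5)          # half-up for positive m/z
    if (key >= mz_lo && key <= mz_hi)
      out[key - mz_lo + 1L] <- out[key - mz_lo + 1L] + intensity[k]
  }
  out
}

# Exhaustive valley scan: a bin is a valley if zero, or if positive and
# the nearest distinct values on both sides are larger and it is the
# leftmost bin of its equal-valued plateau.  A valley starts a new run
# (the valley bin belongs to the run on its right); runs with positive
# total become peaks keyed by the rounded intensity-weighted mean m/z.
oracle_centroid <- function(x, mz) {
  n <- length(x)
  is_valley <- logical(n)
  for (i in seq_len(n)) {
    if (x[i] == 0) { is_valley[i] <- TRUE; next }
    if (i > 1 && x[i - 1] == x[i]) next        # not leftmost of plateau
    j <- i - 1
    while (j >= 1 && x[j] == x[i]) j <- j - 1
    k <- i + 1
    while (k <= n && x[k] == x[i]) k <- k + 1
    if (j >= 1 && k <= n && x[j] > x[i] && x[k] > x[i])
      is_valley[i] <- TRUE
  }
  run <- cumsum(is_valley)
  peaks <- list()
  for (r in unique(run)) {
    idx <- which(run == r)
    tot <- sum(x[idx])
    if (tot > 0) {
      key <- floor(sum(x[idx] * mz[idx]) / tot + 0.5)
      peaks[[as.character(key)]] <-
        (peaks[[as.character(key)]] %||% 0) + tot
    }
  }
  keys <- as.integer(names(peaks))
  o <- order(keys)
  list(mz = keys[o], area = unlist(peaks, use.names = FALSE)[o])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Explicit per-peak comparison loop for sample classification.
oracle_classify <- function(areas, mzs, pcv_df, label_a, label_b) {
  n_a <- 0L
  for (r in seq_len(nrow(pcv_df))) {
    a <- 0
    hit <- which(mzs == pcv_df$mz[r])
    if (length(hit)) a <- areas[hit]
    assigned <- if (a > pcv_df$pcv[r]) pcv_df$direction[r]
                else if (pcv_df$direction[r] == label_a) label_b
                else label_a
    if (assigned == label_a) n_a <- n_a + 1L
  }
  100 * n_a / nrow(pcv_df)
}

# Cohort built directly from an area matrix (bypassing spectra) for
# deterministic small-scale tests.
matrix_cohort <- function(m, groups, label_a = "A", label_b = "B",
                          sex = NULL, age = NULL) {
  n <- nrow(m)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(m) <- ids
  if (is.null(colnames(m)))
    colnames(m) <- as.character(seq(500, length.out = ncol(m)))
  md <- data.frame(sample_id = ids, group = groups,
                   sex = sex %||% rep(c("M", "F"), length.out = n),
                   age = age %||% seq(60, 80, length.out = n))
  cohort(md, m, label_a, label_b)
}

# Well-separated two-group cohort on a small grid: `n_disc` columns
# shifted in group A, the rest shared noise.
separated_cohort <- function(n_a = 6, n_b = 6, n_disc = 30, n_noise = 40,
                             shift = 5, seed = 42) {
  set.seed(seed)
  n <- n_a + n_b
  m <- matrix(rlnorm(n * (n_disc + n_noise), log(20), 0.3), n)
  m[seq_len(n_a), seq_len(n_disc)] <-
    m[seq_len(n_a), seq_len(n_disc)] * exp(shift * 0.3)
  matrix_cohort(m, rep(c("A", "B"), c(n_a, n_b)))
}
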