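# Column-wise Welch statistics for a cohort area matrix.
# Returns per-m/z means, one-tailed p (in the observed direction) and a
# "degenerate" flag for columns with zero variance in both groups and
# equal means (no usable contrast).
peak_welch_sweep <- function(m, rows_a, rows_b) {
  na <- length(rows_a); nb <- length(rows_b)
  if (na < 2L || nb < 2L)
    stop_bad("each group needs at least 2 samples for peak t-tests")
  xa <- m[rows_a, , drop = FALSE]
  xb <- m[rows_b, , drop = FALSE]
  mean_a <- colMeans(xa); mean_b <- colMeans(xb)
  var_a <- (colSums(xa^2) - na * mean_a^2) / (na - 1)
  var_b <- (colSums(xb^2) - nb * mean_b^2) / (nb - 1)
  var_a <- pmax(var_a, 0); var_b <- pmax(var_b, 0)   # guard fp rounding
  se2 <- var_a / na + var_b / nb
  diff <- mean_a - mean_b
  degenerate <- se2 == 0 & diff == 0
  p_one <- numeric(length(diff))
  pos <- se2 > 0
  tstat <- diff[pos] / sqrt(se2[pos])
  df <- se2[pos]^2 /
    ((var_a[pos] / na)^2 / (na - 1) + (var_b[pos] / nb)^2 / (nb - 1))
  p_one[pos] <- stats::pt(-abs(tstat), df)
  p_one[!pos & diff != 0] <- 0            # zero variance, unequal means
  p_one[degenerate] <- NA_real_
  list(mean_a = mean_a, mean_b = mean_b, p_one = p_one,
       degenerate = degenerate)
}

new_pcv_set <- function(df, left_in_ids, label_a, label_b,
                        alpha, floor_fraction) {
  o <- order(df$mz)
  structure(df[o, , drop = FALSE],
            left_in_ids = left_in_ids, label_a = label_a, label_b = label_b,
            alpha = alpha, floor_fraction = floor_fraction,
            class = c("pcv_set", "data.frame"))
}

#' Select group-discriminating peaks and their PCV thresholds
#'
#' For every unit m/z observed anywhere in the cohort (a sample lacking
#' the peak contributes area 0) an unequal-variance Welch t statistic is
#' computed between the two groups, with a one-tailed p value in the
#' direction of the observed mean difference.  A peak is retained iff
#' `p < alpha` *and* the larger of its two group means reaches
#' `floor_fraction` of the maximum group-mean peak area over all m/z in
#' the data (a relative-abundance floor that discards trace peaks).
#' Each retained peak records the group with the larger mean
#' (`direction`) and its peak classification valuation
#' `pcv = (mean_a + mean_b) / 2`, the midpoint of the two group means.
#' m/z with zero variance in both groups and equal means carry no
#' contrast and are skipped; zero variance with unequal means is treated
#' as p = 0.
#'
#' @param x A `cohort`.
#' @param alpha Peak-level significance threshold (default 0.05).
#' @param floor_fraction Relative abundance floor (default 0.003, i.e.
#'   0.3% of the maximum group-mean peak area).
#' @return A `pcv_set`: data frame with columns `mz`, `p_value`,
#'   `mean_a`, `mean_b`, `direction`, `pcv`, sorted by m/z, plus
#'   attributes `left_in_ids`, `alpha`, `floor_fraction`.
#' @export
select_significant_peaks <- function(x, alpha = 0.05, floor_fraction = 0.003) {
  stopifnot(inherits(x, "cohort"))
  sw <- peak_welch_sweep(x$areas, group_rows(x, x$label_a),
                         group_rows(x, x$label_b))
  floor_base <- max(pmax(sw$mean_a, sw$mean_b), 0)
  keep <- !sw$degenerate &
    sw$p_one < alpha &
    pmax(sw$mean_a, sw$mean_b) >= floor_fraction * floor_base
  df <- data.frame(
    mz = x$mz[keep],
    p_value = sw$p_one[keep],
    mean_a = sw$mean_a[keep],
    mean_b = sw$mean_b[keep],
    direction = ifelse(sw$mean_a[keep] > sw$mean_b[keep],
                       x$label_a, x$label_b),
    pcv = (sw$mean_a[keep] + sw$mean_b[keep]) / 2,
    row.names = NULL)
  new_pcv_set(df, x$metadata$sample_id, x$label_a, x$label_b,
              alpha, floor_fraction)
}

#' @export
print.pcv_set <- function(x, ...) {
  cat(sprintf("<pcv_set> %d significant peaks (%s vs %s), alpha %g, floor %g\n",
              nrow(x), attr(x, "label_a"), attr(x, "label_b"),
              attr(x, "alpha"), attr(x, "floor_fraction")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Classify one sample's peaks against a PCV set
#'
#' At every peak of the PCV set, the sample's area at that m/z (0 when
#' the peak is absent) is compared to the peak's PCV threshold: an area
#' strictly above the PCV classifies the peak to the peak's `direction`
#' group; an area at or below the PCV classifies it to the opposite
#' group.  The sample's score is the percentage of peaks classified to
#' each group.
#'
#' @param areas A `peak_areas` (or a named numeric vector keyed by m/z).
#' @param pcvs A non-empty `pcv_set`.
#' @param true_group Optional known group label, carried into the result.
#' @return One-row data frame: `sample_id`, `true_group`, `n_peaks`,
#'   `pct_a`, `pct_b` (percent of peaks classified to `label_a` /
#'   `label_b`; they sum to 100).
#' @export
classify_sample <- function(areas, pcvs, true_group = NA_character_) {
  stopifnot(inherits(pcvs, "pcv_set"))
  if (!nrow(pcvs)) stop_bad("empty PCV set: no classification possible")
  a <- as.numeric(areas)[match(pcvs$mz, as.integer(names(areas)))]
  a[is.na(a)] <- 0
  above <- a > pcvs$pcv
  label_a <- attr(pcvs, "label_a"); label_b <- attr(pcvs, "label_b")
  assigned <- ifelse(above, pcvs$direction,
                     ifelse(pcvs$direction == label_a, label_b, label_a))
  pct_a <- 100 * mean(assigned == label_a)
  data.frame(sample_id = attr(areas, "sample_id") %||% NA_character_,
             true_group = true_group,
             n_peaks = nrow(pcvs),
             pct_a = pct_a, pct_b = 100 - pct_a,
             row.names = NULL)
}

#' Build the full-cohort PCV set (no sample left out)
#'
#' Identical to [select_significant_peaks()] on the whole cohort; used to
#' score blinded or external samples against an entire binary comparison.
#'
#' @inheritParams select_significant_peaks
#' @return A `pcv_set` whose `left_in_ids` are all cohort sample ids.
#' @export
build_full_pcv_set <- function(x, alpha = 0.05, floor_fraction = 0.003) {
  select_significant_peaks(x, alpha, floor_fraction)
}

#' Leave-one-out cross-validated peak classification
#'
#' Each sample is left out in turn; a PCV set is built from the other
#' N-1 samples only, and the left-out sample's raw peak areas are
#' classified against it.  The result is one classification per sample
#' -- the sample's percentage of peaks scored to each group.
#'
#' @inheritParams select_significant_peaks
#' @param fold_peaks_fn Internal hook: function(cohort) -> `pcv_set`
#'   used to build each fold's peak set (defaults to
#'   [select_significant_peaks()] with `alpha`/`floor_fraction`).
#' @return A `sample_classifications` data frame (`sample_id`,
#'   `true_group`, `n_peaks`, `pct_a`, `pct_b`) with an integer
#'   `fold_peaks` attribute recording each fold's significant-peak count.
#' @export
run_loocv <- function(x, alpha = 0.05, floor_fraction = 0.003,
                      fold_peaks_fn = NULL) {
  stopifnot(inherits(x, "cohort"))
  fold_peaks_fn <- fold_peaks_fn %||%
    function(co) select_significant_peaks(co, alpha, floor_fraction)
  ids <- x$metadata$sample_id
  rows <- lapply(seq_along(ids), function(i) {
    fold <- cohort_subset(x, ids[i], drop = TRUE)
    pcvs <- fold_peaks_fn(fold)
    classify_sample(cohort_areas(x, ids[i]), pcvs,
                    true_group = x$metadata$group[i])
  })
  out <- do.call(rbind, rows)
  structure(out,
            fold_peaks = vapply(rows, function(r) r$n_peaks, numeric(1)),
            label_a = x$label_a, label_b = x$label_b,
            class = c("sample_classifications", "data.frame"))
}

#' Write a PCV set as TSV
#' @param pcvs A `pcv_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pcv_set <- function(pcvs, path) {
  utils::write.table(as.data.frame(pcvs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample classifications as TSV
#' @param cls A `sample_classifications` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifications <- function(cls, path) {
  utils::write.table(as.data.frame(cls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
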