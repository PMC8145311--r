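welch_core <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                       tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (n_a < 2 || n_b < 2) stop_bad("each group needs n >= 2")
  if (any(c(sd_a, sd_b) < 0)) stop_bad("standard deviations must be >= 0")
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  se2 <- va + vb
  diff <- mean_a - mean_b
  if (se2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- NA_real_
    p <- if (diff == 0) { if (tails == "two") 1 else 0.5 } else 0
  } else {
    t <- diff / sqrt(se2)
    df <- se2^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
    p_one <- stats::pt(-abs(t), df)
    p <- if (tails == "two") 2 * p_one else p_one
  }
  list(t = t, df = df, p = p, tails = tails)
}

#' Welch unequal-variance t-test
#'
#' Two-sample t statistic with sample (n-1) variances, Welch-Satterthwaite
#' degrees of freedom, and a p value from the t distribution; the
#' one-tailed p is half the two-tailed p, taken in the observed direction
#' of the mean difference.
#'
#' @param x,y Numeric vectors (length >= 2 each).
#' @param tails `"two"` (default) or `"one"`.
#' @return List with `t`, `df`, `p`, `tails`.
#' @seealso [welch_t_summary()] for the summary-statistics form.
#' @export
welch_t <- function(x, y, tails = c("two", "one")) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) stop_bad("each sample needs length >= 2")
  if (anyNA(x) || anyNA(y)) stop_bad("missing values not allowed")
  welch_core(mean(x), stats::sd(x), length(x),
             mean(y), stats::sd(y), length(y), tails)
}

#' Welch t-test from summary statistics
#'
#' @param mean_a,sd_a,n_a Group A mean, SD and size.
#' @param mean_b,sd_b,n_b Group B mean, SD and size.
#' @inheritParams welch_t
#' @return List with `t`, `df`, `p`, `tails`.
#' @export
welch_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                            tails = c("two", "one")) {
  welch_core(mean_a, sd_a, n_a, mean_b, sd_b, n_b, tails)
}

#' Cohen's d effect size from group means and SDs
#'
#' `d = (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)`: the mean
#' difference standardized by the root-mean-square of the two group SDs.
#'
#' @param mean_a,sd_a Group A mean and SD.
#' @param mean_b,sd_b Group B mean and SD.
#' @return Cohen's d (signed; antisymmetric under group swap).
#' @examples
#' cohens_d(62.73, 7.34, 28.07, 6.85)  # ~4.88
#' @export
cohens_d <- function(mean_a, sd_a, mean_b, sd_b) {
  if (any(c(sd_a, sd_b) < 0)) stop_bad("standard deviations must be >= 0")
  if (sd_a == 0 && sd_b == 0)
    stop_bad("Cohen's d undefined when both SDs are 0")
  (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2)
}

#' Two-sample t-test power for a given effect size
#'
#' Power of the two-sided two-sample t test at significance `alpha`
#' against a standardized effect `d`, via the noncentral t distribution
#' with noncentrality `d * sqrt(n_a * n_b / (n_a + n_b))` and
#' `n_a + n_b - 2` degrees of freedom.
#'
#' @param d Cohen's d effect size.
#' @param n_a,n_b Group sizes (>= 2).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\]; equals `alpha` at `d = 0`.
#' @export
power_estimate <- function(d, n_a, n_b, alpha = 0.05) {
  if (!is.finite(d)) stop_bad("d must be finite")
  if (n_a < 2 || n_b < 2) stop_bad("group sizes must be >= 2")
  df <- n_a + n_b - 2
  ncp <- d * sqrt(n_a * n_b / (n_a + n_b))
  tcrit <- stats::qt(1 - alpha / 2, df)
  # pt() warns about its last digits for large noncentrality; power is
  # saturated at 1 there and the warning is immaterial
  withCallingHandlers(
    (1 - stats::pt(tcrit, df, ncp)) + stats::pt(-tcrit, df, ncp),
    warning = function(w) {
      if (grepl("full precision", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Multiplier cut-off lines for a binary %-classified comparison
#'
#' The multiplier is `M = (mean_a - mean_b) / (sd_a + sd_b)` where group
#' A is the higher-scoring group.  The group A cut-off line is
#' `mean_a - M * sd_a` and the group B line is `mean_b + M * sd_b`; when
#' M is computed from these same statistics the two lines coincide
#' algebraically.  For a randomization control the *true-pathology*
#' multiplier is reused (`multiplier` supplied), which typically yields
#' two crossed, independent lines.
#'
#' @param mean_a,sd_a Group A (higher) mean and SD of % classified peaks.
#' @param mean_b,sd_b Group B mean and SD.
#' @param multiplier Optional externally supplied multiplier; when `NULL`
#'   (default) it is computed from the four summary statistics, and
#'   `mean_a >= mean_b` is required.
#' @return List with `multiplier`, `cutoff_a`, `cutoff_b`.
#' @examples
#' cutoff_lines(63.67, 5.01, 37.29, 5.86)  # M ~ 2.43, coincident lines
#' @export
cutoff_lines <- function(mean_a, sd_a, mean_b, sd_b, multiplier = NULL) {
  if (any(c(sd_a, sd_b) < 0)) stop_bad("standard deviations must be >= 0")
  if (sd_a + sd_b == 0) stop_bad("sd_a + sd_b must be > 0")
  if (is.null(multiplier)) {
    if (mean_a < mean_b)
      stop_bad("by convention group A is the higher-mean group")
    multiplier <- (mean_a - mean_b) / (sd_a + sd_b)
  }
  list(multiplier = multiplier,
       cutoff_a = mean_a - multiplier * sd_a,
       cutoff_b = mean_b + multiplier * sd_b)
}

#' Confusion counts and test metrics from classifications and cut-offs
#'
#' A group A ("disease") sample counts as a true positive when its
#' `pct_a` is at or above the group A cut-off line, and as a false
#' negative when it is at or below the group B line; a group B sample
#' counts as a true negative at or below the B line and a false positive
#' at or above the A line.  When the two lines are strictly crossed
#' (`cutoff_a < cutoff_b`, the randomized regime) a sample lying between
#' them counts in both of its categories at once; with coincident or
#' separated lines each sample counts at most once, and a sample exactly
#' on a coincident line counts as correctly classified.
#'
#' @param cls A `sample_classifications` data frame.
#' @param cutoff_a,cutoff_b Cut-off lines from [cutoff_lines()].
#' @param label_a The "positive"/disease group label.
#' @return List of class `confusion_metrics`: `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `efficiency` (metrics
#'   are `NA` when their denominator is 0).
#' @export
confusion_metrics <- function(cls, cutoff_a, cutoff_b, label_a) {
  stopifnot(is.finite(cutoff_a), is.finite(cutoff_b))
  is_a <- cls$true_group == label_a
  pa <- cls$pct_a[is_a]; pb <- cls$pct_a[!is_a]
  crossed <- cutoff_a < cutoff_b
  tp_i <- pa >= cutoff_a
  fn_i <- pa <= cutoff_b
  fp_i <- pb >= cutoff_a
  tn_i <- pb <= cutoff_b
  if (!crossed) {         # on a coincident line: count once, as correct
    fn_i <- fn_i & !tp_i
    fp_i <- fp_i & !tn_i
  }
  tp <- sum(tp_i); fn <- sum(fn_i); tn <- sum(tn_i); fp <- sum(fp_i)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp),
         ppv = rate(tp, tp + fp),
         npv = rate(tn, tn + fn),
         efficiency = rate(tp + tn, tp + tn + fp + fn)),
    class = "confusion_metrics")
}

#' Summarize a binary LOOCV comparison
#'
#' Distribution-level statistics on the % classified values: group means
#' and SDs, Welch t / degrees of freedom / p, Cohen's d, noncentral-t
#' power, multiplier cut-off lines (self-computed, or reusing a supplied
#' true-pathology multiplier), and the resulting confusion metrics.
#'
#' @param cls A `sample_classifications` data frame.
#' @param label_a,label_b Group labels; default to the attributes stored
#'   by [run_loocv()].
#' @param multiplier Optional multiplier to reuse (randomization control).
#' @param tails Tails for the distribution-level Welch test (default
#'   two-tailed).
#' @param alpha Significance level used for the power calculation.
#' @return List of class `group_comparison` with fields `label_a`,
#'   `label_b`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `t_stat`, `df`, `p_value`, `tails`, `effect_d`, `power`,
#'   `multiplier`, `cutoff_a`, `cutoff_b` and the confusion counts and
#'   rates of [confusion_metrics()].
#' @export
summarize_comparison <- function(cls, label_a = NULL, label_b = NULL,
                                 multiplier = NULL,
                                 tails = c("two", "one"), alpha = 0.05) {
  tails <- match.arg(tails)
  label_a <- label_a %||% attr(cls, "label_a")
  label_b <- label_b %||% attr(cls, "label_b")
  if (is.null(label_a) || is.null(label_b))
    stop_bad("group labels are required")
  pa <- cls$pct_a[cls$true_group == label_a]
  pb <- cls$pct_a[cls$true_group == label_b]
  if (length(pa) < 2 || length(pb) < 2)
    stop_bad("each group needs >= 2 classified samples")
  w <- welch_t(pa, pb, tails)
  stats_ab <- c(mean(pa), stats::sd(pa), mean(pb), stats::sd(pb))
  cut <- cutoff_lines(stats_ab[1], stats_ab[2], stats_ab[3], stats_ab[4],
                      multiplier = multiplier)
  cm <- confusion_metrics(cls, cut$cutoff_a, cut$cutoff_b, label_a)
  structure(
    c(list(label_a = label_a, label_b = label_b,
           mean_a = stats_ab[1], sd_a = stats_ab[2], n_a = length(pa),
           mean_b = stats_ab[3], sd_b = stats_ab[4], n_b = length(pb),
           t_stat = w$t, df = w$df, p_value = w$p, tails = w$tails,
           effect_d = cohens_d(stats_ab[1], stats_ab[2],
                               stats_ab[3], stats_ab[4]),
           power = power_estimate(
             cohens_d(stats_ab[1], stats_ab[2], stats_ab[3], stats_ab[4]),
             length(pa), length(pb), alpha),
           multiplier = cut$multiplier,
           cutoff_a = cut$cutoff_a, cutoff_b = cut$cutoff_b),
      unclass(cm)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s vs %s\n", x$label_a, x$label_b))
  cat(sprintf("  %% classified: %.2f (SD %.2f, n=%d) vs %.2f (SD %.2f, n=%d)\n",
              x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  Welch t = %.3f, df = %.1f, p (%s-tailed) = %.3g\n",
              x$t_stat, x$df, x$tails, x$p_value))
  cat(sprintf("  Cohen's d = %.2f, power = %.3f\n", x$effect_d, x$power))
  cat(sprintf("  multiplier M = %.3f, cut-offs A %.2f / B %.2f\n",
              x$multiplier, x$cutoff_a, x$cutoff_b))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d  sens %.2f  spec %.2f  eff %.2f\n",
              x$tp, x$fn, x$tn, x$fp, x$sensitivity, x$specificity,
              x$efficiency))
  invisible(x)
}
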