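#' Blinded left-out assignment within a cohort
#'
#' Removes the `blind_ids` samples, runs LOOCV on the remaining training
#' cohort, and classifies each blind sample once against the training
#' cohort's full PCV set.  Blind samples carry no group assumption in any
#' metric; their `true_group` is reported as recorded in the cohort
#' metadata for bookkeeping only.
#'
#' @param x A `cohort`.
#' @param blind_ids Sample ids to blind (subset of the cohort; removing
#'   them must leave >= 2 samples per group).
#' @param alpha,floor_fraction Peak-selection parameters.
#' @return List with `training` (a `sample_classifications` data frame
#'   from LOOCV on the remainder), `blind` (classifications of the blind
#'   samples against the full training PCV set; empty when `blind_ids`
#'   is empty), and `pcvs` (the training PCV set).
#' @export
leave_out_blind <- function(x, blind_ids, alpha = 0.05,
                            floor_fraction = 0.003) {
  stopifnot(inherits(x, "cohort"))
  blind_ids <- as.character(blind_ids)
  if (!all(blind_ids %in% x$metadata$sample_id))
    stop_bad("blind ids not all present in the cohort")
  training <- if (length(blind_ids)) cohort_subset(x, blind_ids, drop = TRUE)
              else x
  counts <- table(factor(training$metadata$group,
                         levels = c(x$label_a, x$label_b)))
  if (any(counts < 2))
    stop_bad("blind set leaves a group with < 2 training samples")
  training_cls <- run_loocv(training, alpha, floor_fraction)
  pcvs <- build_full_pcv_set(training, alpha, floor_fraction)
  blind_cls <- if (length(blind_ids)) {
    rows <- lapply(blind_ids, function(id)
      classify_sample(cohort_areas(x, id), pcvs,
                      true_group = x$metadata$group[
                        match(id, x$metadata$sample_id)]))
    do.call(rbind, rows)
  } else {
    training_cls[0, ]
  }
  list(training = training_cls, blind = blind_cls, pcvs = pcvs)
}

#' Assign external samples against a fixed PCV set and cut-off lines
#'
#' Scores each external sample (e.g. an unrelated patient cohort measured
#' and preprocessed identically) against the full-cohort PCV set of an
#' existing binary comparison, and tallies how many fall on the group A
#' side, the group B side, or between/outside the lines (indeterminate,
#' mirroring the dual-classification zone of crossed cut-offs).  The PCV
#' set is never modified.
#'
#' @param samples List of `peak_areas` for the external samples.
#' @param pcvs A full-cohort `pcv_set`.
#' @param cutoff_a,cutoff_b Cut-off lines of the binary comparison.
#' @return List with `assignments` (data frame `sample_id`, `pct_a`,
#'   `pct_b`, `side` in `c("A", "B", "indeterminate")`) and `tally`
#'   (named counts `a_side`, `b_side`, `indeterminate`; they sum to the
#'   number of external samples).
#' @export
assign_external <- function(samples, pcvs, cutoff_a, cutoff_b) {
  stopifnot(inherits(pcvs, "pcv_set"))
  if (!nrow(pcvs)) stop_bad("empty PCV set")
  for (s in samples) {
    lo <- attr(s, "mz_lo"); hi <- attr(s, "mz_hi")
    if (!is.null(lo) && !is.null(hi) && (min(pcvs$mz) < lo || max(pcvs$mz) > hi))
      stop_bad("grid mismatch: PCV peaks outside external sample m/z range")
  }
  rows <- lapply(samples, classify_sample, pcvs = pcvs)
  df <- do.call(rbind, rows)
  above_a <- df$pct_a >= cutoff_a
  below_b <- df$pct_a <= cutoff_b
  df$side <- ifelse(above_a & !below_b, "A",
                    ifelse(below_b & !above_a, "B", "indeterminate"))
  tally <- c(a_side = sum(df$side == "A"),
             b_side = sum(df$side == "B"),
             indeterminate = sum(df$side == "indeterminate"))
  list(assignments = df[, c("sample_id", "pct_a", "pct_b", "side")],
       tally = tally)
}
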