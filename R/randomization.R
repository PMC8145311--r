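#' Demographically balanced label permutation
#'
#' Shuffles group labels among samples *within strata* defined by sex
#' crossed with cohort-wide age tertiles, so the permuted grouping keeps
#' the original group sizes exactly and the original sex and age
#' composition of each group to within the stratum resolution.  This is a
#' reproducible surrogate for manually balancing a random relabeling by
#' gender and age.  When any sex-by-age stratum is too small to permute
#' (fewer than 2 samples) the strata are relaxed to sex only, and, if
#' still degenerate, to a single stratum; each relaxation raises a
#' warning.
#'
#' @param x A `cohort`.
#' @param seed Integer seed; the plan is deterministic given the seed.
#' @return A `randomization_plan`: list with `seed`, `strata` (per-sample
#'   stratum labels), and `assignment`, a data frame `sample_id`,
#'   `original_group`, `randomized_group`.
#' @export
balanced_permutation <- function(x, seed) {
  stopifnot(inherits(x, "cohort"))
  md <- x$metadata
  age_cut <- stats::quantile(md$age, c(1 / 3, 2 / 3), names = FALSE)
  tertile <- findInterval(md$age, age_cut, left.open = TRUE) + 1L
  strata <- paste(md$sex, tertile, sep = ".")
  if (min(table(strata)) < 2L) {
    warning("sex-by-age strata too small to permute; relaxing to sex-only strata",
            call. = FALSE)
    strata <- md$sex
    if (min(table(strata)) < 2L) {
      warning("sex strata too small to permute; using a single stratum",
              call. = FALSE)
      strata <- rep("all", nrow(md))
    }
  }
  randomized <- md$group
  with_seed(seed, {
    for (s in unique(strata)) {
      idx <- which(strata == s)
      randomized[idx] <- randomized[sample(idx)]
    }
  })
  structure(
    list(seed = as.integer(seed), strata = strata,
         assignment = data.frame(sample_id = md$sample_id,
                                 original_group = md$group,
                                 randomized_group = randomized,
                                 row.names = NULL)),
    class = "randomization_plan")
}

#' @export
print.randomization_plan <- function(x, ...) {
  moved <- sum(x$assignment$original_group != x$assignment$randomized_group)
  cat(sprintf("<randomization_plan> seed %d, %d samples, %d relabeled, %d strata\n",
              x$seed, nrow(x$assignment), moved, length(unique(x$strata))))
  invisible(x)
}

#' Apply a randomization plan to a cohort
#'
#' @param x A `cohort`.
#' @param plan A `randomization_plan` built for this cohort.
#' @return A `cohort` with the permuted group labels.
#' @export
apply_plan <- function(x, plan) {
  stopifnot(inherits(x, "cohort"), inherits(plan, "randomization_plan"))
  idx <- match(x$metadata$sample_id, plan$assignment$sample_id)
  if (anyNA(idx)) stop_bad("plan does not cover all cohort samples")
  md <- x$metadata
  md$group <- plan$assignment$randomized_group[idx]
  cohort(md, x$areas, x$label_a, x$label_b)
}

# Fold peak selection with the significant-peak count forced to a target:
# all m/z are ranked by ascending one-tailed p (ties broken by m/z), the
# abundance floor still applies, and the top `n_target` peaks are kept --
# relaxing the alpha threshold beyond its nominal value when fewer than
# `n_target` peaks are nominally significant.
select_top_peaks <- function(x, n_target, floor_fraction = 0.003) {
  sw <- peak_welch_sweep(x$areas, group_rows(x, x$label_a),
                         group_rows(x, x$label_b))
  floor_base <- max(pmax(sw$mean_a, sw$mean_b), 0)
  eligible <- !sw$degenerate &
    pmax(sw$mean_a, sw$mean_b) >= floor_fraction * floor_base
  idx <- which(eligible)
  o <- idx[order(sw$p_one[idx], x$mz[idx])]
  if (length(o) < n_target) {
    warning("only ", length(o), " eligible peaks for a target of ", n_target,
            call. = FALSE)
  } else {
    o <- o[seq_len(n_target)]
  }
  df <- data.frame(
    mz = x$mz[o],
    p_value = sw$p_one[o],
    mean_a = sw$mean_a[o],
    mean_b = sw$mean_b[o],
    direction = ifelse(sw$mean_a[o] > sw$mean_b[o], x$label_a,
                       ifelse(sw$mean_a[o] < sw$mean_b[o], x$label_b,
                              x$label_a)),
    pcv = (sw$mean_a[o] + sw$mean_b[o]) / 2,
    row.names = NULL)
  new_pcv_set(df, x$metadata$sample_id, x$label_a, x$label_b,
              NA_real_, floor_fraction)
}

#' LOOCV on a randomized relabeling (overfitting control)
#'
#' Runs the identical leave-one-out procedure on the relabeled cohort,
#' except that each fold's peak set is truncated or extended to exactly
#' the number of significant peaks the *true-pathology* run selected
#' (ranked by ascending p, relaxing the significance threshold when
#' needed), and the cut-off lines reuse the true-pathology multiplier.
#' A randomized run of a genuinely discriminating comparison should lose
#' significance by many orders of magnitude; failure to do so indicates
#' overfitting.
#'
#' @param x A `cohort` (original labels).
#' @param plan A `randomization_plan` for `x`.
#' @param n_peaks_target Per-fold significant-peak count from the
#'   true-pathology run (a single integer, e.g. the rounded mean of the
#'   true run's `fold_peaks` attribute; must be >= 1).
#' @param multiplier The true-pathology multiplier, reused for the
#'   randomized cut-off lines.
#' @param floor_fraction Relative abundance floor (as in the true run).
#' @param tails Tails for the distribution-level Welch test.
#' @return List with `classifications` (a `sample_classifications` data
#'   frame under the randomized labels) and `stats` (a
#'   `group_comparison`).
#' @export
run_randomized_loocv <- function(x, plan, n_peaks_target, multiplier,
                                 floor_fraction = 0.003,
                                 tails = c("two", "one")) {
  n_peaks_target <- as.integer(n_peaks_target)
  if (is.na(n_peaks_target) || n_peaks_target < 1L)
    stop_bad("n_peaks_target must be >= 1")
  relabeled <- apply_plan(x, plan)
  cls <- run_loocv(relabeled,
                   fold_peaks_fn = function(co)
                     select_top_peaks(co, n_peaks_target, floor_fraction))
  stats <- summarize_comparison(cls, multiplier = multiplier, tails = tails)
  list(classifications = cls, stats = stats)
}

#' True-pathology run plus a matched randomization control
#'
#' Convenience wrapper: runs LOOCV on the true labels, builds a balanced
#' label permutation, and reruns LOOCV on the relabeled cohort with the
#' peak count matched to the true run's median fold count and the true
#' multiplier reused.
#'
#' @param x A `cohort`.
#' @param seed Seed for the label permutation.
#' @param alpha,floor_fraction Peak-selection parameters.
#' @param tails Tails for the distribution-level Welch tests.
#' @return List with `true` (classifications, stats), `plan`, and
#'   `randomized` (classifications, stats).
#' @export
randomization_control <- function(x, seed, alpha = 0.05,
                                  floor_fraction = 0.003,
                                  tails = c("two", "one")) {
  tails <- match.arg(tails)
  cls_true <- run_loocv(x, alpha, floor_fraction)
  stats_true <- summarize_comparison(cls_true, tails = tails)
  plan <- balanced_permutation(x, seed)
  n_target <- max(1L, as.integer(round(
    stats::median(attr(cls_true, "fold_peaks")))))
  rand <- run_randomized_loocv(x, plan, n_target, stats_true$multiplier,
                               floor_fraction, tails)
  list(true = list(classifications = cls_true, stats = stats_true),
       plan = plan, randomized = rand)
}

#' Write a randomization plan as TSV
#' @param plan A `randomization_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  utils::write.table(plan$assignment, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
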