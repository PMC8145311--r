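#' Run the full profiling pipeline from a configuration
#'
#' Orchestrates an end-to-end run -- spectra (from files or a simulation
#' preset), preprocessing, LOOCV/PCV classification, distribution-level
#' test metrics with multiplier cut-off lines, an optional balanced
#' randomization control and an optional blinded subset -- and writes all
#' artifacts to an output directory.
#'
#' The configuration is a YAML file (or an equivalent named list) with:
#' \preformatted{
#' cohort:
#'   preset: mildAD_vs_control_iontrap   # either a simulation preset...
#'   seed: 7
#'   # ...or spectra/metadata files:
#'   # spectra: path/to/spectra.tsv      # wide or long dialect, or .mzML
#'   # metadata: path/to/metadata.tsv    # sample_id group sex age
#'   # label_a: mildAD
#'   # label_b: control
#' alpha: 0.05            # peak-level one-tailed significance
#' floor_fraction: 0.003  # relative abundance floor
#' tails: two             # distribution-level Welch test
#' randomize:
#'   enabled: true
#'   seed: 7
#' blind_ids: []          # optional blinded subset
#' plot: true             # Fig-style scatter of % classified
#' }
#'
#' @param config Path to a YAML configuration file, or a named list.
#' @param out_dir Output directory (created if needed; defaults to
#'   `config$out_dir`, which must then be set).
#' @return The output directory path, invisibly.  Files written:
#'   `peak_matrix.tsv`, `pcv_full.tsv`, `classifications.tsv`,
#'   `fold_peaks.tsv`, `stats.json`, and, when requested,
#'   `randomization_plan.tsv`, `random_classifications.tsv`,
#'   `random_stats.json`, `blind_classifications.tsv`,
#'   `pct_classified.pdf`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg) || is.null(cfg$cohort))
    stop_bad("malformed config: a 'cohort' section is required")
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop_bad("malformed config: no output directory")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  alpha <- cfg$alpha %||% 0.05
  floor_fraction <- cfg$floor_fraction %||% 0.003
  tails <- cfg$tails %||% "two"

  co <- pipeline_cohort(cfg$cohort)
  write_peak_matrix(co$areas, file.path(out_dir, "peak_matrix.tsv"))

  pcv_full <- build_full_pcv_set(co, alpha, floor_fraction)
  write_pcv_set(pcv_full, file.path(out_dir, "pcv_full.tsv"))

  cls <- run_loocv(co, alpha, floor_fraction)
  write_classifications(cls, file.path(out_dir, "classifications.tsv"))
  utils::write.table(
    data.frame(sample_left_out = cls$sample_id,
               n_significant_peaks = attr(cls, "fold_peaks")),
    file.path(out_dir, "fold_peaks.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  stats <- summarize_comparison(cls, tails = tails, alpha = alpha)
  jsonlite::write_json(unclass(stats), file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(cfg$randomize$enabled)) {
    seed <- cfg$randomize$seed %||% cfg$cohort$seed %||% 1L
    plan <- balanced_permutation(co, seed)
    write_plan(plan, file.path(out_dir, "randomization_plan.tsv"))
    n_target <- max(1L, as.integer(round(
      stats::median(attr(cls, "fold_peaks")))))
    rand <- run_randomized_loocv(co, plan, n_target, stats$multiplier,
                                 floor_fraction, tails)
    write_classifications(rand$classifications,
                          file.path(out_dir, "random_classifications.tsv"))
    jsonlite::write_json(unclass(rand$stats),
                         file.path(out_dir, "random_stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if (length(cfg$blind_ids)) {
    blind <- leave_out_blind(co, cfg$blind_ids, alpha, floor_fraction)
    write_classifications(blind$blind,
                          file.path(out_dir, "blind_classifications.tsv"))
  }

  if (isTRUE(cfg$plot)) {
    grDevices::pdf(file.path(out_dir, "pct_classified.pdf"),
                   width = 7, height = 5)
    plot_classifications(cls, stats)
    grDevices::dev.off()
  }
  invisible(out_dir)
}

pipeline_cohort <- function(spec) {
  if (!is.null(spec$preset)) {
    sim <- simulate_cohort(preset(spec$preset, seed = spec$seed %||% 1L))
    return(as_cohort(sim))
  }
  if (is.null(spec$spectra) || is.null(spec$metadata))
    stop_bad("malformed config: cohort needs a 'preset' or spectra+metadata files")
  spectra <- if (grepl("\\.mzml$", spec$spectra, ignore.case = TRUE))
    stop_bad("per-sample mzML input requires one call to read_spectra_mzml per sample; supply a TSV here")
  else read_spectra_tsv(spec$spectra)
  metadata <- utils::read.delim(spec$metadata, stringsAsFactors = FALSE)
  build_cohort(spectra, metadata, spec$label_a, spec$label_b)
}

#' Scatter plot of % classified peaks per sample with cut-off lines
#'
#' @param cls A `sample_classifications` data frame.
#' @param stats The matching `group_comparison` (for labels and cut-offs).
#' @return Invisibly, `NULL`.  Draws on the current graphics device.
#' @export
plot_classifications <- function(cls, stats) {
  is_a <- cls$true_group == stats$label_a
  n <- nrow(cls)
  graphics::plot(seq_len(n), cls$pct_a,
                 pch = ifelse(is_a, 17, 45), cex = ifelse(is_a, 1.2, 1.8),
                 xlab = "sample", ylab = paste0("% peaks classified ",
                                                stats$label_a),
                 ylim = c(0, 100),
                 main = sprintf("%s vs %s (p = %.3g)", stats$label_a,
                                stats$label_b, stats$p_value))
  graphics::abline(h = stats$cutoff_a, lty = 1)
  graphics::abline(h = stats$cutoff_b, lty = 2)
  invisible(NULL)
}
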