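#' Phenotype annotation legend for the packaged hit tables
#'
#' Named character vector mapping annotation codes 1..7 to phenotype
#' category labels (dementia/amyloidosis, inflammation, neurogenesis,
#' ion channels, brain injury/blood-brain barrier, vasculature,
#' neuronal cell death).
#'
#' @return Named character vector of length 7.
#' @export
phenotype_legend <- function() {
  c(`1` = "Alzheimer's disease/dementia/amyloidosis",
    `2` = "inflammation/neuroinflammation",
    `3` = "neurogenesis",
    `4` = "ion channels",
    `5` = "brain injury/CNS trauma/blood-brain barrier",
    `6` = "vasculature",
    `7` = "neuronal cell death")
}

validate_hit_table <- function(df, n_per_group = 8L) {
  req <- c("symbol", "sera_a", "hits_a", "sera_b", "hits_b")
  if (!all(req %in% names(df)))
    stop_bad("hit table needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(df$symbol))
    stop_bad("duplicate symbols in hit table: ",
             paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
  num <- c("sera_a", "hits_a", "sera_b", "hits_b")
  for (col in num) {
    v <- df[[col]]
    if (anyNA(v) || any(v < 0) || any(v != round(v)))
      stop_bad(col, " must be non-negative integers")
  }
  if (any(df$sera_a > n_per_group) || any(df$sera_b > n_per_group))
    stop_bad("positive-sera counts exceed n_per_group = ", n_per_group)
  if (any(df$sera_a > 0 & df$hits_a == 0) ||
      any(df$sera_b > 0 & df$hits_b == 0))
    stop_bad("positive sera with zero hits is inconsistent")
  if (is.null(df$annotations)) df$annotations <- ""
  df$annotations <- ifelse(is.na(df$annotations), "", df$annotations)
  codes <- unlist(strsplit(df$annotations[df$annotations != ""], ","))
  if (length(codes) && !all(trimws(codes) %in% names(phenotype_legend())))
    stop_bad("unknown phenotype annotation code(s): ",
             paste(setdiff(trimws(codes), names(phenotype_legend())),
                   collapse = ", "))
  df
}

#' Read a tandem-MS hit table
#'
#' Tab-separated with columns `symbol`, `sera_a`, `hits_a`, `sera_b`,
#' `hits_b` and optional `annotations` (comma-separated phenotype codes
#' 1..7, see [phenotype_legend()]).  `sera_*` is the number of positive
#' subject sera in a group (0..`n_per_group`); `hits_*` the total MS/MS
#' spectral-count hits.
#'
#' @param path Path to the TSV.
#' @param n_per_group Sera per group (default 8).
#' @return A validated `hit_table` data frame.
#' @export
read_hit_table <- function(path, n_per_group = 8L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
  df <- validate_hit_table(df, n_per_group)
  structure(df, n_per_group = as.integer(n_per_group),
            class = c("hit_table", "data.frame"))
}

#' Packaged serum peptidome hit tables (mild AD vs control)
#'
#' Loads the two packaged hit tables for the published mild-AD-versus-
#' control tandem-MS comparison: 90 peptides/proteins elevated in mild AD
#' sera and 64 elevated in control sera (154 entries in total, 8 sera per
#' group).  Both are stored with group A = mild AD and group B = control.
#'
#' @param which `"mild_ad_up"`, `"control_up"`, or `"both"` (row-bound).
#' @return A `hit_table` data frame.
#' @export
hit_table_fixture <- function(which = c("both", "mild_ad_up", "control_up")) {
  which <- match.arg(which)
  path <- function(f) system.file("extdata", f, package = "seroclass",
                                  mustWork = TRUE)
  up <- read_hit_table(path("hits_mild_ad_up.tsv"))
  dn <- read_hit_table(path("hits_control_up.tsv"))
  switch(which,
         mild_ad_up = up,
         control_up = dn,
         both = structure(rbind(as.data.frame(up), as.data.frame(dn)),
                          n_per_group = 8L,
                          class = c("hit_table", "data.frame")))
}

#' Filter hit-table entries by sera and hit fold changes
#'
#' An entry passes in the A-over-B direction iff its group A positive-sera
#' count reaches `min_sera`, its sera ratio `sera_a / sera_b` reaches
#' `sera_fold` (a zero group B sera count passes automatically), and its
#' hit ratio `hits_a / hits_b`, rounded half-up to one decimal, reaches
#' `hit_fold` (a zero group B hit count passes automatically).  The
#' B-over-A direction mirrors this.  Entries passing neither direction
#' are dropped.  The filter is idempotent and symmetric under swapping
#' the two groups' columns.
#'
#' @param entries A `hit_table` data frame.
#' @param min_sera Minimum positive sera in the elevated group (default 3).
#' @param sera_fold Minimum sera-count fold difference (default 2).
#' @param hit_fold Minimum hit-count fold difference after one-decimal
#'   rounding (default 1.5).
#' @return List with `a_over_b` and `b_over_a` `hit_table` data frames.
#' @export
filter_entries <- function(entries, min_sera = 3L, sera_fold = 2,
                           hit_fold = 1.5) {
  stopifnot(all(c(min_sera, sera_fold, hit_fold) > 0))
  passes <- function(sera_hi, hits_hi, sera_lo, hits_lo) {
    sera_hi >= min_sera &
      (sera_lo == 0 | sera_hi / sera_lo >= sera_fold) &
      (hits_lo == 0 | round_half_up(hits_hi / hits_lo, 1) >= hit_fold)
  }
  a <- passes(entries$sera_a, entries$hits_a, entries$sera_b, entries$hits_b)
  b <- passes(entries$sera_b, entries$hits_b, entries$sera_a, entries$hits_a)
  keep_tbl <- function(i) {
    structure(as.data.frame(entries)[i, , drop = FALSE],
              n_per_group = attr(entries, "n_per_group"),
              class = c("hit_table", "data.frame"))
  }
  list(a_over_b = keep_tbl(a), b_over_a = keep_tbl(b))
}

#' Log2 hit-ratio table for pathway-analysis import
#'
#' `log2((hits_a + pseudocount) / (hits_b + pseudocount))` per entry; the
#' pseudocount keeps zero-hit groups finite.
#'
#' @param entries A `hit_table` data frame.
#' @param pseudocount Positive pseudocount added to both groups (default 1).
#' @return Data frame `symbol`, `log2_ratio`.
#' @export
log2_ratio_table <- function(entries, pseudocount = 1) {
  if (!is.finite(pseudocount) || pseudocount <= 0)
    stop_bad("pseudocount must be > 0")
  data.frame(symbol = entries$symbol,
             log2_ratio = log2((entries$hits_a + pseudocount) /
                               (entries$hits_b + pseudocount)),
             row.names = NULL)
}

#' Write a pathway-analysis-ready log2 ratio table
#' @param entries A `hit_table`.
#' @param path Output path.
#' @param pseudocount Passed to [log2_ratio_table()].
#' @return `path`, invisibly.
#' @export
write_ipa_table <- function(entries, path, pseudocount = 1) {
  utils::write.table(log2_ratio_table(entries, pseudocount), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

entry_codes <- function(entries) {
  ann <- entries$annotations %||% rep("", nrow(entries))
  ann <- ifelse(is.na(ann), "", ann)
  lapply(strsplit(ann, ","), trimws)
}

#' Tally phenotype annotations across hit-table entries
#'
#' Counts, per phenotype category, the entries carrying that annotation
#' code (a multi-annotated entry counts in every one of its categories)
#' and reports the percentage of all entries, rounded half-up to an
#' integer.
#'
#' @param entries A `hit_table` data frame.
#' @param categories Codes to tally (default all of [phenotype_legend()]).
#' @return Data frame `code`, `label`, `count`, `percent`.
#' @export
phenotype_tally <- function(entries, categories = names(phenotype_legend())) {
  legend <- phenotype_legend()
  categories <- as.character(categories)
  if (!all(categories %in% names(legend)))
    stop_bad("unknown phenotype code(s): ",
             paste(setdiff(categories, names(legend)), collapse = ", "))
  codes <- entry_codes(entries)
  bad <- setdiff(unique(unlist(codes)), c(names(legend), ""))
  if (length(bad))
    stop_bad("unknown phenotype annotation code(s): ",
             paste(bad, collapse = ", "))
  n <- nrow(entries)
  counts <- vapply(categories,
                   function(cc) sum(vapply(codes, function(v) cc %in% v,
                                           logical(1))),
                   integer(1))
  data.frame(code = as.integer(categories),
             label = unname(legend[categories]),
             count = unname(counts),
             percent = if (n > 0) round_half_up(100 * unname(counts) / n)
                       else rep(0, length(counts)),
             row.names = NULL)
}
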