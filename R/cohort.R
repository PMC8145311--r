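#' Construct a binary-comparison cohort
#'
#' A cohort bundles per-sample averaged peak areas with sample metadata
#' (group label, sex, age) for one binary comparison, e.g. mild AD versus
#' control.  Areas are held as a dense matrix (rows = samples, columns =
#' the union of observed unit m/z; absence of a peak is an informative
#' zero in locally normalized spectra).
#'
#' @param metadata Data frame with columns `sample_id`, `group`, `sex`
#'   (`"M"`/`"F"`), `age` (years, > 0).
#' @param areas Either a list of `peak_areas` (one per metadata row, in
#'   any order, matched by sample id) or a numeric matrix with sample-id
#'   row names and unit-m/z column names.
#' @param label_a,label_b The two group labels.  By convention `label_a`
#'   is the condition of interest (plotted/scored as the "positive"
#'   group).  Defaults to the first two distinct values of
#'   `metadata$group` in order of appearance.
#' @return An object of class `cohort` with elements `label_a`,
#'   `label_b`, `metadata`, `areas` (matrix) and `mz` (integer keys).
#' @export
cohort <- function(metadata, areas, label_a = NULL, label_b = NULL) {
  req <- c("sample_id", "group", "sex", "age")
  if (!all(req %in% names(metadata)))
    stop_bad("metadata needs columns: ", paste(req, collapse = ", "))
  metadata$sample_id <- as.character(metadata$sample_id)
  metadata$group <- as.character(metadata$group)
  if (anyDuplicated(metadata$sample_id)) stop_bad("duplicate sample ids")
  if (any(!is.finite(metadata$age) | metadata$age <= 0))
    stop_bad("ages must be positive")
  labs <- unique(metadata$group)
  label_a <- label_a %||% labs[1L]
  label_b <- label_b %||% setdiff(labs, label_a)[1L]
  if (is.na(label_b) || label_a == label_b)
    stop_bad("cohort needs two distinct group labels")
  if (!all(metadata$group %in% c(label_a, label_b)))
    stop_bad("metadata groups outside {", label_a, ", ", label_b, "}")
  if (is.matrix(areas)) {
    m <- areas
    if (is.null(rownames(m))) stop_bad("area matrix needs sample-id row names")
  } else {
    m <- peak_matrix(areas)
  }
  if (!setequal(rownames(m), metadata$sample_id))
    stop_bad("area sample ids do not match metadata sample ids")
  m <- m[metadata$sample_id, , drop = FALSE]
  mz <- as.integer(colnames(m))
  o <- order(mz)
  m <- m[, o, drop = FALSE]
  structure(
    list(label_a = label_a, label_b = label_b,
         metadata = metadata[, req], areas = m, mz = mz[o]),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  na <- sum(x$metadata$group == x$label_a)
  nb <- sum(x$metadata$group == x$label_b)
  cat(sprintf("<cohort> %s (n=%d) vs %s (n=%d), %d m/z peaks\n",
              x$label_a, na, x$label_b, nb, length(x$mz)))
  invisible(x)
}

#' Build a cohort from raw replicate spectra and metadata
#'
#' Groups spectra by sample id, preprocesses each sample (segment
#' normalization, valley-to-valley centroiding, replicate averaging) and
#' assembles the cohort.
#'
#' @param spectra List of `replicate_spectrum` objects.
#' @param metadata Metadata data frame (see [cohort()]).
#' @param label_a,label_b Group labels (see [cohort()]).
#' @param segment_width,target_sum Passed to [segment_normalize()].
#' @return A `cohort`.
#' @export
build_cohort <- function(spectra, metadata, label_a = NULL, label_b = NULL,
                         segment_width = 25L, target_sum = 100) {
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  areas <- lapply(split(spectra, ids),
                  preprocess_sample,
                  segment_width = segment_width, target_sum = target_sum)
  cohort(metadata, unname(areas), label_a, label_b)
}

#' Subset a cohort by sample ids
#'
#' @param x A `cohort`.
#' @param ids Sample ids to keep (or drop when `drop = TRUE`).
#' @param drop If `TRUE`, `ids` are removed instead of kept.
#' @return A `cohort` restricted to the requested samples (peak columns
#'   are kept as-is; downstream selection treats all-zero columns as
#'   absent peaks).
#' @export
cohort_subset <- function(x, ids, drop = FALSE) {
  stopifnot(inherits(x, "cohort"))
  keep <- if (drop) !(x$metadata$sample_id %in% ids)
          else x$metadata$sample_id %in% ids
  if (!any(keep)) stop_bad("subset leaves no samples")
  cohort(x$metadata[keep, , drop = FALSE],
         x$areas[keep, , drop = FALSE],
         x$label_a, x$label_b)
}

group_rows <- function(x, label) which(x$metadata$group == label)

#' Extract one sample's peak areas from a cohort
#'
#' @param x A `cohort`.
#' @param id Sample id.
#' @return A `peak_areas` object.
#' @export
cohort_areas <- function(x, id) {
  stopifnot(inherits(x, "cohort"))
  i <- match(id, x$metadata$sample_id)
  if (is.na(i)) stop_bad("unknown sample id: ", id)
  a <- x$areas[i, ]
  keep <- a > 0
  lo <- if (length(x$mz)) min(x$mz) else 400L
  hi <- if (length(x$mz)) max(x$mz) else 2000L
  peak_areas(id, x$mz[keep], a[keep], mz_lo = lo, mz_hi = hi)
}
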