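#' Construct a replicate spectrum on the unit-mass grid
#'
#' A replicate spectrum holds one injection's non-negative intensities on
#' an inclusive unit-m/z grid, by default 400--2000 (1601 bins), the range
#' acquired by the ion-trap instrument the platform was designed around.
#'
#' @param sample_id Sample identifier (string).
#' @param replicate Replicate index (integer, conventionally 1..3).
#' @param intensities Numeric vector of non-negative intensities, one per
#'   unit m/z bin, length `mz_hi - mz_lo + 1`.
#' @param mz_lo,mz_hi Integer m/z bounds of the grid (inclusive).
#' @param normalized Logical; whether segment normalization has been applied.
#' @return An object of class `replicate_spectrum`.
#' @seealso [nominal_bin()], [segment_normalize()], [centroid_areas()]
#' @export
replicate_spectrum <- function(sample_id, replicate, intensities,
                               mz_lo = 400L, mz_hi = 2000L,
                               normalized = FALSE) {
  mz_lo <- as.integer(mz_lo); mz_hi <- as.integer(mz_hi)
  if (mz_hi < mz_lo) stop_bad("mz_hi must be >= mz_lo")
  n <- mz_hi - mz_lo + 1L
  intensities <- as.numeric(intensities)
  if (length(intensities) != n)
    stop_bad("intensities must have length ", n, " (one per unit m/z bin)")
  if (anyNA(intensities) || any(intensities < 0))
    stop_bad("intensities must be non-negative and finite")
  structure(
    list(sample_id = as.character(sample_id),
         replicate = as.integer(replicate),
         mz_lo = mz_lo, mz_hi = mz_hi,
         intensities = intensities,
         normalized = isTRUE(normalized)),
    class = "replicate_spectrum")
}

#' @export
print.replicate_spectrum <- function(x, ...) {
  cat(sprintf("<replicate_spectrum> sample %s, replicate %d, m/z %d-%d%s\n",
              x$sample_id, x$replicate, x$mz_lo, x$mz_hi,
              if (x$normalized) ", segment-normalized" else ""))
  cat(sprintf("  total intensity %.4g over %d bins (%d non-zero)\n",
              sum(x$intensities), length(x$intensities),
              sum(x$intensities > 0)))
  invisible(x)
}

#' Mass grid of a spectrum
#' @param spec A `replicate_spectrum`.
#' @return Integer vector of unit m/z values.
#' @export
mz_grid <- function(spec) seq.int(spec$mz_lo, spec$mz_hi)

#' Collapse raw (m/z, intensity) points to nominal unit-mass bins
#'
#' Each acquired point contributes its full intensity to the bin at its
#' half-up-rounded m/z; points rounding outside `[mz_lo, mz_hi]` are
#' dropped.  This reproduces the "nominal mass" export of profile data
#' sampled at fractional m/z resolution.
#'
#' @param mz Numeric vector of m/z values (finite).
#' @param intensity Numeric vector of non-negative intensities, same length.
#' @param sample_id,replicate Identifiers for the resulting spectrum.
#' @param mz_lo,mz_hi Integer grid bounds (inclusive).
#' @return A `replicate_spectrum`.
#' @examples
#' sp <- nominal_bin(c(500.01, 500.49), c(3, 2), "s1", 1)
#' sp$intensities[101]  # bin 500
#' @export
nominal_bin <- function(mz, intensity, sample_id = "sample", replicate = 1L,
                        mz_lo = 400L, mz_hi = 2000L) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity))
    stop_bad("mz and intensity must have the same length")
  if (anyNA(mz) || any(!is.finite(mz)))
    stop_bad("all m/z values must be finite")
  if (anyNA(intensity) || any(intensity < 0))
    stop_bad("intensities must be non-negative")
  n <- as.integer(mz_hi) - as.integer(mz_lo) + 1L
  out <- numeric(n)
  if (length(mz)) {
    idx <- as.integer(round_half_up(mz)) - as.integer(mz_lo) + 1L
    keep <- idx >= 1L & idx <= n
    if (any(keep)) {
      acc <- rowsum(intensity[keep], group = idx[keep])
      out[as.integer(rownames(acc))] <- acc[, 1L]
    }
  }
  replicate_spectrum(sample_id, replicate, out, mz_lo, mz_hi)
}

#' Locally normalize a spectrum in fixed-width m/z segments
#'
#' Scales each non-overlapping segment of `segment_width` unit-m/z bins
#' (starting at the low end of the grid; the final segment may be partial)
#' so that its summed intensity equals `target_sum`.  All-zero segments
#' are left unchanged -- the scale factor is undefined there and leaving
#' zeros preserves mass bookkeeping.  Local scaling removes global
#' intensity drift between injections while preserving within-segment
#' peak shape.
#'
#' @param spec A `replicate_spectrum`.
#' @param segment_width Segment width in unit m/z bins (default 25).
#' @param target_sum Per-segment target intensity sum (default 100).
#' @return A segment-normalized `replicate_spectrum`.  The operation is
#'   idempotent.
#' @export
segment_normalize <- function(spec, segment_width = 25L, target_sum = 100) {
  stopifnot(inherits(spec, "replicate_spectrum"))
  segment_width <- as.integer(segment_width)
  if (is.na(segment_width) || segment_width < 1L)
    stop_bad("segment_width must be a positive integer")
  if (!is.finite(target_sum) || target_sum <= 0)
    stop_bad("target_sum must be positive")
  x <- spec$intensities
  seg <- (seq_along(x) - 1L) %/% segment_width
  sums <- rowsum(x, group = seg)[, 1L]
  scale <- ifelse(sums > 0, target_sum / sums, 1)
  out <- spec
  out$intensities <- unname(x * scale[seg + 1L])
  out$normalized <- TRUE
  out
}

# Valley positions of an intensity vector: every zero bin, plus the
# leftmost bin of any interior run of equal values that is strictly lower
# than both flanking (distinct-valued) runs.
valley_positions <- function(x) {
  n <- length(x)
  v <- which(x == 0)
  r <- rle(x)
  k <- length(r$values)
  if (k >= 3L) {
    starts <- cumsum(c(1L, r$lengths[-k]))
    interior <- 2:(k - 1L)
    is_min <- r$values[interior] > 0 &
      r$values[interior] < r$values[interior - 1L] &
      r$values[interior] < r$values[interior + 1L]
    v <- c(v, starts[interior][is_min])
  }
  sort(unique(v))
}

#' Centroid a spectrum into valley-to-valley peak areas
#'
#' Partitions the unit-mass intensity vector at valleys (zero bins and
#' strict local minima; for an equal-valued plateau minimum the leftmost
#' plateau bin is the valley).  Each maximal run between consecutive
#' valleys with positive total intensity becomes one peak whose area is
#' the summed intensity of the run and whose m/z key is the half-up
#' rounded intensity-weighted mean m/z (the peak's geometric center).
#' A valley bin opens the run to its right, so every bin's intensity is
#' assigned to exactly one run and total area equals total intensity.
#'
#' @param spec A `replicate_spectrum` (typically segment-normalized).
#' @return A `peak_areas` object: a named numeric vector of strictly
#'   positive areas keyed by unit m/z, with `sample_id` and grid
#'   attributes.  Peaks whose centers round to the same unit m/z are
#'   merged by summing areas.
#' @export
centroid_areas <- function(spec) {
  stopifnot(inherits(spec, "replicate_spectrum"))
  x <- spec$intensities
  mz <- mz_grid(spec)
  is_valley <- logical(length(x))
  is_valley[valley_positions(x)] <- TRUE
  run <- cumsum(is_valley)                 # valley bin starts its own run
  tot <- rowsum(x, group = run)[, 1L]
  ctr <- rowsum(x * mz, group = run)[, 1L]
  pos <- tot > 0
  keys <- as.integer(round_half_up(ctr[pos] / tot[pos]))
  areas <- tot[pos]
  if (anyDuplicated(keys)) {
    acc <- rowsum(areas, group = keys)
    keys <- as.integer(rownames(acc)); areas <- acc[, 1L]
  }
  o <- order(keys)
  peak_areas(spec$sample_id, keys[o], areas[o], spec$mz_lo, spec$mz_hi)
}

#' Construct a peak-area vector
#'
#' @param sample_id Sample identifier.
#' @param mz Integer unit m/z keys within the grid.
#' @param areas Strictly positive areas, same length as `mz` (zero-area
#'   peaks are absent, not stored).
#' @param mz_lo,mz_hi Grid bounds the areas were measured on.
#' @return A `peak_areas` object (named numeric vector, sorted by m/z).
#' @export
peak_areas <- function(sample_id, mz, areas, mz_lo = 400L, mz_hi = 2000L) {
  mz <- as.integer(mz); areas <- as.numeric(areas)
  if (length(mz) != length(areas)) stop_bad("mz and areas lengths differ")
  if (any(areas <= 0)) stop_bad("all stored peak areas must be > 0")
  if (anyDuplicated(mz)) stop_bad("duplicate m/z keys")
  if (length(mz) && (min(mz) < mz_lo || max(mz) > mz_hi))
    stop_bad("m/z keys outside [mz_lo, mz_hi]")
  o <- order(mz)
  structure(stats::setNames(areas[o], mz[o]),
            sample_id = as.character(sample_id),
            mz_lo = as.integer(mz_lo), mz_hi = as.integer(mz_hi),
            class = "peak_areas")
}

#' @export
print.peak_areas <- function(x, ...) {
  cat(sprintf("<peak_areas> sample %s: %d peaks, total area %.4g\n",
              attr(x, "sample_id"), length(x), sum(x)))
  invisible(x)
}

#' Average replicate peak-area vectors for one sample
#'
#' The area at each unit m/z is the arithmetic mean over replicates,
#' counting a replicate with no peak at that m/z as zero.  m/z whose mean
#' is zero are omitted.  Any replicate count >= 1 is accepted; a count
#' other than 3 (the platform's triplicate convention) raises a warning.
#'
#' @param reps List of `peak_areas` for the same sample.
#' @return A single averaged `peak_areas`.
#' @export
average_replicates <- function(reps) {
  if (!length(reps)) stop_bad("need at least one replicate")
  stopifnot(all(vapply(reps, inherits, logical(1), "peak_areas")))
  ids <- vapply(reps, attr, character(1), "sample_id")
  if (length(unique(ids)) != 1L)
    stop_bad("replicates mix sample ids: ", paste(unique(ids), collapse = ", "))
  if (length(reps) != 3L)
    warning("averaging ", length(reps), " replicates (platform convention is 3)",
            call. = FALSE)
  keys <- sort(unique(unlist(lapply(reps, function(r) as.integer(names(r))))))
  if (!length(keys))
    return(peak_areas(ids[1L], integer(0), numeric(0),
                      attr(reps[[1L]], "mz_lo"), attr(reps[[1L]], "mz_hi")))
  acc <- numeric(length(keys))
  for (r in reps) {
    idx <- match(as.integer(names(r)), keys)
    acc[idx] <- acc[idx] + as.numeric(r)
  }
  mean_area <- acc / length(reps)
  keep <- mean_area > 0
  peak_areas(ids[1L], keys[keep], mean_area[keep],
             attr(reps[[1L]], "mz_lo"), attr(reps[[1L]], "mz_hi"))
}

#' Preprocess one sample's replicate spectra into averaged peak areas
#'
#' Convenience wrapper: segment-normalize each replicate, centroid it
#' valley-to-valley, and average the replicate peak areas.
#'
#' @param reps List of `replicate_spectrum` objects for one sample.
#' @param segment_width,target_sum Passed to [segment_normalize()].
#' @return A `peak_areas` object.
#' @export
preprocess_sample <- function(reps, segment_width = 25L, target_sum = 100) {
  pav <- lapply(reps, function(r)
    centroid_areas(segment_normalize(r, segment_width, target_sum)))
  average_replicates(pav)
}
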