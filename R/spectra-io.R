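#' Read replicate spectra from TSV
#'
#' Two tabulated dialects are accepted.  *Wide*: header
#' `sample_id  replicate  I400  I401 ... I2000`, one row per replicate,
#' one intensity column per unit m/z.  *Long*: header
#' `sample_id  replicate  mz  intensity`, one row per (possibly
#' fractional-m/z) point; points are nominal-binned half-up.
#'
#' @param path Path to a tab-separated file.
#' @param format `"auto"` (detect from the header), `"wide"`, or `"long"`.
#' @param mz_lo,mz_hi Grid bounds used for the long dialect (the wide
#'   dialect carries its grid in the header).
#' @return A list of `replicate_spectrum` objects.
#' @export
read_spectra_tsv <- function(path, format = c("auto", "wide", "long"),
                             mz_lo = 400L, mz_hi = 2000L) {
  format <- match.arg(format)
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cols <- names(df)
  if (format == "auto") {
    format <- if (all(c("mz", "intensity") %in% cols)) "long" else "wide"
  }
  if (!all(c("sample_id", "replicate") %in% cols))
    stop_bad("spectra TSV needs 'sample_id' and 'replicate' columns")
  if (format == "long") {
    if (!all(c("mz", "intensity") %in% cols))
      stop_bad("long spectra TSV needs 'mz' and 'intensity' columns")
    key <- interaction(df$sample_id, df$replicate, drop = TRUE)
    out <- lapply(split(df, key), function(d)
      nominal_bin(d$mz, d$intensity, d$sample_id[1L], d$replicate[1L],
                  mz_lo, mz_hi))
  } else {
    icols <- grep("^I\\d+$", cols, value = TRUE)
    if (!length(icols)) stop_bad("wide spectra TSV has no I<mz> columns")
    mzs <- as.integer(sub("^I", "", icols))
    o <- order(mzs)
    icols <- icols[o]; mzs <- mzs[o]
    if (!all(diff(mzs) == 1L))
      stop_bad("wide spectra TSV I<mz> columns must form a contiguous unit grid")
    out <- lapply(seq_len(nrow(df)), function(i)
      replicate_spectrum(df$sample_id[i], df$replicate[i],
                         as.numeric(df[i, icols]),
                         mz_lo = mzs[1L], mz_hi = mzs[length(mzs)]))
  }
  unname(out)
}

#' Write replicate spectra as wide TSV
#'
#' @param spectra List of `replicate_spectrum` on a common grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_tsv <- function(spectra, path) {
  stopifnot(length(spectra) > 0)
  lo <- spectra[[1L]]$mz_lo; hi <- spectra[[1L]]$mz_hi
  ok <- vapply(spectra, function(s) s$mz_lo == lo && s$mz_hi == hi, logical(1))
  if (!all(ok)) stop_bad("spectra are not on a common m/z grid")
  mat <- do.call(rbind, lapply(spectra, function(s) s$intensities))
  df <- data.frame(
    sample_id = vapply(spectra, function(s) s$sample_id, character(1)),
    replicate = vapply(spectra, function(s) s$replicate, integer(1)),
    mat, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("I", seq.int(lo, hi))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read replicate spectra from an mzML file
#'
#' Uses the Bioconductor `mzR` reader; every scan in the file becomes one
#' replicate (in acquisition order) and its profile or centroid points are
#' nominal-binned half-up onto the unit-mass grid.
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample identifier to attach to all scans.
#' @param mz_lo,mz_hi Grid bounds.
#' @return A list of `replicate_spectrum` objects, one per scan.
#' @export
read_spectra_mzml <- function(path, sample_id, mz_lo = 400L, mz_hi = 2000L) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop_bad("reading mzML requires the 'mzR' package")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  n <- length(handle)
  pk <- mzR::peaks(handle)
  if (n == 1L && is.matrix(pk)) pk <- list(pk)
  lapply(seq_len(n), function(i)
    nominal_bin(pk[[i]][, 1L], pk[[i]][, 2L], sample_id, i, mz_lo, mz_hi))
}

#' Assemble per-sample peak areas into a dense peak matrix
#'
#' @param areas List of `peak_areas`, one per sample.
#' @return Numeric matrix, rows = samples (named by sample id), columns =
#'   the sorted union of unit m/z keys; absent peaks are 0.
#' @export
peak_matrix <- function(areas) {
  stopifnot(length(areas) > 0,
            all(vapply(areas, inherits, logical(1), "peak_areas")))
  ids <- vapply(areas, attr, character(1), "sample_id")
  if (anyDuplicated(ids)) stop_bad("duplicate sample ids in peak matrix")
  keys <- sort(unique(unlist(lapply(areas, function(a) as.integer(names(a))))))
  m <- matrix(0, nrow = length(areas), ncol = length(keys),
              dimnames = list(ids, as.character(keys)))
  for (i in seq_along(areas)) {
    a <- areas[[i]]
    m[i, match(as.integer(names(a)), keys)] <- as.numeric(a)
  }
  m
}

#' Write a peak matrix as TSV
#'
#' Rows are samples, columns unit m/z, cells averaged areas (0 = absent).
#'
#' @param m Matrix from [peak_matrix()] (or a cohort's `$areas`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
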