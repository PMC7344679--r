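#' Construct a molecular feature table
#'
#' The central container of the pipeline: an aligned untargeted LC-MS feature
#' table. Each row is a molecular feature -- a (m/z, retention time) pair --
#' and each column of the intensity matrix is a sample. Intensities are
#' relative, nonnegative, and may be missing (`NA`). A zero is a measured
#' value; missingness is encoded only as `NA`.
#'
#' @param feature_id character vector of unique feature identifiers.
#' @param mz numeric vector of mass-to-charge ratios (Thomson), all positive.
#' @param rt numeric vector of retention times (minutes), all nonnegative.
#' @param intensities numeric matrix, features x samples, with column names
#'   giving unique sample identifiers. Nonnegative or `NA`.
#' @param mode ionization mode, `"positive"` or `"negative"`. Tables from the
#'   two modes are analysed separately end to end.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(feature_id, mz, rt, intensities,
                          mode = c("negative", "positive")) {
  mode <- match.arg(mode)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  p <- length(feature_id)
  if (p == 0L) stop("feature table must contain at least one feature")
  if (nrow(intensities) != p || length(mz) != p || length(rt) != p)
    stop("feature_id, mz, rt and intensity rows must all have equal length")
  if (ncol(intensities) == 0L) stop("feature table must contain at least one sample")
  dup <- feature_id[duplicated(feature_id)]
  if (length(dup))
    stop("duplicated feature_id: ", paste(unique(dup), collapse = ", "))
  if (is.null(colnames(intensities)))
    stop("intensity matrix must carry sample ids as column names")
  dup_s <- colnames(intensities)[duplicated(colnames(intensities))]
  if (length(dup_s))
    stop("duplicated sample id: ", paste(unique(dup_s), collapse = ", "))
  bad_mz <- which(!is.finite(mz) | mz <= 0)
  if (length(bad_mz))
    stop("non-positive or non-finite mz for feature ", feature_id[bad_mz[1L]])
  bad_rt <- which(!is.finite(rt) | rt < 0)
  if (length(bad_rt))
    stop("negative or non-finite rt for feature ", feature_id[bad_rt[1L]])
  neg <- which(intensities < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative intensity for feature ", feature_id[neg[1L, 1L]])
  rownames(intensities) <- feature_id
  structure(
    list(feature_id = as.character(feature_id),
         mz = as.numeric(mz), rt = as.numeric(rt),
         mode = mode, intensities = intensities),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%s mode)\n",
              n_features(x), n_samples(x), x$mode))
  cat(sprintf("  m/z %.4f-%.4f Th, rt %.2f-%.2f min, %.1f%% missing\n",
              min(x$mz), max(x$mz), min(x$rt), max(x$rt),
              100 * mean(is.na(x$intensities))))
  invisible(x)
}

#' Number of features / samples in a table
#' @param table a `feature_table`.
#' @return integer count.
#' @export
n_features <- function(table) length(table$feature_id)

#' @rdname n_features
#' @export
n_samples <- function(table) ncol(table$intensities)

#' @export
`[.feature_table` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(n_features(x))
  if (missing(j)) j <- seq_len(n_samples(x))
  if (is.character(i)) i <- match(i, x$feature_id)
  feature_table(x$feature_id[i], x$mz[i], x$rt[i],
                x$intensities[i, j, drop = FALSE], mode = x$mode)
}

sample_ids <- function(table) colnames(table$intensities)

# keep a subset of features, preserving order; errors if nothing survives
keep_features <- function(table, keep, what) {
  if (!any(keep))
    stop("degenerate table: every feature removed by the ", what, " filter")
  table[which(keep), ]
}
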