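# Feature filtering and normalization.
#
# Three filters, applied in this order, then three normalization steps:
#   1. low-intensity: mean observed intensity < frac * highest per-feature mean
#   2. missingness:   more than max_missing of a feature's cells missing
#   3. early elution: retention time before min_rt
# then per sample divide by injection volume and by the sample's median
# observed intensity, and per feature divide by the within-batch median.
# All boundary comparisons are strict; means and medians use observed
# (non-missing) values only.

#' Remove low-intensity features
#'
#' Drops features whose mean observed intensity is strictly below
#' `frac` times the highest per-feature mean. A feature with no observed
#' values (all missing) has an undefined mean and is dropped as well.
#'
#' @param table a `feature_table`.
#' @param frac fraction of the maximum per-feature mean (default 0.001,
#'   i.e. 0.1%).
#' @return filtered `feature_table`.
#' @export
filter_low_intensity <- function(table, frac = 0.001) {
  m <- rowMeans(table$intensities, na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  thr <- frac * max(m, na.rm = TRUE)
  keep_features(table, !is.na(m) & m >= thr, "low-intensity")
}

#' Remove features with excessive missingness
#'
#' Drops features whose missing fraction strictly exceeds `max_missing`
#' (default 30%); a feature at exactly the boundary is kept.
#'
#' @param table a `feature_table`.
#' @param max_missing maximum tolerated missing fraction.
#' @return filtered `feature_table`.
#' @export
filter_missing <- function(table, max_missing = 0.30) {
  fr <- rowMeans(is.na(table$intensities))
  keep_features(table, fr <= max_missing, "missingness")
}

#' Remove early-eluting features
#'
#' Drops features with retention time strictly below `min_rt` minutes
#' (default 0.45); the solvent front region of the chromatogram.
#'
#' @param table a `feature_table`.
#' @param min_rt minimum retention time in minutes.
#' @return filtered `feature_table`.
#' @export
filter_early_rt <- function(table, min_rt = 0.45) {
  keep_features(table, table$rt >= min_rt, "early-retention-time")
}

#' Normalize a filtered feature table
#'
#' Per sample: divide by the sample's injection volume, then by the sample's
#' median observed intensity. Then per feature: divide each entry by the
#' median observed intensity of that feature across the samples of the
#' entry's batch, compensating instrument sensitivity drift between runs.
#' Missing entries stay missing.
#'
#' Directly after the sample-median step every sample's median observed
#' intensity is exactly 1, and directly after the batch step every feature's
#' within-batch median is exactly 1 (the batch step then perturbs sample
#' medians slightly). The `steps` argument runs a prefix of the chain, which
#' is how these stage-wise identities can be verified.
#'
#' @param table a `feature_table` (filters already applied).
#' @param metadata sample metadata with `sample_id`, `injection_volume`,
#'   `batch`.
#' @param steps which normalization steps to run, in order.
#' @return normalized `feature_table`.
#' @export
normalize_table <- function(table, metadata,
                            steps = c("volume", "sample_median",
                                      "batch_median")) {
  steps <- match.arg(steps, several.ok = TRUE)
  validate_dataset(table, metadata)
  meta <- metadata[match(sample_ids(table), metadata$sample_id), ]
  x <- table$intensities
  if ("volume" %in% steps)
    x <- sweep(x, 2L, meta$injection_volume, "/")
  if ("sample_median" %in% steps) {
    med_s <- apply(x, 2L, stats::median, na.rm = TRUE)
    bad <- which(!is.finite(med_s) | med_s == 0)
    if (length(bad))
      stop("zero or undefined median intensity for sample ",
           sample_ids(table)[bad[1L]])
    x <- sweep(x, 2L, med_s, "/")
  }
  if (!"batch_median" %in% steps) {
    out <- table
    out$intensities <- x
    return(out)
  }
  for (b in unique(meta$batch)) {
    cols <- which(meta$batch == b)
    med_f <- apply(x[, cols, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    bad_f <- which(!is.finite(med_f) | med_f == 0)
    if (length(bad_f))
      stop("zero or undefined within-batch median for feature ",
           table$feature_id[bad_f[1L]], " in batch ", b)
    x[, cols] <- x[, cols, drop = FALSE] / med_f
  }
  out <- table
  out$intensities <- x
  out
}

#' Run the full filtering and normalization chain
#'
#' Applies the three filters in order (low-intensity, missingness, early
#' retention time), then [normalize_table()], and reports per-step removal
#' counts. Each removed feature is attributed to the first filter that
#' removes it, so the report counts are additive.
#'
#' @param table a raw `feature_table`.
#' @param metadata sample metadata.
#' @param frac,max_missing,min_rt filter thresholds (defaults 0.001, 0.30,
#'   0.45).
#' @return list with `table` (processed `feature_table`) and `report`
#'   (a `preprocess_report`).
#' @export
preprocess <- function(table, metadata, frac = 0.001, max_missing = 0.30,
                       min_rt = 0.45) {
  n0 <- n_features(table)
  t1 <- filter_low_intensity(table, frac)
  t2 <- filter_missing(t1, max_missing)
  t3 <- filter_early_rt(t2, min_rt)
  normed <- normalize_table(t3, metadata)
  report <- structure(list(
    n_input_features = n0,
    n_removed_low_intensity = n0 - n_features(t1),
    n_removed_missing = n_features(t1) - n_features(t2),
    n_removed_early_rt = n_features(t2) - n_features(t3),
    n_output_features = n_features(t3),
    removed_low_intensity = setdiff(table$feature_id, t1$feature_id),
    removed_missing = setdiff(t1$feature_id, t2$feature_id),
    removed_early_rt = setdiff(t2$feature_id, t3$feature_id),
    normalization_steps = c("injection_volume", "sample_median",
                            "batch_feature_median")),
    class = "preprocess_report")
  list(table = normed, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(paste0("preprocess: %d features in, %d out\n",
                     "  removed: %d low-intensity, %d high-missingness, %d early-RT\n",
                     "  normalization: %s\n"),
              x$n_input_features, x$n_output_features,
              x$n_removed_low_intensity, x$n_removed_missing,
              x$n_removed_early_rt,
              paste(x$normalization_steps, collapse = " -> ")))
  invisible(x)
}
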