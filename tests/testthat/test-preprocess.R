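test_that("relative-intensity filter uses a strict 0.1%-of-max boundary", {
  tab <- tiny_table()   # feature means 100, 0.05, 50 -> threshold 0.1
  out <- filter_low_intensity(tab, frac = 0.001)
  expect_setequal(out$feature_id, c("f1", "f3"))
  # a mean exactly at the threshold is kept ("less than" is strict)
  ints <- matrix(c(100, 100, 0.1, 0.1), 2, 2, byrow = TRUE,
                 dimnames = list(NULL, c("S1", "S2")))
  tab2 <- feature_table(c("a", "b"), c(100, 200), c(1, 2), ints)
  expect_setequal(filter_low_intensity(tab2)$feature_id, c("a", "b"))
  # a single feature is its own maximum and always survives
  expect_equal(n_features(filter_low_intensity(tab2[1, ])), 1L)
})

test_that("missingness filter uses a strict 30% boundary", {
  mk <- function(n_missing) {
    x <- matrix(1, 2, 10, dimnames = list(NULL, paste0("S", 1:10)))
    x[2, seq_len(n_missing)] <- NA
    feature_table(c("full", "holey"), c(100, 200), c(1, 2), x)
  }
  expect_setequal(filter_missing(mk(4))$feature_id, "full")    # 40% removed
  expect_setequal(filter_missing(mk(3))$feature_id, c("full", "holey")) # 30% kept
  expect_setequal(filter_missing(mk(0))$feature_id, c("full", "holey"))
})

test_that("early-elution filter removes rt < 0.45 strictly", {
  x <- matrix(1, 4, 2, dimnames = list(NULL, c("S1", "S2")))
  tab <- feature_table(paste0("f", 1:4), mz = rep(100, 4),
                       rt = c(0.44, 0.45, 10.0, 0.0), intensities = x)
  expect_setequal(filter_early_rt(tab)$feature_id, c("f2", "f3"))
  late <- tab[c(2L, 3L), ]
  expect_equal(filter_early_rt(late), late)  # no early features: unchanged
})

test_that("filters are idempotent", {
  ds <- generate_dataset(small_config(seed = 9))
  tab <- ds$feature_table
  for (f in list(filter_low_intensity, filter_missing, filter_early_rt)) {
    once <- f(tab)
    expect_equal(f(once), once)
  }
})

test_that("a filter that removes everything is an error", {
  x <- matrix(1, 2, 2, dimnames = list(NULL, c("S1", "S2")))
  tab <- feature_table(c("a", "b"), c(100, 200), rt = c(0.1, 0.2), x)
  expect_error(filter_early_rt(tab), "degenerate")
})

test_that("normalization follows forced arithmetic, step by step", {
  x <- matrix(c(2, 4, 8), 3, 3, dimnames = list(NULL, paste0("S", 1:3)))
  x[2, ] <- c(4, 8, 16); x[3, ] <- c(8, 16, 32); x[1, ] <- c(2, 4, 8)
  tab <- feature_table(paste0("f", 1:3), rep(100, 3), rep(1, 3), x)
  meta <- tiny_metadata(paste0("S", 1:3), batches = rep("B1", 3))
  # sample S1 holds {2, 4, 8}; after volume (1) and its median (4): {0.5, 1, 2}
  s <- normalize_table(tab, meta, steps = c("volume", "sample_median"))
  expect_equal(unname(s$intensities[, "S1"]), c(0.5, 1, 2))
  # one batch, feature f1 = {1, 2, 3} across samples -> {0.5, 1, 1.5}
  x2 <- matrix(c(1, 2, 3), 1, 3, dimnames = list(NULL, paste0("S", 1:3)))
  tab2 <- feature_table("f1", 100, 1, x2)
  b <- normalize_table(tab2, meta, steps = "batch_median")
  expect_equal(unname(b$intensities[1, ]), c(0.5, 1, 1.5))
})

test_that("two identical batches reduce the batch step to a global median", {
  set.seed(30)
  x <- matrix(runif(5 * 4, 1, 10), 5, 4, dimnames = list(NULL, paste0("S", 1:4)))
  x[, 3:4] <- x[, 1:2]
  tab <- feature_table(paste0("f", 1:5), rep(100, 5), rep(1, 5), x)
  meta <- tiny_metadata(paste0("S", 1:4), batches = c("B1", "B1", "B2", "B2"))
  per_batch <- normalize_table(tab, meta, steps = "batch_median")
  glob <- sweep(x, 1L, apply(x, 1, median), "/")
  expect_equal(unname(per_batch$intensities), unname(glob))
})

test_that("normalization identities hold exactly, stage by stage", {
  ds <- generate_dataset(small_config(seed = 10))
  t3 <- filter_early_rt(filter_missing(filter_low_intensity(ds$feature_table)))
  meta <- ds$sample_metadata
  s <- normalize_table(t3, meta, steps = c("volume", "sample_median"))
  expect_equal(unname(apply(s$intensities, 2, median, na.rm = TRUE)),
               rep(1, n_samples(s)), tolerance = 1e-12)
  full <- normalize_table(t3, meta)
  for (b in unique(meta$batch)) {
    cols <- meta$sample_id[meta$batch == b]
    med <- apply(full$intensities[, cols], 1, median, na.rm = TRUE)
    expect_equal(unname(med), rep(1, n_features(full)), tolerance = 1e-12)
  }
})

test_that("the report is additive and attributes removals to the first filter", {
  ds <- generate_dataset(small_config(seed = 5))
  pp <- preprocess(ds$feature_table, ds$sample_metadata)
  r <- pp$report
  expect_equal(r$n_input_features,
               r$n_output_features + r$n_removed_low_intensity +
                 r$n_removed_missing + r$n_removed_early_rt)
  expect_equal(r$n_output_features, n_features(pp$table))
  removed <- c(r$removed_low_intensity, r$removed_missing, r$removed_early_rt)
  expect_equal(anyDuplicated(removed), 0L)
  expect_setequal(c(removed, pp$table$feature_id), ds$feature_table$feature_id)
})

test_that("undefined medians are reported with the culprit named", {
  x <- matrix(c(1, NA, 2, NA), 2, 2, dimnames = list(NULL, c("S1", "S2")))
  tab <- feature_table(c("f1", "f2"), c(100, 200), c(1, 2), x)
  meta <- tiny_metadata(c("S1", "S2"), batches = c("B1", "B2"))
  expect_error(normalize_table(tab, meta), "f2")
})
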