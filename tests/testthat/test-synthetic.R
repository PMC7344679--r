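test_that("default design yields 2x3x4x3 = 72 samples with complete metadata", {
  ds <- generate_dataset(synthetic_config(seed = 2, n_features = 400,
                                          n_biomarkers_per_attribute = 3))
  expect_equal(n_samples(ds$feature_table), 72L)
  expect_equal(nrow(ds$sample_metadata), 72L)
  expect_setequal(unique(ds$sample_metadata$season), c("s1", "s2"))
  expect_setequal(unique(ds$sample_metadata$cluster_type), c("i", "ii", "iii"))
  expect_equal(nrow(ds$sensory_scores), 72L)
  expect_setequal(setdiff(names(ds$sensory_scores), "sample_id"),
                  sensory_attributes())
  expect_true(validate_dataset(ds$feature_table, ds$sample_metadata,
                               ds$sensory_scores))
})

test_that("identical seed and config reproduce every output exactly", {
  a <- generate_dataset(small_config(seed = 11))
  b <- generate_dataset(small_config(seed = 11))
  expect_identical(a$feature_table, b$feature_table)
  expect_identical(a$sensory_scores, b$sensory_scores)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_dataset(small_config(seed = 12))
  expect_false(identical(a$feature_table$intensities,
                         c$feature_table$intensities))
})

test_that("ground truth references only emitted features, with configured sizes", {
  cfg <- small_config(seed = 3)
  ds <- generate_dataset(cfg)
  gt <- ds$ground_truth
  ids <- ds$feature_table$feature_id
  for (m in gt$biomarker_map) {
    expect_equal(nrow(m), cfg$n_biomarkers_per_attribute)
    expect_true(all(m$feature_id %in% ids))
  }
  # biomarker sets are disjoint across attributes
  all_bio <- unlist(lapply(gt$biomarker_map, `[[`, "feature_id"))
  expect_equal(anyDuplicated(all_bio), 0L)
  expect_length(gt$planted_low_intensity, cfg$n_planted_low_intensity)
  expect_length(gt$planted_missing, cfg$n_planted_missing)
  expect_length(gt$planted_early_rt, cfg$n_planted_early_rt)
  expect_true(all(gt$planted_compounds$feature_id %in% ids))
  expect_equal(nrow(gt$planted_compounds), cfg$n_planted_annotations)
})

test_that("null configuration decouples attribute scores from intensities", {
  cfg <- small_config(seed = 4, season_effect_sd = 0, cluster_effect_sd = 0,
                      biomarker_effect = 0, biomarker_latent_sd = 0)
  ds <- generate_dataset(cfg)
  X <- t(log10(ds$feature_table$intensities))
  Y <- as.matrix(ds$sensory_scores[, sensory_attributes()])
  cors <- suppressWarnings(cor(X, Y, use = "pairwise.complete.obs"))
  # mean |correlation| at n = 72 under independence is ~ sqrt(2/(pi*71))
  expect_lt(mean(abs(cors), na.rm = TRUE), 0.13)
})

test_that("degenerate configurations are rejected", {
  expect_error(synthetic_config(n_features = 0), "positive")
  expect_error(synthetic_config(n_seasons = 0), "positive")
  expect_error(synthetic_config(missing_rate = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(n_features = 50), "too small")
})

test_that("plant-and-recover: filters remove exactly the planted features", {
  for (seed in c(21, 22)) {
    ds <- generate_dataset(small_config(seed = seed))
    pp <- preprocess(ds$feature_table, ds$sample_metadata)
    gt <- ds$ground_truth
    expect_setequal(pp$report$removed_low_intensity, gt$planted_low_intensity)
    expect_setequal(pp$report$removed_missing, gt$planted_missing)
    expect_setequal(pp$report$removed_early_rt, gt$planted_early_rt)
  }
})

test_that("dataset tables survive a write/read round trip", {
  ds <- generate_dataset(small_config(seed = 6))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  tab <- read_feature_table(file.path(dir, "feature_table.csv"))
  expect_equal(tab$feature_id, ds$feature_table$feature_id)
  expect_equal(tab$intensities, ds$feature_table$intensities,
               tolerance = 1e-12)
  meta <- read_sample_metadata(file.path(dir, "sample_metadata.csv"))
  expect_equal(meta$sample_id, ds$sample_metadata$sample_id)
  sens <- read_sensory_scores(file.path(dir, "sensory_scores.csv"))
  expect_equal(sens, ds$sensory_scores, tolerance = 1e-12,
               ignore_attr = TRUE)
})
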