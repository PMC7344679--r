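# shared fixtures, all built in code

# a tiny hand-checkable table: 3 features x 4 samples
tiny_table <- function(mode = "negative") {
  ints <- matrix(c(100, 100, 100, 100,
                   0.05, 0.05, 0.05, 0.05,
                   50, 50, 50, 50),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(NULL, paste0("S", 1:4)))
  feature_table(c("f1", "f2", "f3"), mz = c(200.1, 350.2, 500.3),
                rt = c(1.2, 5.5, 10.0), intensities = ints, mode = mode)
}

tiny_metadata <- function(ids = paste0("S", 1:4), batches = c("B1", "B1", "B2", "B2")) {
  data.frame(sample_id = ids, season = rep(c("s1", "s2"), length.out = length(ids)),
             cluster_type = "i", batch = batches, injection_volume = 1,
             biological_rep = 1, technical_rep = seq_along(ids))
}

# a fast, small synthetic configuration for structural tests
small_config <- function(seed = 1, ...) {
  synthetic_config(seed = seed, n_features = 400,
                   n_biomarkers_per_attribute = 3,
                   n_planted_low_intensity = 5, n_planted_missing = 6,
                   n_planted_early_rt = 4, n_planted_annotations = 10, ...)
}

random_table <- function(n = 12, p = 30, seed = 1, missing = 0) {
  set.seed(seed)
  x <- matrix(10^rnorm(n * p, 4, 0.5), p, n,
              dimnames = list(NULL, paste0("S", seq_len(n))))
  if (missing > 0) x[sample(length(x), missing)] <- NA
  feature_table(sprintf("f%03d", seq_len(p)), mz = runif(p, 100, 1000),
                rt = runif(p, 1, 15), intensities = x)
}
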