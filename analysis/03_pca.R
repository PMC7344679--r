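#!/usr/bin/env Rscript
# Stage 3: unsupervised overview by NIPALS PCA (5 components, unit-variance
# scaling, missing values handled without imputation). The expected pattern
# of the emulated design: PC1 tracks harvest season, later components carry
# cluster-type structure.

library(sensomet)

tab <- read_feature_table("results/run/processed_table.csv")
meta <- read_sample_metadata("results/run/inputs/sample_metadata.csv")

fit <- fit_pca(tab, n_components = 5)
print(fit)

season <- as.numeric(factor(meta$season[match(colnames(tab$intensities),
                                              meta$sample_id)]))
cat(sprintf("PC1 vs season point-biserial r = %.3f\n",
            cor(fit$scores[, 1], season)))

write.csv(data.frame(sample_id = rownames(fit$scores), fit$scores),
          "results/run/pca_scores.csv", row.names = FALSE)
write.csv(data.frame(feature_id = tab$feature_id, fit$loadings),
          "results/run/pca_loadings.csv", row.names = FALSE)
jsonlite::write_json(list(r2_per_component = fit$r2_per_component,
                          scaling = fit$scaling),
                     "results/run/pca_summary.json",
                     auto_unbox = TRUE, digits = NA)
cat("scores, loadings and summary written to results/run/\n")
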