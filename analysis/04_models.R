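#!/usr/bin/env Rscript
# Stage 4: one sparse PLS-DA model per categorical response (season, grape
# cluster type) and one sparse PLS model per sensory attribute, each with
# its (n_components, keepX) pair chosen by repeated 5-fold cross-validation
# over the standard grid. 5 repeats per grid point keep this desk-sized;
# pass --full-cv for 100 repeats.
#
# Writes one model JSON per response under results/run/models/ and the
# supra-threshold (VIP > 1) table results/run/vip_tables.tsv.

library(sensomet)

full_cv <- "--full-cv" %in% commandArgs(trailingOnly = TRUE)
n_repeats <- if (full_cv) 100L else 5L

tab <- read_feature_table("results/run/processed_table.csv")
meta <- read_sample_metadata("results/run/inputs/sample_metadata.csv")
sens <- read_sensory_scores("results/run/inputs/sensory_scores.csv")
X <- t(tab$intensities)
meta <- meta[match(rownames(X), meta$sample_id), ]
sens <- sens[match(rownames(X), sens$sample_id), ]

dir.create("results/run/models", recursive = TRUE, showWarnings = FALSE)
responses <- c(list(season = list(kind = "splsda", y = meta$season),
                    cluster_type = list(kind = "splsda",
                                        y = meta$cluster_type)),
               setNames(lapply(sensory_attributes(), function(a)
                 list(kind = "spls", y = sens[[a]])), sensory_attributes()))

vip_rows <- list()
for (i in seq_along(responses)) {
  nm <- names(responses)[i]; r <- responses[[i]]
  cv <- suppressMessages(suppressWarnings(
    grid_search(X, r$y, kind = r$kind, n_repeats = n_repeats,
                seed = 3000L + i)))
  fit <- suppressMessages(
    if (r$kind == "splsda")
      fit_splsda(X, r$y, cv$best_pair[["n_components"]],
                 cv$best_pair[["keepX"]])
    else fit_spls(X, r$y, cv$best_pair[["n_components"]],
                  cv$best_pair[["keepX"]]))
  crit <- cv$grid$criterion[cv$grid$n_components == cv$best_pair[[1]] &
                              cv$grid$keepX == cv$best_pair[[2]]]
  cat(sprintf("%-16s %-7s best: %2d comp, keepX %4d  (%s = %.3f)\n",
              nm, r$kind, cv$best_pair[[1]], cv$best_pair[[2]],
              cv$criterion_kind, crit))
  jsonlite::write_json(
    list(response = nm, kind = r$kind, best_pair = as.list(cv$best_pair),
         criterion_kind = cv$criterion_kind, cv_grid = cv$grid,
         selected_features = fit$selected_features, vip = as.list(fit$vip)),
    file.path("results/run/models", paste0(nm, ".json")),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  hit <- fit$vip[fit$vip > 1]
  if (length(hit))
    vip_rows[[nm]] <- data.frame(response = nm, feature_id = names(hit),
                                 vip = unname(hit))
}
vip_tab <- do.call(rbind, vip_rows)
write.table(vip_tab, "results/run/vip_tables.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("%d supra-threshold (VIP > 1) entries across %d models\n",
            nrow(vip_tab), length(responses)))
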