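#!/usr/bin/env Rscript
# Stage 5: putative annotation of the processed features by exact-mass
# adduct matching against the compound table at 5 ppm, with MSI confidence
# levels, and a recovery check against the planted compound identities.
# Stage 6 decorates network nodes with the classes assigned here.

library(sensomet)

tab <- read_feature_table("results/run/processed_table.csv")
db <- read_compound_db("results/run/inputs/compounds.csv")
gt <- jsonlite::read_json("results/run/inputs/ground_truth.json",
                          simplifyVector = TRUE)

ann <- annotate_features(tab, db, tol_ppm = 5)
write_annotations(ann, "results/run/annotations.tsv")

lv <- table(factor(ann$msi_levels$msi_level, levels = c(2, 3, 4)))
cat(sprintf("MSI levels over %d features: %d level-2, %d level-3, %d level-4\n",
            n_features(tab), lv[["2"]], lv[["3"]], lv[["4"]]))

planted <- gt$planted_compounds
planted <- planted[planted$feature_id %in% tab$feature_id, ]
keys <- paste(ann$candidates$feature_id, ann$candidates$compound,
              ann$candidates$adduct)
hit <- paste(planted$feature_id, planted$compound, planted$adduct) %in% keys
cat(sprintf("planted (compound, adduct) pairs recovered: %d / %d\n",
            sum(hit), nrow(planted)))
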