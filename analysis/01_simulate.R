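#!/usr/bin/env Rscript
# Stage 1: simulate the study-design dataset with known ground truth.
#
# Emits the four input tables (feature table, sample metadata, sensory
# scores, compound database) plus the ground-truth JSON under
# results/run/inputs/. Later stages read these files, so every stage is
# re-runnable on its own.

library(sensomet)

cfg <- synthetic_config(seed = 2020L)
ds <- generate_dataset(cfg)
dir <- "results/run/inputs"
write_dataset(ds, dir)

cat(sprintf("simulated %d features x %d samples (%s mode)\n",
            n_features(ds$feature_table), n_samples(ds$feature_table),
            cfg$ionization_mode))
cat(sprintf("planted: %d low-intensity, %d high-missingness, %d early-RT,\n",
            cfg$n_planted_low_intensity, cfg$n_planted_missing,
            cfg$n_planted_early_rt))
cat(sprintf("         %d biomarkers per attribute, %d adduct-exact m/z\n",
            cfg$n_biomarkers_per_attribute, cfg$n_planted_annotations))
cat("tables written to", dir, "\n")
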