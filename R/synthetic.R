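# Synthetic wine-metabolomics data with known ground truth.
#
# Emulates the study design the pipeline targets: 2 harvest seasons x 3
# grape cluster types x 4 biological x 3 technical replicates (72 samples),
# a dominant season effect on a large fraction of features, smaller
# cluster-type effects, per-batch sensitivity shifts, intensity-dependent
# missingness, planted filter violations with exactly known membership,
# planted feature-attribute linear associations (the biomarkers), and
# features whose m/z sits at exact adduct masses of a compound database.

#' Configuration for the synthetic dataset generator
#'
#' Defaults encode the emulated study design (2 x 3 x 4 x 3 = 72 samples)
#' and effect sizes on the log10-intensity scale. Sensory scores live on an
#' arbitrary continuous scale (the panel's numeric scale is not part of the
#' emulated design).
#'
#' @param seed integer RNG seed; identical seed and config reproduce every
#'   output exactly.
#' @param n_features number of molecular features.
#' @param n_seasons,n_cluster_types,n_biological,n_technical design factors.
#' @param n_batches instrument batches, assigned as contiguous sample blocks.
#' @param season_effect_sd sd of per-feature season shifts (log10 units),
#'   applied to `frac_season_affected` of features.
#' @param cluster_effect_sd sd of per-feature, per-cluster-type shifts
#'   (log10 units), applied to `frac_cluster_affected` of features.
#' @param frac_season_affected,frac_cluster_affected affected fractions.
#' @param n_biomarkers_per_attribute planted biomarkers per sensory
#'   attribute; the 15 biomarker sets are disjoint and drawn from features
#'   free of season/cluster effects.
#' @param biomarker_effect score units per unit of standardized
#'   log-intensity of each biomarker feature.
#' @param biomarker_latent_sd sd of the latent per-bio-unit abundance factor
#'   shared by the biomarker features of one attribute (log10 units); models
#'   the strong co-variation of adducts, in-source fragments and
#'   co-regulated members of a compound family. 0 makes biomarkers mutually
#'   independent.
#' @param attribute_noise_sd sd of the additive noise on attribute scores.
#' @param missing_rate baseline missing-completely-at-random rate.
#' @param low_intensity_missing_boost multiplier added to the missing rate
#'   for lowest-decile intensities (rate * (1 + boost)).
#' @param batch_effect_sd sd of per-feature, per-batch log10 shifts.
#' @param baseline_log_mean,baseline_log_sd log10-normal baseline intensity
#'   parameters (mean 5, sd 1: the typical LC-MS dynamic range).
#' @param bio_noise_sd,tech_noise_sd biological- and technical-replicate
#'   noise sd (log10 units); technical replicates share their biological
#'   replicate's effects plus small technical noise.
#' @param n_planted_low_intensity,n_planted_missing,n_planted_early_rt
#'   features planted to fail, respectively, the relative-intensity filter,
#'   the 30% missingness filter and the 0.45 min retention-time filter --
#'   and the only features that do, so filter counts are known by
#'   construction.
#' @param n_planted_annotations features whose m/z is set to an exact adduct
#'   m/z of a compound database entry, offset by `annotation_ppm_offset`.
#' @param annotation_ppm_offset ppm offset applied to planted m/z values.
#' @param rt_range,mz_range retention-time (minutes) and m/z (Th) ranges of
#'   the emulated acquisition (0-19 min, 100-1500 Th).
#' @param ionization_mode mode of the emitted table.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_features = 2000L,
                             n_seasons = 2L, n_cluster_types = 3L,
                             n_biological = 4L, n_technical = 3L,
                             n_batches = 4L,
                             season_effect_sd = 0.8, cluster_effect_sd = 0.4,
                             frac_season_affected = 0.4,
                             frac_cluster_affected = 0.2,
                             n_biomarkers_per_attribute = 20L,
                             biomarker_effect = 1.0,
                             biomarker_latent_sd = 0.3,
                             attribute_noise_sd = 0.5,
                             missing_rate = 0.05,
                             low_intensity_missing_boost = 3,
                             batch_effect_sd = 0.1,
                             baseline_log_mean = 5, baseline_log_sd = 1,
                             bio_noise_sd = 0.1, tech_noise_sd = 0.05,
                             n_planted_low_intensity = 25L,
                             n_planted_missing = 30L,
                             n_planted_early_rt = 30L,
                             n_planted_annotations = 40L,
                             annotation_ppm_offset = 0,
                             rt_range = c(0, 19), mz_range = c(100, 1500),
                             ionization_mode = c("negative", "positive")) {
  cfg <- list(seed = as.integer(seed), n_features = as.integer(n_features),
              n_seasons = as.integer(n_seasons),
              n_cluster_types = as.integer(n_cluster_types),
              n_biological = as.integer(n_biological),
              n_technical = as.integer(n_technical),
              n_batches = as.integer(n_batches),
              season_effect_sd = season_effect_sd,
              cluster_effect_sd = cluster_effect_sd,
              frac_season_affected = frac_season_affected,
              frac_cluster_affected = frac_cluster_affected,
              n_biomarkers_per_attribute = as.integer(n_biomarkers_per_attribute),
              biomarker_effect = biomarker_effect,
              biomarker_latent_sd = biomarker_latent_sd,
              attribute_noise_sd = attribute_noise_sd,
              missing_rate = missing_rate,
              low_intensity_missing_boost = low_intensity_missing_boost,
              batch_effect_sd = batch_effect_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              bio_noise_sd = bio_noise_sd, tech_noise_sd = tech_noise_sd,
              n_planted_low_intensity = as.integer(n_planted_low_intensity),
              n_planted_missing = as.integer(n_planted_missing),
              n_planted_early_rt = as.integer(n_planted_early_rt),
              n_planted_annotations = as.integer(n_planted_annotations),
              annotation_ppm_offset = annotation_ppm_offset,
              rt_range = rt_range, mz_range = mz_range,
              ionization_mode = match.arg(ionization_mode))
  counts <- cfg[c("n_features", "n_seasons", "n_cluster_types",
                  "n_biological", "n_technical", "n_batches")]
  if (any(unlist(counts) < 1L))
    stop("design counts must be positive (zero samples or features rejected)")
  fracs <- cfg[c("frac_season_affected", "frac_cluster_affected",
                 "missing_rate")]
  if (any(unlist(fracs) < 0) || any(unlist(fracs) > 1))
    stop("fractions must lie in [0, 1]")
  if (cfg$low_intensity_missing_boost < 0)
    stop("low_intensity_missing_boost must be nonnegative")
  n_attr <- length(sensory_attributes())
  planted <- cfg$n_planted_low_intensity + cfg$n_planted_missing +
    cfg$n_planted_early_rt
  need <- planted + n_attr * cfg$n_biomarkers_per_attribute
  if (need > cfg$n_features)
    stop("n_features too small for the requested planted sets (need >= ",
         need, ")")
  structure(cfg, class = "synthetic_config")
}

#' The bundled wine compound table
#'
#' A small synthetic compound database (common wine phenolics, organic acids
#' and anthocyanin cations with their elemental formulas and compound
#' classes) shipped with the package, in the schema of
#' [read_compound_db()].
#' @return data.frame of compounds.
#' @export
wine_compounds <- function() {
  read_compound_db(system.file("extdata", "wine_compounds_synthetic.csv",
                               package = "sensomet", mustWork = TRUE))
}

#' Generate a synthetic dataset with known ground truth
#'
#' Draws log10-normal baseline intensities per feature, adds season shifts to
#' the season-affected features, per-cluster-type shifts to the
#' cluster-affected features, nested biological/technical replicate noise and
#' per-batch multiplicative sensitivity shifts; computes each attribute score
#' as the sum of `biomarker_effect` times the standardized log intensity of
#' its planted biomarker features plus noise; applies missingness (baseline
#' rate, boosted for low-decile intensities); and plants the filter
#' violations and adduct-exact m/z values recorded in the ground truth.
#'
#' Two guarantees make the planted filter sets exact: random per-feature
#' missingness is capped at the 30% boundary for unplanted features, and any
#' unplanted feature whose mean would fall under the 0.1%-of-maximum
#' intensity threshold is lifted by a constant factor (which leaves its
#' standardized log intensities, and hence all planted associations,
#' unchanged).
#'
#' @param config a [synthetic_config()].
#' @param compound_db compound database used for m/z planting (default the
#'   bundled [wine_compounds()] table).
#' @return list of class `wine_dataset`: `feature_table`, `sample_metadata`,
#'   `sensory_scores` (wide, one column per attribute), `compound_db`,
#'   `ground_truth`.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             compound_db = wine_compounds()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  p <- config$n_features
  seasons <- paste0("s", seq_len(config$n_seasons))
  clusters <- c("i", "ii", "iii", paste0("c", seq_len(max(0, config$n_cluster_types - 3))))
  clusters <- clusters[seq_len(config$n_cluster_types)]
  design <- expand.grid(technical_rep = seq_len(config$n_technical),
                        biological_rep = seq_len(config$n_biological),
                        cluster_type = clusters, season = seasons,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(design)
  sample_id <- sprintf("%s_%s_b%d_t%d", design$season, design$cluster_type,
                       design$biological_rep, design$technical_rep)
  # acquisition batches are balanced blocks: within every season x cluster
  # group, samples are randomized and dealt round-robin across batches, so
  # batch composition is as even as the design allows and batch is never
  # confounded with season or cluster type
  batch <- character(n)
  for (g in split(seq_len(n), paste(design$season, design$cluster_type))) {
    batch[sample(g)] <- paste0("B", rep_len(seq_len(config$n_batches),
                                            length(g)))
  }
  metadata <- data.frame(sample_id = sample_id, season = design$season,
                         cluster_type = design$cluster_type, batch = batch,
                         injection_volume = 2,
                         biological_rep = design$biological_rep,
                         technical_rep = design$technical_rep)

  feature_id <- sprintf("F%04d", seq_len(p))
  attrs <- sensory_attributes()

  # --- planted feature sets ------------------------------------------------
  removal <- sample.int(p, config$n_planted_low_intensity +
                          config$n_planted_missing + config$n_planted_early_rt)
  planted_low <- removal[seq_len(config$n_planted_low_intensity)]
  planted_miss <- removal[config$n_planted_low_intensity +
                            seq_len(config$n_planted_missing)]
  planted_early <- removal[config$n_planted_low_intensity +
                             config$n_planted_missing +
                             seq_len(config$n_planted_early_rt)]
  season_affected <- sort(sample.int(p, round(config$frac_season_affected * p)))
  cluster_affected <- sort(sample.int(p, round(config$frac_cluster_affected * p)))
  biomarker_pool <- setdiff(seq_len(p),
                            c(removal, season_affected, cluster_affected))
  need_bio <- length(attrs) * config$n_biomarkers_per_attribute
  if (length(biomarker_pool) < need_bio)
    stop("not enough unaffected features to host ", need_bio, " biomarkers")
  bio_idx <- sample(biomarker_pool, need_bio)
  biomarker_map <- stats::setNames(
    split(bio_idx, rep(seq_along(attrs), each = config$n_biomarkers_per_attribute)),
    attrs)

  # --- log10 intensity surface --------------------------------------------
  mu <- stats::rnorm(p, config$baseline_log_mean, config$baseline_log_sd)
  L <- matrix(mu, p, n)
  season_delta <- numeric(p)
  season_delta[season_affected] <- stats::rnorm(length(season_affected),
                                                0, config$season_effect_sd)
  s2 <- as.numeric(design$season == seasons[min(2L, length(seasons))])
  L <- L + outer(season_delta / 2, 2 * s2 - 1)
  cl_delta <- matrix(0, p, config$n_cluster_types)
  cl_delta[cluster_affected, ] <- stats::rnorm(
    length(cluster_affected) * config$n_cluster_types, 0,
    config$cluster_effect_sd)
  cl_delta <- cl_delta - rowMeans(cl_delta)
  L <- L + cl_delta[, match(design$cluster_type, clusters)]
  bio_unit <- interaction(design$season, design$cluster_type,
                          design$biological_rep, drop = TRUE)
  bio_eff <- matrix(stats::rnorm(p * nlevels(bio_unit), 0, config$bio_noise_sd),
                    p, nlevels(bio_unit))
  L <- L + bio_eff[, as.integer(bio_unit)]
  L <- L + matrix(stats::rnorm(p * n, 0, config$tech_noise_sd), p, n)
  # the biomarker features of one attribute co-vary: they stand for adducts,
  # in-source fragments and co-regulated members of one compound family, so
  # each set shares a latent per-bio-unit abundance factor
  if (config$biomarker_latent_sd > 0) {
    for (a in attrs) {
      g <- stats::rnorm(nlevels(bio_unit), 0, config$biomarker_latent_sd)
      L[biomarker_map[[a]], ] <-
        sweep(L[biomarker_map[[a]], , drop = FALSE], 2L,
              g[as.integer(bio_unit)], "+")
    }
  }
  batch_eff <- matrix(stats::rnorm(p * config$n_batches, 0,
                                   config$batch_effect_sd),
                      p, config$n_batches)
  L <- L + batch_eff[, match(batch, paste0("B", seq_len(config$n_batches)))]

  # --- sensory scores from standardized log intensities --------------------
  scores <- matrix(0, n, length(attrs), dimnames = list(NULL, attrs))
  for (a in attrs) {
    idx <- biomarker_map[[a]]
    z <- t(scale(t(L[idx, , drop = FALSE])))
    scores[, a] <- config$biomarker_effect * colSums(z) +
      stats::rnorm(n, 0, config$attribute_noise_sd)
  }
  sensory <- data.frame(sample_id = sample_id, scores, check.names = FALSE)

  X <- 10^L

  # --- missingness ----------------------------------------------------------
  guard_frac <- 0.30                       # the downstream missingness filter
  cap <- floor(guard_frac * n)
  exempt <- c(planted_low, planted_miss)
  if (config$missing_rate > 0 || config$low_intensity_missing_boost > 0) {
    q10 <- stats::quantile(X, 0.10)
    prob <- matrix(config$missing_rate, p, n)
    prob[X < q10] <- min(1, config$missing_rate *
                           (1 + config$low_intensity_missing_boost))
    miss <- matrix(stats::runif(p * n) < prob, p, n)
    miss[exempt, ] <- FALSE
    over <- which(rowSums(miss) > cap)
    for (f in over) {                       # cap at the filter boundary
      hit <- which(miss[f, ])
      keep_missing <- sample(hit, cap)
      miss[f, ] <- FALSE
      miss[f, keep_missing] <- TRUE
    }
    X[miss] <- NA_real_
  }
  for (f in planted_miss) {                 # strictly above the 30% boundary
    X[f, sample.int(n, cap + 1L)] <- NA_real_
  }

  # --- planted low-intensity features and the exactness rescue -------------
  frac_thr <- 0.001                         # the downstream intensity filter
  means <- rowMeans(X, na.rm = TRUE)
  max_mean <- max(means[-planted_low])
  X[planted_low, ] <- frac_thr * max_mean * 0.01
  means <- rowMeans(X, na.rm = TRUE)
  thr <- frac_thr * max(means)
  lift <- setdiff(which(means < 1.05 * thr), planted_low)
  for (f in lift) X[f, ] <- X[f, ] * (1.1 * thr / means[f])

  # --- retention times and m/z ---------------------------------------------
  rt <- stats::runif(p, max(0.5, config$rt_range[1L]), config$rt_range[2L])
  rt[planted_early] <- stats::runif(length(planted_early), config$rt_range[1L],
                                    0.45)
  mz <- stats::runif(p, config$mz_range[1L], config$mz_range[2L])
  adducts <- adduct_table()
  adducts <- adducts[adducts$mode == config$ionization_mode, , drop = FALSE]
  db_ok <- if (any(adducts$intrinsic)) compound_db else
    compound_db[compound_db$intrinsic_charge == 0, , drop = FALSE]
  annot_pool <- setdiff(seq_len(p), removal)
  n_annot <- min(config$n_planted_annotations, length(annot_pool))
  annot_idx <- sample(annot_pool, n_annot)
  planted_compounds <- NULL
  if (n_annot > 0L && nrow(db_ok)) {
    rows <- sample.int(nrow(db_ok), n_annot, replace = TRUE)
    planted_compounds <- do.call(rbind, lapply(seq_len(n_annot), function(k) {
      cmp <- db_ok[rows[k], ]
      ok <- if (cmp$intrinsic_charge == 1) adducts$intrinsic else !adducts$intrinsic
      ad <- adducts[ok, , drop = FALSE]
      ad <- ad[sample.int(nrow(ad), 1L), ]
      theo <- formula_monoisotopic_mass(cmp$formula) + ad$mass_shift
      data.frame(feature_id = feature_id[annot_idx[k]], compound = cmp$name,
                 adduct = ad$adduct, theoretical_mz = theo,
                 ppm_offset = config$annotation_ppm_offset)
    }))
    mz[annot_idx] <- planted_compounds$theoretical_mz *
      (1 + config$annotation_ppm_offset * 1e-6)
  }

  colnames(X) <- sample_id
  table <- feature_table(feature_id, mz, rt, X, mode = config$ionization_mode)
  ground_truth <- list(
    biomarker_map = lapply(biomarker_map, function(idx)
      data.frame(feature_id = feature_id[idx],
                 effect = config$biomarker_effect)),
    season_affected = feature_id[season_affected],
    cluster_affected = feature_id[cluster_affected],
    planted_low_intensity = feature_id[sort(planted_low)],
    planted_missing = feature_id[sort(planted_miss)],
    planted_early_rt = feature_id[sort(planted_early)],
    planted_compounds = planted_compounds)
  structure(list(feature_table = table, sample_metadata = metadata,
                 sensory_scores = sensory, compound_db = compound_db,
                 ground_truth = ground_truth, config = config),
            class = "wine_dataset")
}

#' @export
print.wine_dataset <- function(x, ...) {
  cat(sprintf("wine_dataset: %d features x %d samples, %d attributes scored\n",
              n_features(x$feature_table), n_samples(x$feature_table),
              ncol(x$sensory_scores) - 1L))
  invisible(x)
}

#' Write all tables of a synthetic dataset to a directory
#'
#' Emits `feature_table.csv`, `sample_metadata.csv`, `sensory_scores.csv`,
#' `compounds.csv` and `ground_truth.json`.
#' @param dataset a `wine_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "wine_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(dataset$feature_table, file.path(dir, "feature_table.csv"))
  utils::write.csv(dataset$sample_metadata,
                   file.path(dir, "sample_metadata.csv"), row.names = FALSE)
  utils::write.csv(dataset$sensory_scores,
                   file.path(dir, "sensory_scores.csv"), row.names = FALSE)
  utils::write.csv(dataset$compound_db, file.path(dir, "compounds.csv"),
                   row.names = FALSE)
  jsonlite::write_json(dataset$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
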