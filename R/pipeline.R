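# End-to-end orchestration: simulate/load -> preprocess -> PCA ->
# sPLS-DA / per-attribute sPLS with cross-validated grids -> VIP tables ->
# aroma/taste networks -> annotation. Every stage writes its outputs under
# the run directory so each is individually re-runnable from serialized
# intermediates.

#' Configuration for a full pipeline run
#'
#' Either a synthetic-data configuration or paths to the four input tables.
#' All randomness flows from `seed`: the simulation uses `seed + 1` and the
#' grid search of the i-th response model uses `seed + 100 + i`.
#'
#' @param out_dir run directory (created; a serialized copy of the config is
#'   written alongside the outputs).
#' @param seed root integer seed.
#' @param synthetic a [synthetic_config()], or `NULL` when reading inputs
#'   from files.
#' @param feature_table_path,metadata_path,sensory_path,compounds_path input
#'   table paths (ignored when `synthetic` is given).
#' @param ionization_mode mode of the input table when read from file.
#' @param frac,max_missing,min_rt filter thresholds (see [preprocess()]).
#' @param pca_components PCA components (default 5).
#' @param comp_grid_spls,comp_grid_splsda component grids (`NULL` for the
#'   1-12 / 1-3 defaults).
#' @param keepX_grid selected-variable grid (default 50, 100, 200, 300, 500,
#'   1000).
#' @param n_repeats cross-validation repeats per grid point. The default 10
#'   keeps a full run desk-sized; `full_cv = TRUE` restores the
#'   canonical 100.
#' @param k_folds folds (default 5).
#' @param full_cv use 100 cross-validation repeats per grid point.
#' @param vip_threshold network edge threshold on VIP (default 1.0; 0 gives
#'   the every-positive-VIP variant).
#' @param tol_ppm annotation mass tolerance (default 5 ppm).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            synthetic = synthetic_config(),
                            feature_table_path = NULL, metadata_path = NULL,
                            sensory_path = NULL, compounds_path = NULL,
                            ionization_mode = "negative",
                            frac = 0.001, max_missing = 0.30, min_rt = 0.45,
                            pca_components = 5L,
                            comp_grid_spls = NULL, comp_grid_splsda = NULL,
                            keepX_grid = c(50L, 100L, 200L, 300L, 500L, 1000L),
                            n_repeats = 10L, k_folds = 5L, full_cv = FALSE,
                            vip_threshold = 1.0, tol_ppm = 5.0) {
  if (is.null(synthetic) &&
      (is.null(feature_table_path) || is.null(metadata_path) ||
       is.null(sensory_path) || is.null(compounds_path)))
    stop("either a synthetic config or all four input paths are required")
  if (full_cv) n_repeats <- 100L
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic,
                 feature_table_path = feature_table_path,
                 metadata_path = metadata_path, sensory_path = sensory_path,
                 compounds_path = compounds_path,
                 ionization_mode = ionization_mode,
                 frac = frac, max_missing = max_missing, min_rt = min_rt,
                 pca_components = as.integer(pca_components),
                 comp_grid_spls = comp_grid_spls,
                 comp_grid_splsda = comp_grid_splsda,
                 keepX_grid = as.integer(keepX_grid),
                 n_repeats = as.integer(n_repeats),
                 k_folds = as.integer(k_folds),
                 vip_threshold = vip_threshold, tol_ppm = tol_ppm),
            class = "pipeline_config")
}

write_model_json <- function(model, cv, path) {
  jsonlite::write_json(list(
    response = model$response_names,
    classes = model$classes,
    n_components = model$n_components,
    keepX = model$keepX,
    best_pair = as.list(cv$best_pair),
    criterion_kind = cv$criterion_kind,
    cv_grid = cv$grid,
    selected_features = model$selected_features,
    vip = as.list(model$vip)),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Produces, under `config$out_dir`: the (simulated) input tables, the
#' preprocessing report, PCA scores/loadings/summary, one model JSON per
#' response variable (season and cluster type by sPLS-DA, each of the 15
#' sensory attributes by sPLS), supra-threshold VIP tables, aroma and taste
#' networks (GraphML + edge TSV), the annotation TSV, and a run log with
#' seed and per-stage timings. Any stage error aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the run directory, the per-response best
#'   hyperparameters and the network summaries.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_lines <- c(sprintf("sensomet %s | R %s | seed %d | %s",
                         as.character(utils::packageVersion("sensomet")),
                         paste(R.version$major, R.version$minor, sep = "."),
                         config$seed, format(Sys.time())))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    log_lines <<- c(log_lines, sprintf("%-12s %8.2f s", name,
                                       proc.time()[["elapsed"]] - t0))
    res
  }
  cfg_copy <- config
  cfg_copy$synthetic <- unclass(config$synthetic)
  jsonlite::write_json(unclass(cfg_copy),
                       file.path(config$out_dir, "pipeline_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  inputs <- stage("inputs", {
    if (!is.null(config$synthetic)) {
      syn <- config$synthetic
      syn$seed <- config$seed + 1L
      ds <- generate_dataset(syn)
      write_dataset(ds, file.path(config$out_dir, "inputs"))
      ds
    } else {
      tab <- read_feature_table(config$feature_table_path,
                                mode = config$ionization_mode)
      meta <- read_sample_metadata(config$metadata_path)
      sens <- read_sensory_scores(config$sensory_path)
      db <- read_compound_db(config$compounds_path)
      validate_dataset(tab, meta, sens)
      list(feature_table = tab, sample_metadata = meta,
           sensory_scores = sens, compound_db = db, ground_truth = NULL)
    }
  })

  pp <- stage("preprocess", {
    out <- preprocess(inputs$feature_table, inputs$sample_metadata,
                      frac = config$frac, max_missing = config$max_missing,
                      min_rt = config$min_rt)
    jsonlite::write_json(unclass(out$report),
                         file.path(config$out_dir, "preprocess_report.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })
  tab <- pp$table
  meta <- inputs$sample_metadata[match(sample_ids(tab),
                                       inputs$sample_metadata$sample_id), ]

  pca <- stage("pca", {
    ncomp <- min(config$pca_components, n_samples(tab) - 1L, n_features(tab))
    fit <- fit_pca(tab, n_components = ncomp)
    utils::write.csv(data.frame(sample_id = sample_ids(tab), fit$scores),
                     file.path(config$out_dir, "pca_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(feature_id = tab$feature_id, fit$loadings),
                     file.path(config$out_dir, "pca_loadings.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(n_components = fit$n_components,
                              r2_per_component = fit$r2_per_component,
                              scaling = fit$scaling),
                         file.path(config$out_dir, "pca_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    fit
  })

  X <- t(tab$intensities)
  sens <- inputs$sensory_scores[match(sample_ids(tab),
                                      inputs$sensory_scores$sample_id), ]
  responses <- c(list(season = list(kind = "splsda", y = meta$season),
                      cluster_type = list(kind = "splsda",
                                          y = meta$cluster_type)),
                 stats::setNames(lapply(sensory_attributes(), function(a)
                   list(kind = "spls", y = sens[[a]])), sensory_attributes()))
  model_dir <- file.path(config$out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  vips <- list()
  best <- list()
  for (i in seq_along(responses)) {
    nm <- names(responses)[i]
    r <- responses[[i]]
    fit <- stage(paste0("model:", nm), {
      cv <- grid_search(X, r$y, kind = r$kind,
                        comp_grid = if (r$kind == "spls") config$comp_grid_spls
                                    else config$comp_grid_splsda,
                        keepX_grid = config$keepX_grid,
                        n_repeats = config$n_repeats, k = config$k_folds,
                        seed = config$seed + 100L + i)
      m <- if (r$kind == "splsda") {
        fit_splsda(X, r$y, n_components = cv$best_pair[["n_components"]],
                   keepX = cv$best_pair[["keepX"]])
      } else {
        fit_spls(X, r$y, n_components = cv$best_pair[["n_components"]],
                 keepX = cv$best_pair[["keepX"]])
      }
      write_model_json(m, cv, file.path(model_dir, paste0(nm, ".json")))
      best[[nm]] <- cv$best_pair
      m
    })
    vips[[nm]] <- fit$vip
  }

  ann <- stage("annotate", {
    a <- annotate_features(tab, inputs$compound_db, tol_ppm = config$tol_ppm)
    write_annotations(a, file.path(config$out_dir, "annotations.tsv"))
    a
  })

  nets <- stage("network", {
    top_class <- vapply(tab$feature_id, function(f) {
      cc <- ann$candidates$compound_class[ann$candidates$feature_id == f]
      if (length(cc)) cc[1L] else NA_character_
    }, character(1))
    feature_info <- data.frame(feature_id = tab$feature_id, mz = tab$mz,
                               rt = tab$rt, annotation = top_class)
    vip_tab <- do.call(rbind, lapply(names(vips), function(nm) {
      v <- vips[[nm]]
      hit <- v > config$vip_threshold
      if (!any(hit)) return(NULL)
      data.frame(response = nm, feature_id = names(v)[hit],
                 vip = unname(v[hit]))
    }))
    utils::write.table(vip_tab, file.path(config$out_dir, "vip_tables.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out <- list()
    for (grp in c("aroma", "taste")) {
      net <- build_network(vips[sensory_attributes(grp)],
                           threshold = config$vip_threshold,
                           feature_info = feature_info)
      write_network(net, file.path(config$out_dir,
                                   paste0("network_", grp, ".graphml")),
                    format = "graphml")
      write_network(net, file.path(config$out_dir,
                                   paste0("network_", grp, "_edges.tsv")),
                    format = "edge_tsv")
      out[[grp]] <- network_summary(net)
    }
    out
  })

  writeLines(log_lines, log_path)
  invisible(list(out_dir = config$out_dir, best_pairs = best,
                 pca_r2 = pca$r2_per_component, networks = nets))
}
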