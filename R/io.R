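#' The fixed sensory attribute vocabulary
#'
#' The 15 attributes scored by the expert panel, split into 11 aroma and 4
#' taste (mouthfeel) attributes. Attribute columns of a sensory score table
#' must be drawn from this vocabulary. Names are lower-case tokens
#' (`coffee_chocolate` stands for the coffee/chocolate descriptor,
#' `red_berries` and `stone_fruits` for the two fruit descriptors).
#'
#' @param group `"all"`, `"aroma"` or `"taste"`.
#' @return character vector of attribute names.
#' @export
sensory_attributes <- function(group = c("all", "aroma", "taste")) {
  group <- match.arg(group)
  aroma <- c("spice", "woody", "smoky", "coffee_chocolate", "vegetal",
             "animal", "herbal", "red_berries", "stone_fruits", "nuts",
             "caramel")
  taste <- c("astringency", "acidity", "bitterness", "sweetness")
  switch(group, all = c(aroma, taste), aroma = aroma, taste = taste)
}

# Sniff the delimiter of a CSV/TSV by inspecting the header line.
sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty file: ", path)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

read_delim_strict <- function(path) {
  utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), comment.char = "")
}

#' Read an aligned feature table from CSV/TSV
#'
#' Expects header columns `feature_id`, `mz`, `rt`, followed by one column per
#' sample. Empty cells and `NA` parse as missing intensities; zero is a
#' measured value. Validation failures name the offending feature.
#'
#' @param path path to a CSV or TSV file (delimiter sniffed).
#' @param mode ionization mode of the table.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, mode = c("negative", "positive")) {
  mode <- match.arg(mode)
  df <- read_delim_strict(path)
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(df)))
    stop("feature table must start with columns: ", paste(need, collapse = ", "))
  sample_cols <- setdiff(names(df), need)
  if (!length(sample_cols)) stop("feature table has no sample columns")
  ints <- as.matrix(df[sample_cols])
  if (!is.numeric(ints)) {
    bad <- sample_cols[!vapply(df[sample_cols], is.numeric, logical(1))][1L]
    stop("non-numeric intensity in sample column ", bad)
  }
  colnames(ints) <- sample_cols
  feature_table(df$feature_id, df$mz, df$rt, ints, mode = mode)
}

#' Write a feature table to CSV
#' @param table a `feature_table`.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(feature_id = table$feature_id, mz = table$mz, rt = table$rt,
                   table$intensities, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read sample metadata
#'
#' Columns: `sample_id`, `season`, `cluster_type`, `batch`,
#' `injection_volume`, `biological_rep`, `technical_rep`.
#' @param path path to CSV/TSV.
#' @return data.frame of metadata, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  df <- read_delim_strict(path)
  need <- c("sample_id", "season", "cluster_type", "batch",
            "injection_volume", "biological_rep", "technical_rep")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) stop("duplicated sample_id in metadata: ", dup[1L])
  if (any(!is.finite(df$injection_volume) | df$injection_volume <= 0))
    stop("injection_volume must be positive")
  df
}

#' Read a sensory score table
#'
#' Wide format: a `sample_id` column plus one numeric column per attribute.
#' Attribute names must come from [sensory_attributes()].
#' @param path path to CSV/TSV.
#' @param require_complete require all 15 attributes to be present.
#' @return data.frame, samples x attributes.
#' @export
read_sensory_scores <- function(path, require_complete = TRUE) {
  df <- read_delim_strict(path)
  if (!"sample_id" %in% names(df)) stop("sensory table needs a sample_id column")
  attrs <- setdiff(names(df), "sample_id")
  unknown <- setdiff(attrs, sensory_attributes())
  if (length(unknown))
    stop("unknown sensory attribute(s): ", paste(unknown, collapse = ", "),
         "; the vocabulary is: ", paste(sensory_attributes(), collapse = ", "))
  if (require_complete) {
    miss <- setdiff(sensory_attributes(), attrs)
    if (length(miss))
      stop("incomplete attribute set; missing: ", paste(miss, collapse = ", "))
  }
  if (any(!vapply(df[attrs], is.numeric, logical(1))))
    stop("sensory scores must be numeric")
  df
}

#' Read a compound database table
#'
#' Columns: `name`, `formula`, `compound_class`, `intrinsic_charge` (0 for
#' neutral molecules, 1 for intrinsic cations such as flavylium anthocyanins,
#' whose formula is that of the cation). Formulas are validated against the
#' supported element set.
#' @param path path to CSV/TSV.
#' @return data.frame of compounds.
#' @export
read_compound_db <- function(path) {
  df <- read_delim_strict(path)
  need <- c("name", "formula", "compound_class", "intrinsic_charge")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("compound table missing columns: ", paste(miss, collapse = ", "))
  dup <- df$name[duplicated(df$name)]
  if (length(dup)) stop("duplicated compound name: ", dup[1L])
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({ parse_formula(df$formula[i]); TRUE }, error = function(e) FALSE)
    if (!ok) stop("unparseable formula for compound ", df$name[i], ": ", df$formula[i])
  }
  if (!all(df$intrinsic_charge %in% c(0, 1)))
    stop("intrinsic_charge must be 0 or 1")
  df
}

#' Cross-validate a loaded dataset
#'
#' Assembly-time checks that individual readers cannot perform: every sample
#' in the feature table must have exactly one metadata row, and sensory scores
#' (when given) must cover every sample.
#' @param table a `feature_table`.
#' @param metadata sample metadata data.frame.
#' @param scores optional sensory score data.frame.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_dataset <- function(table, metadata, scores = NULL) {
  ids <- sample_ids(table)
  miss <- setdiff(ids, metadata$sample_id)
  if (length(miss))
    stop("samples missing from metadata: ", paste(miss, collapse = ", "))
  if (!is.null(scores)) {
    miss_s <- setdiff(ids, scores$sample_id)
    if (length(miss_s))
      stop("samples missing from sensory scores: ", paste(miss_s, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a biomarker network
#'
#' `edge_tsv` writes one row per edge with columns `attribute`, `feature_id`,
#' `vip`, `mz`, `rt`, `annotation`; `graphml` writes the bipartite graph with
#' node type and compound-category attributes.
#' @param net a `biomarker_network`.
#' @param path output path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "biomarker_network"))
  if (format == "edge_tsv") {
    edges <- net$edges
    fi <- net$features[match(edges$feature_id, net$features$feature_id), , drop = FALSE]
    out <- data.frame(attribute = edges$attribute, feature_id = edges$feature_id,
                      vip = edges$vip,
                      mz = if (nrow(edges)) fi$mz else numeric(0),
                      rt = if (nrow(edges)) fi$rt else numeric(0),
                      annotation = if (nrow(edges)) fi$annotation else character(0))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#' @param path GraphML path.
#' @return a `biomarker_network` (attribute/feature/edge structure only).
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  type <- igraph::vertex_attr(g, "type")
  name <- igraph::vertex_attr(g, "name")
  el <- igraph::as_edgelist(g)
  w <- igraph::edge_attr(g, "weight")
  is_attr <- type == "attribute"
  edges <- data.frame(attribute = character(nrow(el)),
                      feature_id = character(nrow(el)),
                      vip = as.numeric(w))
  for (k in seq_len(nrow(el))) {
    a <- el[k, ][is_attr[match(el[k, ], name)]]
    f <- setdiff(el[k, ], a)
    edges$attribute[k] <- a
    edges$feature_id[k] <- f
  }
  feat <- data.frame(feature_id = name[!is_attr],
                     mz = vattr_num(g, "mz")[!is_attr],
                     rt = vattr_num(g, "rt")[!is_attr],
                     annotation = vattr_chr(g, "annotation")[!is_attr])
  structure(list(attributes = data.frame(attribute = name[is_attr],
                                         has_edges = name[is_attr] %in% edges$attribute),
                 features = feat, edges = edges,
                 threshold_used = NA_real_),
            class = "biomarker_network")
}

vattr_num <- function(g, nm) {
  if (nm %in% igraph::vertex_attr_names(g)) as.numeric(igraph::vertex_attr(g, nm))
  else rep(NA_real_, igraph::vcount(g))
}
vattr_chr <- function(g, nm) {
  if (nm %in% igraph::vertex_attr_names(g)) as.character(igraph::vertex_attr(g, nm))
  else rep(NA_character_, igraph::vcount(g))
}

#' Write annotation results to TSV
#'
#' One row per (feature, candidate); unannotated features keep a single row
#' with empty candidate fields and their MSI level (4).
#' @param ann an `annotation_result` from [annotate_features()].
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_result"))
  cand <- ann$candidates
  lev <- ann$msi_levels
  rows <- merge(lev, cand, by = "feature_id", all.x = TRUE, sort = FALSE)
  rows <- rows[order(match(rows$feature_id, lev$feature_id)), ]
  out <- data.frame(feature_id = rows$feature_id, mz = rows$mz,
                    adduct = rows$adduct, compound = rows$compound,
                    formula = rows$formula, class = rows$compound_class,
                    ppm_error = rows$ppm_error, msi_level = rows$msi_level)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
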