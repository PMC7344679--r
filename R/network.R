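#' Build the bipartite attribute-feature biomarker network
#'
#' One node per sensory attribute and per supra-threshold molecular feature;
#' an edge joins an attribute to a feature when the feature's VIP coefficient
#' in that attribute's sparse PLS model is strictly greater than the
#' threshold (default 1.0, the above-average-importance convention). Edge
#' weight is the VIP. Feature nodes appear only when incident to at least one
#' edge; attribute nodes are always kept, flagged when they have no
#' supra-threshold feature.
#'
#' @param vip_by_attribute named list (attribute -> named VIP vector) or a
#'   features x attributes matrix; all vectors must cover the same feature
#'   universe.
#' @param threshold VIP threshold; edges require `vip > threshold` (strict).
#'   `0` gives the every-positive-VIP variant.
#' @param feature_info optional data.frame with `feature_id`, `mz`, `rt` and
#'   optionally `annotation` (compound category), carried onto feature nodes.
#' @return a `biomarker_network` with `attributes`, `features`, `edges` and
#'   `threshold_used`.
#' @export
build_network <- function(vip_by_attribute, threshold = 1.0,
                          feature_info = NULL) {
  if (is.matrix(vip_by_attribute)) {
    vip_by_attribute <- stats::setNames(
      lapply(seq_len(ncol(vip_by_attribute)),
             function(j) vip_by_attribute[, j]),
      colnames(vip_by_attribute))
  }
  if (is.null(names(vip_by_attribute)))
    stop("vip_by_attribute must be named by attribute")
  universe <- names(vip_by_attribute[[1L]])
  if (is.null(universe)) stop("VIP vectors must be named by feature id")
  for (a in names(vip_by_attribute)) {
    if (!identical(names(vip_by_attribute[[a]]), universe))
      stop("VIP vector for attribute '", a,
           "' is over a different feature universe")
  }
  edges <- do.call(rbind, lapply(names(vip_by_attribute), function(a) {
    v <- vip_by_attribute[[a]]
    hit <- which(v > threshold)
    if (!length(hit)) return(NULL)
    data.frame(attribute = a, feature_id = universe[hit], vip = unname(v[hit]))
  }))
  if (is.null(edges))
    edges <- data.frame(attribute = character(0), feature_id = character(0),
                        vip = numeric(0))
  feat_ids <- unique(edges$feature_id)
  features <- data.frame(feature_id = feat_ids,
                         mz = rep(NA_real_, length(feat_ids)),
                         rt = rep(NA_real_, length(feat_ids)),
                         annotation = rep(NA_character_, length(feat_ids)))
  if (!is.null(feature_info) && nrow(features)) {
    m <- match(feat_ids, feature_info$feature_id)
    features$mz <- feature_info$mz[m]
    features$rt <- feature_info$rt[m]
    if ("annotation" %in% names(feature_info))
      features$annotation <- feature_info$annotation[m]
  }
  structure(list(
    attributes = data.frame(attribute = names(vip_by_attribute),
                            has_edges = names(vip_by_attribute) %in% edges$attribute),
    features = features, edges = edges, threshold_used = threshold),
    class = "biomarker_network")
}

#' @export
print.biomarker_network <- function(x, ...) {
  cat(sprintf("biomarker_network: %d attributes, %d features, %d edges (VIP > %g)\n",
              nrow(x$attributes), nrow(x$features), nrow(x$edges),
              x$threshold_used))
  invisible(x)
}

as_igraph <- function(net) {
  verts <- rbind(
    data.frame(name = net$attributes$attribute, type = "attribute",
               mz = NA_real_, rt = NA_real_, annotation = NA_character_),
    data.frame(name = net$features$feature_id, type = "feature",
               mz = net$features$mz, rt = net$features$rt,
               annotation = net$features$annotation))
  verts$annotation[is.na(verts$annotation)] <- ""
  el <- data.frame(from = net$edges$attribute, to = net$edges$feature_id,
                   weight = net$edges$vip)
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' Summarise a biomarker network's topology
#'
#' Connectivity is reported the way aroma vs taste networks are compared:
#' edges per attribute and the number of features shared by two or more
#' attributes, alongside node/edge counts, per-attribute degree and connected
#' components.
#'
#' @param net a `biomarker_network`.
#' @return list with `n_attributes`, `n_features`, `n_edges`,
#'   `degree_by_attribute`, `edges_per_attribute`, `n_components`,
#'   `n_shared_features`, `shared_by_pair` (attribute-pair shared-feature
#'   counts).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "biomarker_network"))
  deg <- table(factor(net$edges$attribute, levels = net$attributes$attribute))
  n_attr <- nrow(net$attributes)
  shared <- table(net$edges$feature_id)
  attrs <- net$attributes$attribute
  pair_counts <- if (length(attrs) >= 2L && nrow(net$edges)) {
    pairs <- utils::combn(attrs, 2L)
    by_attr <- split(net$edges$feature_id, net$edges$attribute)
    data.frame(attribute_a = pairs[1L, ], attribute_b = pairs[2L, ],
               n_shared = apply(pairs, 2L, function(pr) {
                 length(intersect(by_attr[[pr[1L]]], by_attr[[pr[2L]]]))
               }))
  } else {
    data.frame(attribute_a = character(0), attribute_b = character(0),
               n_shared = integer(0))
  }
  n_comp <- if (nrow(net$edges)) {
    igraph::count_components(as_igraph(net)) -
      sum(!net$attributes$has_edges)  # isolated attribute nodes not counted
  } else 0L
  list(n_attributes = n_attr, n_features = nrow(net$features),
       n_edges = nrow(net$edges),
       degree_by_attribute = stats::setNames(as.integer(deg), names(deg)),
       edges_per_attribute = if (n_attr) nrow(net$edges) / n_attr else 0,
       n_components = n_comp,
       n_shared_features = sum(shared >= 2L),
       shared_by_pair = pair_counts)
}
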