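#' Interaction networks and graph metrics
#'
#' Interacting drugs (or their ATC classes at rollup levels 1-3) are nodes; an
#' edge joins two nodes whenever at least one patient-level detection links
#' them, weighted by the number of such detections. At rollup levels a
#' detection whose two drugs fall in the same class is tallied as a self-pair,
#' not an edge; detections involving an unclassified drug are tallied as
#' unmapped. Edge weights + self-pairs + unmapped always add up to the number
#' of input detections.
#'
#' @name network
NULL

# map generic names to node labels at the requested level; NA = unmapped
node_labels <- function(drugs, level, annotation) {
  if (identical(level, "medication")) return(drugs)
  stopifnot(inherits(annotation, "atc_annotation"), level %in% 1:3)
  ann <- annotation$annotated
  col <- paste0("atc_level", level)
  map <- ann[!duplicated(ann$generic_name), c("generic_name", col)]
  map[[col]][match(drugs, map$generic_name)]
}

#' Build an interaction network
#'
#' @param detections detection data.frame from [detect_interactions()] (or the
#'   single-patient finders).
#' @param level `"medication"` or an ATC level 1-3.
#' @param annotation an `atc_annotation`; required for ATC levels.
#' @return list of class `interaction_network`: `level`, `nodes`, `edges`
#'   (data.frame `source`, `target`, `weight` with `source` < `target`),
#'   `self_pairs` (detections collapsing to one node), `unmapped` (detections
#'   involving an unclassified drug).
#' @export
build_network <- function(detections, level = "medication",
                          annotation = NULL) {
  la <- node_labels(detections$drug_a, level, annotation)
  lb <- node_labels(detections$drug_b, level, annotation)
  unmapped <- is.na(la) | is.na(lb)
  if (any(unmapped)) {
    message(sum(unmapped),
            " detection(s) involve an unclassified drug; routed to the ",
            "unmapped tally")
  }
  la2 <- la[!unmapped]
  lb2 <- lb[!unmapped]
  self <- la2 == lb2
  p <- canonical_pair(la2[!self], lb2[!self])
  edges <- if (length(p$a) > 0) {
    agg <- stats::aggregate(list(weight = rep(1L, length(p$a))),
                            by = list(source = p$a, target = p$b), FUN = sum)
    agg <- agg[order(agg$source, agg$target), , drop = FALSE]
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(source = character(0), target = character(0),
               weight = integer(0), stringsAsFactors = FALSE)
  }
  structure(list(
    level = level,
    nodes = sort(unique(c(edges$source, edges$target))),
    edges = edges,
    self_pairs = sum(self),
    unmapped = sum(unmapped)
  ), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "interaction_network (level %s): %d nodes, %d edges (%d self-pair, %d unmapped detections)\n",
    format(x$level), length(x$nodes), nrow(x$edges), x$self_pairs, x$unmapped))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[c("source", "target", "weight")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
}

#' Graph metrics of an interaction network
#'
#' Density is 2E / (N(N-1)) (0 when N < 2); the diameter is the longest
#' shortest path within the largest connected component (the network can split
#' into disconnected sub-networks, especially at medication level); triadic
#' closure is the global transitivity, 3 x triangles / connected triples. Mean
#' local clustering is reported as a secondary statistic since "triadic
#' closure" is sometimes read that way.
#'
#' @param network an `interaction_network`.
#' @return list of class `network_metrics`: `n_nodes`, `n_edges`, `density`,
#'   `diameter`, `triadic_closure`, `n_components`, `mean_local_clustering`,
#'   `component_diameters`.
#' @export
compute_metrics <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  n <- length(network$nodes)
  e <- nrow(network$edges)
  if (n == 0) {
    return(structure(list(
      n_nodes = 0L, n_edges = 0L, density = 0, diameter = NA_integer_,
      triadic_closure = 0, n_components = 0L, mean_local_clustering = 0,
      component_diameters = integer(0)
    ), class = "network_metrics"))
  }
  g <- as_igraph(network)
  comp <- igraph::components(g)
  comp_diam <- vapply(seq_len(comp$no), function(k) {
    sub <- igraph::induced_subgraph(g, which(comp$membership == k))
    if (igraph::vcount(sub) < 2) return(0L)
    d <- igraph::distances(sub, weights = NA)
    as.integer(max(d))
  }, integer(1))
  largest <- which.max(comp$csize)
  tc <- igraph::transitivity(g, type = "global")
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  structure(list(
    n_nodes = n,
    n_edges = e,
    density = if (n < 2) 0 else 2 * e / (n * (n - 1)),
    diameter = if (e >= 1) comp_diam[largest] else NA_integer_,
    triadic_closure = if (is.nan(tc)) 0 else tc,
    n_components = comp$no,
    mean_local_clustering = mean(local),
    component_diameters = comp_diam
  ), class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("%d nodes, %d edges in %d component(s)\n  density %.3f, diameter ",
           "%s, triadic closure %.3f\n"),
    x$n_nodes, x$n_edges, x$n_components, x$density,
    format(x$diameter), x$triadic_closure))
  invisible(x)
}

#' Chord-diagram occurrence matrix
#'
#' Aggregates detections to the requested level and returns the symmetric
#' pairwise occurrence-count matrix, zeroing pairs below `min_count` (the
#' published chord diagrams hide subgroup interactions below an occurrence
#' threshold).
#'
#' @inheritParams build_network
#' @param min_count minimum occurrence count for a pair to be retained
#'   (>= 1).
#' @return symmetric numeric matrix with sorted labels and zero diagonal.
#' @export
chord_matrix <- function(detections, level = 2, annotation = NULL,
                         min_count = 1) {
  if (min_count < 1) stop_("min_count must be >= 1")
  net <- build_network(detections, level, annotation)
  edges <- net$edges[net$edges$weight >= min_count, , drop = FALSE]
  labels <- sort(unique(c(edges$source, edges$target)))
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  if (nrow(edges) > 0) {
    i <- match(edges$source, labels)
    j <- match(edges$target, labels)
    m[cbind(i, j)] <- edges$weight
    m[cbind(j, i)] <- edges$weight
  }
  m
}

#' Write an edge list to CSV
#' @param network an `interaction_network`.
#' @param path output path.
#' @export
write_edge_list <- function(network, path) {
  utils::write.csv(network$edges, path, row.names = FALSE, quote = FALSE)
}

#' Write a chord matrix to CSV (labels as header row and first column)
#' @param m matrix from [chord_matrix()].
#' @param path output path.
#' @export
write_chord_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
}
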