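#' Intersect component targets with disease genes
#'
#' Deterministic sorted intersection of two symbol sets (both normalized to
#' uppercase), the "common targets" step linking a formula's predicted
#' targets to the disease transcriptome.
#'
#' @param componentTargets character vector of component target symbols.
#' @param degs character vector of differentially expressed gene symbols.
#' @return sorted character vector of shared symbols.
#' @export
commonTargets <- function(componentTargets, degs) {
  sort(intersect(unique(normalizeSymbols(componentTargets)),
                 unique(normalizeSymbols(degs))))
}

#' Build the component-target bipartite network
#'
#' Induces the bipartite subgraph of a component-to-target map on the given
#' component and target node sets. Edges run only between the two parts; a
#' symbol appearing in both parts is a hard error.
#'
#' @param map data.frame with columns `mol_id`, `target` (see
#'   [readTargetMap()]).
#' @param components component ids to keep (default: all in the map).
#' @param targets target symbols to keep (default: all in the map).
#' @return a [GeneNetwork-class] whose graph carries a logical vertex
#'   attribute `is_component`; `meta` records the part sizes.
#' @export
buildBipartite <- function(map, components = NULL, targets = NULL) {
  stopifnot(all(c("mol_id", "target") %in% names(map)))
  map$target <- normalizeSymbols(map$target)
  map$mol_id <- as.character(map$mol_id)
  components <- unique(as.character(components %||% map$mol_id))
  targets <- unique(normalizeSymbols(targets %||% map$target))
  both <- intersect(components, targets)
  if (length(both))
    stop("symbol(s) present in both parts: ", paste(both, collapse = ", "))
  keep <- map$mol_id %in% components & map$target %in% targets
  edges <- unique(map[keep, c("mol_id", "target"), drop = FALSE])
  edges <- edges[order(edges$mol_id, edges$target), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = c(components, targets),
                          is_component = rep(c(TRUE, FALSE),
                                             c(length(components), length(targets)))))
  GeneNetwork(igraph::simplify(g),
              meta = list(n_components = length(components),
                          n_targets = length(targets),
                          n_edges = nrow(edges)))
}

#' Rank targets of a bipartite network by degree
#'
#' Targets sorted by descending degree (number of components hitting them),
#' ties broken alphabetically; the "most frequently targeted" summary.
#'
#' @param net a bipartite [GeneNetwork-class] from [buildBipartite()].
#' @param k number of targets to return (default all).
#' @return data.frame with columns `target`, `degree`.
#' @export
targetDegreeRanking <- function(net, k = Inf) {
  stopifnot(is(net, "GeneNetwork"), k >= 0)
  g <- net@graph
  isComp <- igraph::V(g)$is_component
  if (is.null(isComp)) stop("network is not bipartite (built by buildBipartite)")
  tnames <- igraph::V(g)$name[!isComp]
  deg <- igraph::degree(g)[!isComp]
  out <- data.frame(target = tnames, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$target), , drop = FALSE]
  rownames(out) <- NULL
  head(out, min(k, nrow(out)))
}
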