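#' Load a protein-protein interaction network from an edge list
#'
#' Symbols are uppercase-normalized, self-loops dropped (count reported as a
#' message) and duplicate edges collapsed, yielding a simple undirected
#' graph.
#'
#' @param edges two-column data.frame (`from`, `to`) or a path readable by
#'   [readNetworkEdges()].
#' @return a [GeneNetwork-class].
#' @export
loadNetwork <- function(edges) {
  if (is.character(edges) && length(edges) == 1) edges <- readNetworkEdges(edges)
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  from <- normalizeSymbols(edges[[1]])
  to <- normalizeSymbols(edges[[2]])
  loops <- from == to
  if (any(loops))
    message("dropped ", sum(loops), " self-loop record(s)")
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[!loops], to = to[!loops]), directed = FALSE)
  g <- igraph::simplify(g)
  GeneNetwork(g, meta = list(self_loops_dropped = sum(loops)))
}

#' Annotate a network with node centralities
#'
#' DC is the node degree; BC is unnormalized shortest-path betweenness
#' (Brandes accumulation: each unordered pair counted once, equal-length
#' shortest paths split evenly, endpoints excluded); CC is closeness
#' computed within each connected component,
#' `(reachable)/(sum of distances to reachable nodes)` normalized so an
#' isolated node gets `NA`.
#'
#' @param net a [GeneNetwork-class].
#' @return the network with its `centralities` slot filled.
#' @export
computeCentralities <- function(net) {
  stopifnot(is(net, "GeneNetwork"))
  g <- net@graph
  if (igraph::vcount(g) == 0) {
    net@centralities <- data.frame(node = character(), DC = numeric(),
                                   BC = numeric(), CC = numeric())
    return(net)
  }
  dc <- igraph::degree(g)
  bc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  d <- igraph::distances(g)
  cc <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (!length(reach)) NA_real_ else length(reach) / sum(reach)
  }, numeric(1))
  net@centralities <- data.frame(node = igraph::V(g)$name,
                                 DC = as.numeric(dc), BC = as.numeric(bc),
                                 CC = cc, stringsAsFactors = FALSE)
  validObject(net)
  net
}

inducedNetwork <- function(net, keep, meta) {
  sub <- igraph::induced_subgraph(net@graph, igraph::V(net@graph)[keep])
  GeneNetwork(sub, meta = c(net@meta, meta))
}

#' Double-median-degree subnetwork screen
#'
#' Stage 1 of the topological cascade: keep nodes whose degree strictly
#' exceeds `multiplier x median(degree)` (or a fixed `absolute` threshold
#' when one is supplied, mirroring published cut-offs such as DMD > 57)
#' and return the induced subnetwork. The threshold used is recorded in the
#' result's `meta`.
#'
#' @param net a [GeneNetwork-class].
#' @param multiplier factor applied to the median degree (default 2).
#' @param absolute optional fixed threshold overriding the median rule.
#' @return the induced [GeneNetwork-class] subnetwork.
#' @export
dmdScreen <- function(net, multiplier = 2, absolute = NULL) {
  stopifnot(is(net, "GeneNetwork"))
  deg <- igraph::degree(net@graph)
  thr <- absolute %||% (multiplier * median(deg))
  inducedNetwork(net, deg > thr,
                 list(dmd_threshold = thr,
                      dmd_mode = if (is.null(absolute)) "median" else "absolute"))
}

#' Degree + betweenness core screen
#'
#' Stage 2 of the cascade: degree and betweenness are recomputed on the
#' subnetwork (stage-wise, the way interactive network tools operate), then
#' nodes with `DC > dcMin` and `BC > bcMin` (both strict) are kept and the
#' induced subgraph returned. Passing `NULL` switches a threshold to its
#' relative form: `dcMin = NULL` reapplies the double-median-degree rule on
#' the subnetwork and `bcMin = NULL` means BC > 0 (the node must lie on at
#' least one shortest path). The relative form is the scale-free choice for
#' networks far smaller than the published interactomes.
#'
#' @param net a [GeneNetwork-class] (typically a [dmdScreen()] output).
#' @param dcMin degree threshold (strict), or `NULL` for `2 x median(DC)`.
#' @param bcMin betweenness threshold (strict), or `NULL` for 0.
#' @param recompute recompute centralities on `net` before thresholding
#'   (default TRUE); set FALSE to reuse annotations already present.
#' @return the induced core [GeneNetwork-class].
#' @export
coreScreen <- function(net, dcMin = 60, bcMin = 645, recompute = TRUE) {
  stopifnot(is(net, "GeneNetwork"))
  if (recompute || !nrow(net@centralities)) net <- computeCentralities(net)
  cn <- net@centralities
  # align annotation order with the vertex order
  cn <- cn[match(igraph::V(net@graph)$name, cn$node), , drop = FALSE]
  dcThr <- dcMin %||% (2 * median(cn$DC))
  bcThr <- bcMin %||% 0
  keep <- cn$DC > dcThr & cn$BC > bcThr
  out <- inducedNetwork(net, keep,
                        list(dc_threshold = dcThr, bc_threshold = bcThr))
  out
}

#' Run the full two-stage topological screening cascade
#'
#' @param net a [GeneNetwork-class] (the rudimentary network).
#' @param dmdMultiplier,dmdAbsolute stage-1 parameters (see [dmdScreen()]).
#' @param dcMin,bcMin stage-2 parameters (see [coreScreen()]).
#' @return list with `report` (the stage table from [screenReport()]),
#'   `subnetwork` and `core` ([GeneNetwork-class] objects).
#' @export
screenCascade <- function(net, dmdMultiplier = 2, dmdAbsolute = NULL,
                          dcMin = 60, bcMin = 645) {
  sub <- dmdScreen(net, multiplier = dmdMultiplier, absolute = dmdAbsolute)
  core <- coreScreen(sub, dcMin = dcMin, bcMin = bcMin)
  report <- screenReport(list(input = net, subnetwork = sub, core = core))
  list(report = report, subnetwork = sub, core = core)
}

#' Machine-readable screening report
#'
#' Per-stage node/edge counts plus the threshold each stage applied. Counts
#' must be non-increasing along the cascade; a violation is an error.
#'
#' @param stages named list of [GeneNetwork-class] objects in cascade order.
#' @return data.frame with columns `stage`, `nodes`, `edges`, `threshold`.
#' @export
screenReport <- function(stages) {
  stopifnot(length(stages) >= 1, !is.null(names(stages)))
  rows <- lapply(seq_along(stages), function(i) {
    net <- stages[[i]]
    stopifnot(is(net, "GeneNetwork"))
    m <- net@meta
    thr <- if (!is.null(m$bc_threshold))
      sprintf("DC > %g & BC > %g", m$dc_threshold, m$bc_threshold)
    else if (!is.null(m$dmd_threshold))
      sprintf("DC > %g (%s)", m$dmd_threshold, m$dmd_mode)
    else NA_character_
    data.frame(stage = names(stages)[i],
               nodes = igraph::vcount(net@graph),
               edges = igraph::ecount(net@graph),
               threshold = thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(diff(out$nodes) > 0) || any(diff(out$edges) > 0))
    stop("stage counts must be non-increasing along the cascade")
  out
}

#' Write a centrality table as TSV
#' @param net an annotated [GeneNetwork-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCentralityTable <- function(net, path) {
  stopifnot(is(net, "GeneNetwork"))
  writeTSV(nodeCentralities(net), path)
}
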