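#' S4 containers for the screening pipeline
#'
#' @name herbnet-classes
#' @keywords internal
NULL

# ---- ComponentTable ---------------------------------------------------------

#' Table of herbal-medicine components with ADME properties
#'
#' Holds one row per unique molecule: identifier, name, drug-likeness (DL),
#' octanol-water partition coefficient (AlogP), oral bioavailability in
#' percent (OB), half-life in hours (HL) and the herb(s) the molecule occurs
#' in (semicolon-separated when more than one).
#'
#' @slot components data.frame with columns `mol_id`, `name`, `DL`, `OB` and
#'   optionally `AlogP`, `HL`, `herbs`.
#' @export
setClass("ComponentTable", slots = c(components = "data.frame"))

setValidity("ComponentTable", function(object) {
  df <- object@components
  msgs <- character()
  need <- c("mol_id", "name", "DL", "OB")
  miss <- setdiff(need, names(df))
  if (length(miss))
    msgs <- c(msgs, paste("missing column(s):", paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    if (anyDuplicated(df$mol_id))
      msgs <- c(msgs, "mol_id values must be unique")
    if (any(df$OB < 0, na.rm = TRUE)) msgs <- c(msgs, "OB must be >= 0")
    if (any(df$DL < 0, na.rm = TRUE)) msgs <- c(msgs, "DL must be >= 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ComponentTable
#'
#' @param components data.frame with at least `mol_id`, `name`, `DL`, `OB`;
#'   optional `AlogP`, `HL`, `herbs`.
#' @return A [ComponentTable-class] object; row order is preserved.
#' @export
ComponentTable <- function(components) {
  df <- as.data.frame(components, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(df$mol_id)) df$mol_id <- as.character(df$mol_id)
  new("ComponentTable", components = df)
}

#' @describeIn ComponentTable underlying data.frame
#' @param x,object a `ComponentTable`
#' @export
componentData <- function(x) {
  stopifnot(is(x, "ComponentTable"))
  x@components
}

#' @export
setMethod("length", "ComponentTable", function(x) nrow(x@components))

setMethod("show", "ComponentTable", function(object) {
  df <- object@components
  cat(sprintf("ComponentTable with %d component(s)\n", nrow(df)))
  if (nrow(df)) {
    cat(sprintf("  DL range: [%g, %g]   OB range: [%g, %g]%%\n",
                min(df$DL, na.rm = TRUE), max(df$DL, na.rm = TRUE),
                min(df$OB, na.rm = TRUE), max(df$OB, na.rm = TRUE)))
  }
})

# ---- GeneNetwork ------------------------------------------------------------

#' Undirected simple graph of gene/protein symbols
#'
#' Wraps an [igraph::igraph] guaranteed simple (no loops or multi-edges) and
#' undirected, with optional per-node centrality annotations (DC = degree,
#' BC = unnormalized betweenness, CC = within-component closeness) and a
#' free-form metadata list recording screening thresholds.
#'
#' @slot graph an undirected simple `igraph` with named vertices.
#' @slot centralities data.frame with columns `node`, `DC`, `BC`, `CC`
#'   (zero rows until [computeCentralities()] is called).
#' @slot meta list of provenance/threshold records.
#' @export
setClass("GeneNetwork",
         slots = c(graph = "ANY", centralities = "data.frame", meta = "list"),
         prototype = prototype(
           centralities = data.frame(node = character(), DC = numeric(),
                                     BC = numeric(), CC = numeric()),
           meta = list()))

setValidity("GeneNetwork", function(object) {
  g <- object@graph
  msgs <- character()
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    msgs <- c(msgs, "vertices must be named")
  if (igraph::any_loop(g) || igraph::any_multiple(g))
    msgs <- c(msgs, "graph must be simple (no self-loops or multi-edges)")
  cn <- object@centralities
  if (nrow(cn) && !setequal(cn$node, igraph::V(g)$name))
    msgs <- c(msgs, "centrality annotations must cover exactly the node set")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneNetwork from an igraph
#' @param graph undirected simple igraph with named vertices
#' @param meta optional provenance list
#' @return a [GeneNetwork-class]
#' @export
GeneNetwork <- function(graph, meta = list()) {
  new("GeneNetwork", graph = graph, meta = meta)
}

#' @describeIn GeneNetwork node symbols (sorted igraph order)
#' @param x a `GeneNetwork`
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  as.character(igraph::V(x@graph)$name)
}

#' @describeIn GeneNetwork two-column data.frame of edges
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  el <- igraph::as_edgelist(x@graph)
  data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
}

#' @describeIn GeneNetwork per-node centrality table (empty until computed)
#' @export
nodeCentralities <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  x@centralities
}

#' @describeIn GeneNetwork provenance / threshold metadata
#' @export
networkMeta <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  x@meta
}

setMethod("show", "GeneNetwork", function(object) {
  g <- object@graph
  cat(sprintf("GeneNetwork: %d node(s), %d edge(s)%s\n",
              igraph::vcount(g), igraph::ecount(g),
              if (nrow(object@centralities)) " [centralities annotated]" else ""))
})

# ---- GeneSetCollection ------------------------------------------------------

#' Collection of categorized gene sets
#'
#' @slot sets named list (by set id) of character vectors of member symbols.
#' @slot info data.frame with columns `set_id`, `name`, `category`
#'   (category one of BP, CC, MF, KEGG, custom).
#' @export
setClass("GeneSetCollection",
         slots = c(sets = "list", info = "data.frame"))

setValidity("GeneSetCollection", function(object) {
  msgs <- character()
  ids <- names(object@sets)
  if (length(object@sets)) {
    if (is.null(ids) || anyDuplicated(ids))
      msgs <- c(msgs, "set ids must be unique and non-empty")
    if (any(!vapply(object@sets, length, 1L)))
      msgs <- c(msgs, "gene sets must be nonempty")
  }
  info <- object@info
  if (!all(c("set_id", "name", "category") %in% names(info)))
    msgs <- c(msgs, "info must have set_id, name, category columns")
  else if (!setequal(info$set_id, ids))
    msgs <- c(msgs, "info rows must match set ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetCollection
#' @param sets named list of character vectors (member symbols)
#' @param names optional display names (defaults to set ids)
#' @param categories per-set category in BP/CC/MF/KEGG/custom (recycled)
#' @return a [GeneSetCollection-class]
#' @export
GeneSetCollection <- function(sets, names = NULL, categories = "custom") {
  ids <- base::names(sets)
  info <- data.frame(set_id = ids %||% character(),
                     name = names %||% ids %||% character(),
                     category = if (length(sets)) rep_len(categories, length(sets)) else character(),
                     stringsAsFactors = FALSE)
  new("GeneSetCollection", sets = lapply(sets, normalizeSymbols), info = info)
}

#' @describeIn GeneSetCollection named list of member vectors
#' @param x a `GeneSetCollection`
#' @export
geneSets <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@sets
}

#' @describeIn GeneSetCollection set metadata table
#' @export
geneSetInfo <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@info
}

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d set(s)", length(object@sets)))
  if (length(object@sets)) {
    tab <- table(object@info$category)
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")", sep = "")
  }
  cat("\n")
})

# ---- EnrichmentResult -------------------------------------------------------

#' Over-representation analysis result
#'
#' One row per tested gene set with the hypergeometric overlap statistics:
#' overlap count `k`, set size in the universe `K`, query size `n`, universe
#' size `N`, raw and BH-adjusted p-values (adjusted within category), the
#' overlapping symbols and a significance flag at the configured threshold.
#'
#' @slot table per-set data.frame, sorted ascending by adjusted p.
#' @slot pThresh adjusted-p significance threshold used for the flag.
#' @export
setClass("EnrichmentResult",
         slots = c(table = "data.frame", pThresh = "numeric"))

setValidity("EnrichmentResult", function(object) {
  tb <- object@table
  msgs <- character()
  need <- c("set_id", "name", "category", "k", "K", "n", "N", "p", "p_adjust",
            "overlap", "significant")
  if (!all(need %in% names(tb)))
    msgs <- c(msgs, "result table missing required columns")
  else if (nrow(tb)) {
    if (any(tb$k > pmin(tb$K, tb$n))) msgs <- c(msgs, "k must be <= min(K, n)")
    if (any(tb$p < 0 | tb$p > 1 | tb$p_adjust < 0 | tb$p_adjust > 1))
      msgs <- c(msgs, "p-values must lie in [0, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn EnrichmentResult full per-set table
#' @param x,object an `EnrichmentResult`
#' @export
enrichmentTable <- function(x) {
  stopifnot(is(x, "EnrichmentResult"))
  x@table
}

#' @describeIn EnrichmentResult rows significant at the configured threshold
#' @export
significantTerms <- function(x) {
  stopifnot(is(x, "EnrichmentResult"))
  x@table[x@table$significant, , drop = FALSE]
}

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: %d set(s) tested, %d significant at adjusted p < %g\n",
              nrow(object@table), sum(object@table$significant), object@pThresh))
})

# ---- GseaResult -------------------------------------------------------------

#' Preranked GSEA result for one gene set
#'
#' @slot es enrichment score (maximum-magnitude running-sum deviation).
#' @slot nes ES normalized by the mean |ES| of the sign-matched permutation null.
#' @slot pValue nominal permutation p-value, add-one estimator.
#' @slot leadingEdge symbols driving the ES extremum.
#' @slot setSize number of set members present in the ranking.
#' @slot nPerm number of gene-label permutations used.
#' @export
setClass("GseaResult",
         slots = c(es = "numeric", nes = "numeric", pValue = "numeric",
                   leadingEdge = "character", setSize = "integer",
                   nPerm = "integer"))

setValidity("GseaResult", function(object) {
  msgs <- character()
  if (abs(object@es) > 1 + 1e-12) msgs <- c(msgs, "|ES| must be <= 1")
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "p-value must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GseaResult", function(object) {
  cat(sprintf("GseaResult: ES = %.4f, NES = %.4f, p = %.4g (set size %d, %d permutations)\n",
              object@es, object@nes, object@pValue, object@setSize, object@nPerm))
})

#' @describeIn GseaResult enrichment score
#' @param x a `GseaResult`
#' @export
gseaES <- function(x) { stopifnot(is(x, "GseaResult")); x@es }

#' @describeIn GseaResult normalized enrichment score
#' @export
gseaNES <- function(x) { stopifnot(is(x, "GseaResult")); x@nes }

#' @describeIn GseaResult nominal permutation p-value
#' @export
gseaPValue <- function(x) { stopifnot(is(x, "GseaResult")); x@pValue }

#' @describeIn GseaResult leading-edge symbols
#' @export
leadingEdge <- function(x) { stopifnot(is(x, "GseaResult")); x@leadingEdge }

# ---- SyntheticTruth ---------------------------------------------------------

#' Ground-truth ledger for synthetic pipeline inputs
#'
#' Each generator fills the slots it controls and leaves the rest empty, so
#' ledgers from several generators can be merged with [mergeTruth()].
#'
#' @slot passingComponents mol_ids planted to pass the OB/DL filter.
#' @slot degUp,degDown symbols planted as up-/down-regulated (disjoint).
#' @slot coreNodes symbols of the planted dense subgraph.
#' @slot enrichedSets ids of the gene sets planted as over-represented.
#' @slot pairCorrelations data.frame `gene_a`, `gene_b`, `rho` of planted
#'   bivariate-normal correlations.
#' @export
setClass("SyntheticTruth",
         slots = c(passingComponents = "character",
                   degUp = "character", degDown = "character",
                   coreNodes = "character", enrichedSets = "character",
                   pairCorrelations = "data.frame"),
         prototype = prototype(
           passingComponents = character(), degUp = character(),
           degDown = character(), coreNodes = character(),
           enrichedSets = character(),
           pairCorrelations = data.frame(gene_a = character(),
                                         gene_b = character(),
                                         rho = numeric())))

setValidity("SyntheticTruth", function(object) {
  msgs <- character()
  if (length(intersect(object@degUp, object@degDown)))
    msgs <- c(msgs, "up- and down-regulated truth sets must be disjoint")
  pc <- object@pairCorrelations
  if (nrow(pc) && any(abs(pc$rho) >= 1))
    msgs <- c(msgs, "planted correlations must lie strictly inside (-1, 1)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:\n")
  cat(sprintf("  passing components: %d\n", length(object@passingComponents)))
  cat(sprintf("  DE genes: %d up, %d down\n",
              length(object@degUp), length(object@degDown)))
  cat(sprintf("  planted core nodes: %d\n", length(object@coreNodes)))
  cat(sprintf("  enriched sets: %d\n", length(object@enrichedSets)))
  cat(sprintf("  planted correlation pairs: %d\n", nrow(object@pairCorrelations)))
})

#' Merge ground-truth ledgers from several generators
#' @param ... `SyntheticTruth` objects
#' @return one combined [SyntheticTruth-class]
#' @export
mergeTruth <- function(...) {
  truths <- list(...)
  stopifnot(all(vapply(truths, is, TRUE, "SyntheticTruth")))
  new("SyntheticTruth",
      passingComponents = unique(unlist(lapply(truths, slot, "passingComponents"))) %||% character(),
      degUp = unique(unlist(lapply(truths, slot, "degUp"))) %||% character(),
      degDown = unique(unlist(lapply(truths, slot, "degDown"))) %||% character(),
      coreNodes = unique(unlist(lapply(truths, slot, "coreNodes"))) %||% character(),
      enrichedSets = unique(unlist(lapply(truths, slot, "enrichedSets"))) %||% character(),
      pairCorrelations = do.call(rbind, c(lapply(truths, slot, "pairCorrelations"),
                                          list(data.frame(gene_a = character(),
                                                          gene_b = character(),
                                                          rho = numeric())))))
}

#' Accessors for SyntheticTruth slots
#' @param x a `SyntheticTruth`
#' @name truth-accessors
NULL

#' @rdname truth-accessors
#' @export
truthPassingComponents <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@passingComponents }

#' @rdname truth-accessors
#' @export
truthDegUp <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@degUp }

#' @rdname truth-accessors
#' @export
truthDegDown <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@degDown }

#' @rdname truth-accessors
#' @export
truthCoreNodes <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@coreNodes }

#' @rdname truth-accessors
#' @export
truthEnrichedSets <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@enrichedSets }

#' @rdname truth-accessors
#' @export
truthPairCorrelations <- function(x) { stopifnot(is(x, "SyntheticTruth")); x@pairCorrelations }

# ---- HubReport --------------------------------------------------------------

#' Hub-target selection report
#'
#' `coreActiveTargets` is the intersection of the PPI core network with the
#' formula's component targets; `hubTargets` further intersects with the
#' disease-pathway gene set. Provenance records, per symbol, which of the
#' three input sets it belongs to.
#'
#' @slot coreActiveTargets sorted symbols in core network AND drug targets.
#' @slot hubTargets sorted symbols additionally in the pathway gene set.
#' @slot provenance data.frame `symbol`, `in_core`, `in_drug_targets`,
#'   `in_pathways`.
#' @export
setClass("HubReport",
         slots = c(coreActiveTargets = "character", hubTargets = "character",
                   provenance = "data.frame"))

setValidity("HubReport", function(object) {
  if (!all(object@hubTargets %in% object@coreActiveTargets))
    "hub targets must be a subset of core active targets"
  else TRUE
})

setMethod("show", "HubReport", function(object) {
  cat(sprintf("HubReport: %d core active target(s), %d hub target(s)\n",
              length(object@coreActiveTargets), length(object@hubTargets)))
  if (length(object@hubTargets))
    cat("  hubs:", paste(object@hubTargets, collapse = ", "), "\n")
})

#' @describeIn HubReport core-network targets hit by the formula
#' @param x a `HubReport`
#' @export
coreActiveTargets <- function(x) { stopifnot(is(x, "HubReport")); x@coreActiveTargets }

#' @describeIn HubReport final hub targets (also pathway members)
#' @export
hubTargets <- function(x) { stopifnot(is(x, "HubReport")); x@hubTargets }

#' @describeIn HubReport per-symbol membership provenance
#' @export
hubProvenance <- function(x) { stopifnot(is(x, "HubReport")); x@provenance }
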