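#' Upper-tail hypergeometric overlap probability
#'
#' `P(X >= k)` for the overlap of an `n`-gene query with a `K`-member set
#' drawn without replacement from an `N`-gene universe; the raw p-value of
#' over-representation analysis. `k = 0` gives exactly 1.
#'
#' @param k observed overlap count.
#' @param K set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail probability (vectorized over the arguments).
#' @export
hyperTail <- function(k, K, n, N) {
  ifelse(k <= 0, 1, phyper(k - 1, K, N - K, n, lower.tail = FALSE))
}

#' Over-representation analysis (hypergeometric test with BH control)
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under hypergeometric sampling from the universe:
#' `p = P(X >= k)` with `N` universe genes, `K` set members in the universe
#' and `n` query genes. Benjamini-Hochberg adjustment is applied within
#' each category (BP/CC/MF/KEGG/custom separately, matching per-category
#' reporting conventions). The universe defaults to the union of all set
#' members; query symbols outside the universe are dropped with a warning.
#'
#' @param query character vector of gene symbols.
#' @param collection a [GeneSetCollection-class].
#' @param universe optional character vector of background symbols.
#' @param pThresh adjusted-p significance threshold (default 0.05).
#' @return an [EnrichmentResult-class], sorted ascending by adjusted p
#'   (ties by raw p then set id).
#' @export
ora <- function(query, collection, universe = NULL, pThresh = 0.05) {
  stopifnot(is(collection, "GeneSetCollection"))
  sets <- geneSets(collection)
  info <- geneSetInfo(collection)
  universe <- unique(normalizeSymbols(universe %||% unlist(sets)))
  if (!length(universe)) stop("universe must be nonempty")
  query <- unique(normalizeSymbols(query))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query symbol(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_along(sets), function(i) {
    members <- intersect(sets[[i]], universe)
    ov <- intersect(query, members)
    k <- length(ov); K <- length(members)
    p <- hyperTail(k, K, n, N)
    data.frame(set_id = info$set_id[i], name = info$name[i],
               category = info$category[i], k = k, K = K, n = n, N = N,
               p = p, stringsAsFactors = FALSE,
               overlap = I(list(sort(ov))))
  })
  tb <- do.call(rbind, rows)
  if (is.null(tb))
    tb <- data.frame(set_id = character(), name = character(),
                     category = character(), k = integer(), K = integer(),
                     n = integer(), N = integer(), p = numeric(),
                     overlap = I(list()))
  tb$p_adjust <- numeric(nrow(tb))
  for (cat in unique(tb$category))
    tb$p_adjust[tb$category == cat] <- bhAdjust(tb$p[tb$category == cat])
  tb$significant <- tb$p_adjust < pThresh
  tb <- tb[order(tb$p_adjust, tb$p, tb$set_id), , drop = FALSE]
  rownames(tb) <- NULL
  new("EnrichmentResult", table = tb, pThresh = pThresh)
}

#' Top enriched terms per category
#'
#' The first `n` significant sets of each category, in the ORA sort order.
#'
#' @param result an [EnrichmentResult-class].
#' @param n terms per category (default 10).
#' @return data.frame of at most `n` rows per category.
#' @export
topTerms <- function(result, n = 10) {
  stopifnot(is(result, "EnrichmentResult"), n >= 0)
  sig <- significantTerms(result)
  out <- do.call(rbind, lapply(split(sig, sig$category),
                               function(d) head(d, min(n, nrow(d)))))
  if (is.null(out)) out <- sig[integer(), , drop = FALSE]
  out <- out[order(out$p_adjust, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Term-gene membership edges of the significant sets
#'
#' One edge per overlapping symbol per significant set, in deterministic
#' (set id, gene) order. The union of the `gene` column over the KEGG-like
#' category defines the pathway gene set consumed by hub selection.
#'
#' @param result an [EnrichmentResult-class].
#' @return data.frame with columns `set_id`, `gene`.
#' @export
geneTermEdges <- function(result) {
  stopifnot(is(result, "EnrichmentResult"))
  sig <- significantTerms(result)
  if (!nrow(sig))
    return(data.frame(set_id = character(), gene = character(),
                      stringsAsFactors = FALSE))
  out <- data.frame(set_id = rep(sig$set_id, lengths(sig$overlap)),
                    gene = unlist(sig$overlap),
                    stringsAsFactors = FALSE)
  out <- out[order(out$set_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an ORA result table as TSV
#' @param result an [EnrichmentResult-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeEnrichmentTable <- function(result, path) {
  tb <- enrichmentTable(result)
  tb$overlap <- vapply(tb$overlap, paste, "", collapse = ";")
  writeTSV(tb, path)
}
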