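#' Per-gene log2 fold change (case minus control)
#'
#' Values are assumed to be on the log2 scale already, so the fold change is
#' the simple difference of group means. A value range suggesting raw
#' intensities (max > 30) triggers a warning.
#'
#' @param se a `SummarizedExperiment` from [makeExpressionMatrix()].
#' @return named numeric vector of log2 fold changes, one per gene.
#' @export
log2FoldChange <- function(se) {
  grp <- sampleGroups(se)
  if (is.null(grp)) stop("colData must carry a 'group' column")
  if (!any(grp == "case") || !any(grp == "control"))
    stop("both groups must contain at least one sample")
  mat <- exprValues(se)
  if (max(mat) > 30)
    warning("expression values exceed 30; input may not be log2-transformed")
  rowMeans(mat[, grp == "case", drop = FALSE]) -
    rowMeans(mat[, grp == "control", drop = FALSE])
}

rowVarsLocal <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Per-gene Welch two-sample test
#'
#' Two-sided Welch t-test of case versus control for every gene, vectorized
#' across the matrix. Degenerate genes follow fixed conventions: zero
#' variance in both groups with equal means gives p = 1; unequal means with
#' zero variance in both groups gives p = 0 with a warning.
#'
#' @param se a `SummarizedExperiment` from [makeExpressionMatrix()].
#' @return named numeric vector of raw two-sided p-values.
#' @export
geneWelchTest <- function(se) {
  grp <- checkTwoGroups(se)
  mat <- exprValues(se)
  x <- mat[, grp == "case", drop = FALSE]
  y <- mat[, grp == "control", drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowVarsLocal(x); v2 <- rowVarsLocal(y)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m2)
    p[eq] <- 1
    if (any(degen & !eq)) {
      warning("zero within-group variance with unequal means; p set to 0 for ",
              sum(degen & !eq), " gene(s)")
      p[degen & !eq] <- 0
    }
  }
  setNames(p, rownames(mat))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, order-preserving against the
#' input indexing and capped at 1.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values (q-values) in input order.
#' @export
bhAdjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Full differential-expression table
#'
#' Combines [log2FoldChange()], [geneWelchTest()] and [bhAdjust()] and
#' labels each gene `up`, `down` or `none` under strict thresholds
#' (|log2FC| > `lfcThresh` and q < `qThresh`).
#'
#' @param se a `SummarizedExperiment` from [makeExpressionMatrix()].
#' @param lfcThresh log2 fold-change threshold (strict; default 1).
#' @param qThresh adjusted-p threshold (strict; default 0.05).
#' @return data.frame with columns `gene`, `log2FC`, `p`, `q`, `direction`.
#' @export
runDEG <- function(se, lfcThresh = 1, qThresh = 0.05) {
  stopifnot(lfcThresh > 0, qThresh > 0)
  lfc <- log2FoldChange(se)
  p <- geneWelchTest(se)
  q <- bhAdjust(p)
  direction <- rep("none", length(lfc))
  direction[lfc > lfcThresh & q < qThresh] <- "up"
  direction[lfc < -lfcThresh & q < qThresh] <- "down"
  data.frame(gene = names(lfc), log2FC = unname(lfc), p = unname(p),
             q = unname(q), direction = direction, stringsAsFactors = FALSE)
}

#' Call differentially expressed gene sets
#'
#' Strict thresholds on both axes: `up` requires log2FC > `lfcThresh` and
#' q < `qThresh`; `down` requires log2FC < -`lfcThresh` and q < `qThresh`.
#' A gene sitting exactly on a threshold is not selected.
#'
#' @param deg data.frame from [runDEG()] (columns `gene`, `log2FC`, `q`).
#' @param lfcThresh,qThresh strict thresholds (> 0).
#' @return list with sorted character vectors `up` and `down`.
#' @export
callDEGs <- function(deg, lfcThresh = 1, qThresh = 0.05) {
  stopifnot(lfcThresh > 0, qThresh > 0)
  up <- deg$gene[deg$log2FC > lfcThresh & deg$q < qThresh]
  down <- deg$gene[deg$log2FC < -lfcThresh & deg$q < qThresh]
  list(up = sort(up), down = sort(down))
}

#' Most significant differentially expressed genes
#'
#' Among called DEGs only, sorts ascending by q, then ascending raw p, then
#' descending |log2FC|, then symbol, and returns the first `n`.
#'
#' @param deg data.frame from [runDEG()].
#' @param n number of genes to return (default 100).
#' @param lfcThresh,qThresh thresholds defining the DEG set.
#' @return character vector of at most `n` gene symbols.
#' @export
topBySignificance <- function(deg, n = 100, lfcThresh = 1, qThresh = 0.05) {
  stopifnot(n >= 0)
  sets <- callDEGs(deg, lfcThresh, qThresh)
  sub <- deg[deg$gene %in% c(sets$up, sets$down), , drop = FALSE]
  ord <- order(sub$q, sub$p, -abs(sub$log2FC), sub$gene)
  head(sub$gene[ord], min(n, nrow(sub)))
}

#' Write a DEG table (volcano-ready) as TSV
#' @param deg data.frame from [runDEG()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeDEGTable <- function(deg, path) {
  writeTSV(deg, path)
}
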