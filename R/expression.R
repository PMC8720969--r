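#' Build a two-group expression container
#'
#' Expression data travel through the pipeline as a
#' [SummarizedExperiment::SummarizedExperiment] with one assay `"log2expr"`
#' (genes x samples, log2 scale) and a `group` column in `colData` with
#' levels `control` and `case`.
#'
#' @param values numeric matrix of log2 intensities, rownames = gene symbols,
#'   colnames = sample ids.
#' @param groups character/factor of per-sample labels, values in
#'   `c("case", "control")`.
#' @return a `SummarizedExperiment`
#' @export
makeExpressionMatrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("expression matrix must have gene rownames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols in expression matrix")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("one group label per sample is required")
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  if (!all(is.finite(values))) stop("expression values must be finite")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = values),
    colData = S4Vectors::DataFrame(group = factor(groups,
                                                  levels = c("control", "case")),
                                   row.names = colnames(values)))
}

#' @describeIn makeExpressionMatrix extract the log2 expression assay
#' @param se a `SummarizedExperiment` built by `makeExpressionMatrix()`
#' @export
exprValues <- function(se) {
  SummarizedExperiment::assay(se, "log2expr")
}

#' @describeIn makeExpressionMatrix per-sample group factor
#' @export
sampleGroups <- function(se) {
  SummarizedExperiment::colData(se)$group
}

# shared guard for the testing functions
checkTwoGroups <- function(se) {
  grp <- sampleGroups(se)
  if (is.null(grp)) stop("colData must carry a 'group' column")
  n <- table(grp)
  if (any(n == 0)) stop("both groups must contain at least one sample")
  if (any(n < 2)) stop("each group needs >= 2 samples for testing")
  invisible(grp)
}
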