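#' Select hub targets by double intersection
#'
#' Hub targets survive three independent lines of evidence: they sit in the
#' topologically screened PPI core network, they are targets of the
#' formula's active components, and they belong to disease-relevant
#' pathways. The first two intersect to the "core active targets"; the
#' third intersection yields the hubs.
#'
#' @param coreNodes symbols of the screened core network.
#' @param drugTargets symbols targeted by the active components.
#' @param pathwayGenes symbols of the disease-pathway gene set.
#' @return a [HubReport-class].
#' @export
selectHubs <- function(coreNodes, drugTargets, pathwayGenes) {
  coreNodes <- unique(normalizeSymbols(coreNodes))
  drugTargets <- unique(normalizeSymbols(drugTargets))
  pathwayGenes <- unique(normalizeSymbols(pathwayGenes))
  coreActive <- sort(intersect(coreNodes, drugTargets))
  hubs <- sort(intersect(coreActive, pathwayGenes))
  syms <- sort(unique(c(coreNodes, drugTargets, pathwayGenes)))
  prov <- data.frame(symbol = syms,
                     in_core = syms %in% coreNodes,
                     in_drug_targets = syms %in% drugTargets,
                     in_pathways = syms %in% pathwayGenes,
                     stringsAsFactors = FALSE)
  new("HubReport", coreActiveTargets = coreActive, hubTargets = hubs,
      provenance = prov)
}

#' Coexpression flagging of hub targets against indicator genes
#'
#' Pearson correlation (two-sided p-value via the t transform with n - 2
#' degrees of freedom) for every (hub, indicator) pair, flagged when
#' `r > rMin` and `p < pMax` -- by default the positive-correlation rule of
#' figure-style reporting (R > 0.3, p < 0.05). Set `absolute = TRUE` to
#' flag on |r|. Zero-variance genes yield an undefined r and an unflagged
#' pair with an explanatory note.
#'
#' @param se a `SummarizedExperiment` (groups are ignored) or a numeric
#'   genes x samples matrix.
#' @param hubs,indicators symbols present in the matrix.
#' @param rMin correlation threshold (strict >; default 0.3).
#' @param pMax p-value threshold (strict <; default 0.05).
#' @param method correlation method passed to [stats::cor.test()]
#'   (default `"pearson"`).
#' @param absolute flag on |r| instead of r (default FALSE).
#' @return data.frame with columns `hub`, `indicator`, `r`, `p`, `flagged`,
#'   `note`.
#' @export
coexpression <- function(se, hubs, indicators, rMin = 0.3, pMax = 0.05,
                         method = "pearson", absolute = FALSE) {
  mat <- if (is.matrix(se)) se else exprValues(se)
  if (ncol(mat) < 3) stop("coexpression needs >= 3 samples")
  hubs <- unique(normalizeSymbols(hubs))
  indicators <- unique(normalizeSymbols(indicators))
  missing <- setdiff(c(hubs, indicators), rownames(mat))
  if (length(missing))
    stop("symbol(s) absent from the matrix: ", paste(missing, collapse = ", "))
  grid <- expand.grid(hub = hubs, indicator = indicators,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- mat[grid$hub[i], ]
    y <- mat[grid$indicator[i], ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(data.frame(hub = grid$hub[i], indicator = grid$indicator[i],
                        r = NA_real_, p = NA_real_, flagged = FALSE,
                        note = "zero-variance gene", stringsAsFactors = FALSE))
    }
    ct <- cor.test(x, y, method = method, exact = FALSE)
    r <- unname(ct$estimate)
    flag <- (if (absolute) abs(r) else r) > rMin & ct$p.value < pMax
    data.frame(hub = grid$hub[i], indicator = grid$indicator[i],
               r = r, p = ct$p.value, flagged = flag, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$hub, out$indicator), , drop = FALSE]
}
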