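#' Synthetic component table with a known passing subset
#'
#' Draws a table of herbal components whose ADME properties place an exact,
#' known subset above the oral-bioavailability/drug-likeness screening
#' thresholds (OB >= 30, DL >= 0.18). Passing rows are strictly above both
#' thresholds; failing rows are strictly below at least one. Property ranges
#' are wide enough to cover the values typically reported for flavonoid-rich
#' formulae (DL up to ~0.45, OB 30-70%).
#'
#' @param nComponents number of components to draw (>= 0).
#' @param nHerbs number of herbs in the formula (default 12, a classic
#'   multi-herb decoction).
#' @param fracPassing fraction of rows planted to pass the filter; exactly
#'   `round(fracPassing * nComponents)` rows pass.
#' @param seed integer seed (one seed drives a dedicated RNG stream per
#'   generator, so generators never perturb each other).
#' @return list with `table` (a [ComponentTable-class]) and `truth`
#'   (a [SyntheticTruth-class] with `passingComponents` filled).
#' @export
simulateComponents <- function(nComponents, nHerbs = 12, fracPassing = 0.5,
                               seed = 1) {
  if (nComponents < 0) stop("nComponents must be >= 0")
  if (nHerbs < 1) stop("nHerbs must be >= 1")
  if (fracPassing < 0 || fracPassing > 1)
    stop("fracPassing must lie in [0, 1]")
  nComponents <- as.integer(nComponents)
  if (nComponents == 0) {
    tab <- ComponentTable(data.frame(mol_id = character(), name = character(),
                                     DL = numeric(), AlogP = numeric(),
                                     OB = numeric(), HL = numeric(),
                                     herbs = character(),
                                     stringsAsFactors = FALSE))
    return(list(table = tab, truth = new("SyntheticTruth")))
  }
  nPass <- round(fracPassing * nComponents)
  herbs <- sprintf("HERB_%02d", seq_len(nHerbs))
  withr::with_seed(streamSeed(seed, "components"), {
    passIdx <- sort(sample.int(nComponents, nPass))
    isPass <- seq_len(nComponents) %in% passIdx
    OB <- numeric(nComponents)
    DL <- numeric(nComponents)
    OB[isPass] <- runif(nPass, 30.5, 70)
    DL[isPass] <- runif(nPass, 0.19, 0.45)
    nFail <- nComponents - nPass
    if (nFail > 0) {
      # failing rows miss at least one threshold strictly
      mode <- sample(c("ob", "dl", "both"), nFail, replace = TRUE)
      failOB <- runif(nFail, 2, 29.5)
      failDL <- runif(nFail, 0.01, 0.17)
      anyOB <- runif(nFail, 2, 70)
      anyDL <- runif(nFail, 0.01, 0.45)
      OB[!isPass] <- ifelse(mode %in% c("ob", "both"), failOB, anyOB)
      DL[!isPass] <- ifelse(mode %in% c("dl", "both"), failDL, anyDL)
    }
    herbsPer <- vapply(seq_len(nComponents), function(i) {
      paste(sort(sample(herbs, sample(1:3, 1))), collapse = ";")
    }, character(1))
    df <- data.frame(
      mol_id = sprintf("MOL%06d", seq_len(nComponents)),
      name = sprintf("compound_%04d", seq_len(nComponents)),
      DL = round(DL, 3),
      AlogP = round(runif(nComponents, -2, 6), 2),
      OB = round(OB, 2),
      HL = round(runif(nComponents, 2, 20), 2),
      herbs = herbsPer,
      stringsAsFactors = FALSE)
  })
  truth <- new("SyntheticTruth", passingComponents = df$mol_id[isPass])
  list(table = ComponentTable(df), truth = truth)
}

#' Synthetic two-group log2 expression with planted mean-shift DE genes
#'
#' Gene-level log2 values are Gaussian around gene-specific baselines
#' (microarray-like noise on the log scale). A chosen number of genes
#' receives a mean shift of +/- `lfc` in the case group, half up and half
#' down (an odd count gives the extra gene to the up set). Group sizes
#' default to the 30-case / 9-control design of the emulated cohort.
#'
#' @param nGenes number of genes.
#' @param nCase,nControl samples per group (each >= 2).
#' @param nDE number of differentially expressed genes to plant (<= nGenes).
#' @param lfc planted log2 fold change magnitude.
#' @param sigma within-group standard deviation on the log2 scale (> 0).
#' @param seed integer seed.
#' @param genes optional character vector of gene symbols (length `nGenes`).
#' @param deGenes optional symbols (subset of `genes`) to plant as DE,
#'   overriding the random choice; its length overrides `nDE`.
#' @return list with `matrix` (a `SummarizedExperiment`) and `truth`
#'   (`degUp`/`degDown` filled).
#' @export
simulateExpression <- function(nGenes, nCase = 30, nControl = 9, nDE = 0,
                               lfc = 2, sigma = 0.5, seed = 1, genes = NULL,
                               deGenes = NULL) {
  if (nGenes < 1) stop("nGenes must be >= 1")
  if (nCase < 2 || nControl < 2) stop("each group needs >= 2 samples")
  if (sigma <= 0) stop("sigma must be > 0")
  if (is.null(genes)) genes <- sprintf("GENE%05d", seq_len(nGenes))
  if (length(genes) != nGenes || anyDuplicated(genes))
    stop("genes must be ", nGenes, " unique symbols")
  genes <- normalizeSymbols(genes)
  if (!is.null(deGenes)) {
    deGenes <- unique(normalizeSymbols(deGenes))
    if (length(setdiff(deGenes, genes)))
      stop("deGenes must be a subset of genes")
    nDE <- length(deGenes)
  }
  if (nDE > nGenes) stop("nDE must not exceed nGenes")
  withr::with_seed(streamSeed(seed, "expression"), {
    base <- rnorm(nGenes, mean = 7, sd = 1.5)
    nSamp <- nCase + nControl
    mat <- matrix(rnorm(nGenes * nSamp, sd = sigma), nrow = nGenes) + base
    deIdx <- if (!is.null(deGenes)) sort(match(deGenes, genes))
             else if (nDE > 0) sort(sample.int(nGenes, nDE)) else integer()
    nUp <- ceiling(nDE / 2)
    upIdx <- deIdx[seq_len(nUp)]
    downIdx <- setdiff(deIdx, upIdx)
    caseCols <- seq_len(nCase)
    mat[upIdx, caseCols] <- mat[upIdx, caseCols] + lfc
    mat[downIdx, caseCols] <- mat[downIdx, caseCols] - lfc
  })
  rownames(mat) <- genes
  colnames(mat) <- c(sprintf("CASE%03d", seq_len(nCase)),
                     sprintf("CTRL%03d", seq_len(nControl)))
  se <- makeExpressionMatrix(mat, c(rep("case", nCase), rep("control", nControl)))
  truth <- new("SyntheticTruth", degUp = genes[upIdx], degDown = genes[downIdx])
  list(matrix = se, truth = truth)
}

#' Synthetic scale-free PPI background with a planted dense core
#'
#' The background is a preferential-attachment graph (each new node brings
#' `attachM` edges). A planted core of `coreSize` extra nodes is wired
#' internally with independent edge probability `coreP` and each core node
#' additionally receives `attachM` edges into the background, so the core is
#' never a disconnected component. The returned graph is simple and
#' undirected.
#'
#' @param nBackground number of background nodes (> coreSize).
#' @param attachM preferential-attachment edges per new node.
#' @param coreSize number of planted core nodes (0 for a pure background).
#' @param coreP within-core edge probability in (0, 1].
#' @param seed integer seed.
#' @param backgroundNames,coreNames optional symbol vectors for the two
#'   node groups (defaults `BG0001...` / `CORE01...`).
#' @return list with `network` (a [GeneNetwork-class]) and `truth`
#'   (`coreNodes` filled).
#' @export
simulatePPI <- function(nBackground, attachM = 2, coreSize = 0, coreP = 0.8,
                        seed = 1, backgroundNames = NULL, coreNames = NULL) {
  if (nBackground < 1) stop("nBackground must be >= 1")
  if (coreSize >= nBackground) stop("coreSize must be < nBackground")
  if (coreSize > 0 && (coreP <= 0 || coreP > 1))
    stop("coreP must lie in (0, 1]")
  if (is.null(backgroundNames))
    backgroundNames <- sprintf("BG%04d", seq_len(nBackground))
  if (length(backgroundNames) != nBackground || anyDuplicated(backgroundNames))
    stop("backgroundNames must be ", nBackground, " unique symbols")
  if (coreSize > 0) {
    if (is.null(coreNames)) coreNames <- sprintf("CORE%02d", seq_len(coreSize))
    if (length(coreNames) != coreSize || anyDuplicated(coreNames) ||
        length(intersect(coreNames, backgroundNames)))
      stop("coreNames must be ", coreSize,
           " unique symbols disjoint from backgroundNames")
  } else coreNames <- character()
  backgroundNames <- normalizeSymbols(backgroundNames)
  coreNames <- normalizeSymbols(coreNames)
  withr::with_seed(streamSeed(seed, "ppi"), {
    g <- igraph::sample_pa(nBackground, m = attachM, directed = FALSE)
    igraph::V(g)$name <- backgroundNames
    if (coreSize > 0) {
      g <- igraph::add_vertices(g, coreSize, name = coreNames)
      newEdges <- NULL
      if (coreSize >= 2) {
        pairs <- t(combn(coreNames, 2))
        keep <- runif(nrow(pairs)) < coreP
        newEdges <- pairs[keep, , drop = FALSE]
      }
      anchor <- cbind(rep(coreNames, each = attachM),
                      sample(backgroundNames, coreSize * attachM, replace = TRUE))
      newEdges <- rbind(newEdges, anchor)
      g <- igraph::add_edges(g, t(newEdges))
    }
    g <- igraph::simplify(g)
  })
  list(network = GeneNetwork(g, meta = list(generator = "preferential-attachment + planted core")),
       truth = new("SyntheticTruth", coreNodes = coreNames))
}

#' Synthetic gene-set collection with planted over-representation
#'
#' `nEnriched` sets draw at least 60% of their members from `plantedList`
#' (a query intersected with them will be strongly over-represented); the
#' remaining sets draw uniformly from the universe.
#'
#' @param universe character vector of symbols the sets draw from.
#' @param nSets number of sets.
#' @param setSizeRange length-2 integer range of set sizes.
#' @param plantedList symbols (subset of `universe`) seeding enriched sets.
#' @param nEnriched number of sets planted as enriched (<= nSets).
#' @param seed integer seed.
#' @param category category label(s) for the sets (default `"custom"`).
#' @return list with `collection` (a [GeneSetCollection-class]) and `truth`
#'   (`enrichedSets` filled).
#' @export
simulateGeneSets <- function(universe, nSets, setSizeRange = c(10, 50),
                             plantedList = character(), nEnriched = 0,
                             seed = 1, category = "custom") {
  universe <- unique(normalizeSymbols(universe))
  plantedList <- unique(normalizeSymbols(plantedList))
  if (nSets < 0) stop("nSets must be >= 0")
  if (nEnriched > nSets) stop("nEnriched must not exceed nSets")
  if (max(setSizeRange) > length(universe))
    stop("set sizes must not exceed the universe size")
  if (length(setdiff(plantedList, universe)))
    stop("plantedList must be a subset of the universe")
  if (nEnriched > 0 && length(plantedList) == 0)
    stop("planting enriched sets requires a nonempty plantedList")
  withr::with_seed(streamSeed(seed, "genesets"), {
    ids <- sprintf("SET%03d", seq_len(nSets))
    enrichedIds <- if (nEnriched > 0) sort(sample(ids, nEnriched)) else character()
    sets <- lapply(ids, function(id) {
      s <- sample(seq(setSizeRange[1], setSizeRange[2]), 1)
      if (id %in% enrichedIds) {
        # cap the size so >= 60% of members can come from the planted list
        s <- min(s, floor(length(plantedList) / 0.6))
        s <- max(s, 2L)
        nPlanted <- min(length(plantedList), ceiling(0.6 * s))
        planted <- sample(plantedList, nPlanted)
        rest <- sample(setdiff(universe, planted), s - nPlanted)
        sort(c(planted, rest))
      } else {
        sort(sample(universe, s))
      }
    })
    names(sets) <- ids
  })
  coll <- GeneSetCollection(sets, categories = category)
  list(collection = coll, truth = new("SyntheticTruth", enrichedSets = enrichedIds))
}

#' Synthetic coexpression matrix of bivariate-normal gene pairs
#'
#' Each requested pair is drawn from a bivariate normal with the planted
#' correlation (independent across pairs), shifted to a log2-like baseline.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`, `rho`
#'   (all |rho| < 1; gene symbols unique across pairs).
#' @param nSamples number of samples (>= 3).
#' @param seed integer seed.
#' @return list with `matrix` (a `SummarizedExperiment`, all samples labelled
#'   `case`) and `truth` (`pairCorrelations` filled).
#' @export
simulateCoexpression <- function(pairs, nSamples, seed = 1) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("gene_a", "gene_b", "rho") %in% names(pairs)))
  pairs$gene_a <- normalizeSymbols(pairs$gene_a)
  pairs$gene_b <- normalizeSymbols(pairs$gene_b)
  if (any(abs(pairs$rho) >= 1)) stop("all |rho| must be < 1")
  if (nSamples < 3) stop("nSamples must be >= 3")
  genes <- c(rbind(pairs$gene_a, pairs$gene_b))
  if (anyDuplicated(genes))
    stop("gene symbols must be unique across pairs")
  withr::with_seed(streamSeed(seed, "coexpr"), {
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      x <- rnorm(nSamples)
      y <- pairs$rho[i] * x + sqrt(1 - pairs$rho[i]^2) * rnorm(nSamples)
      rbind(x, y)
    })
    mat <- do.call(rbind, rows) + 7
  })
  rownames(mat) <- genes
  colnames(mat) <- sprintf("S%04d", seq_len(nSamples))
  se <- makeExpressionMatrix(mat, rep("case", nSamples))
  list(matrix = se,
       truth = new("SyntheticTruth", pairCorrelations = pairs))
}
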