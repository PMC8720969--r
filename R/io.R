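#' File formats
#'
#' Tabular artifacts are tab-separated with a header row; networks are SIF
#' (`node relation node`) or two-column TSV; gene sets are GMT; truth ledgers
#' and run reports are JSON.
#'
#' @name herbnet-io
#' @keywords internal
NULL

writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readDelimAuto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

# tolerate the unicode minus sign used in typeset tables
numericClean <- function(x) {
  as.numeric(gsub("−", "-", trimws(as.character(x))))
}

matchColumn <- function(df, candidates) {
  hit <- which(tolower(trimws(names(df))) %in% tolower(candidates))
  if (length(hit)) hit[1] else NA_integer_
}

# ---- component tables -------------------------------------------------------

#' Read a component table (TSV/CSV)
#'
#' Accepts the conventional ADME-table layout: `Mol ID`, `Molecule name`,
#' `DL`, `OB (%)` (or `OB`), optional `AlogP`, `HL` and a herb column
#' (semicolon-separated for multi-herb molecules). Molecules listed under
#' several herbs are deduplicated by mol id with their herb sets merged.
#'
#' @param path file path.
#' @return a [ComponentTable-class]
#' @export
readComponentTable <- function(path) {
  df <- readDelimAuto(path)
  pick <- function(cands, required = FALSE) {
    i <- matchColumn(df, cands)
    if (is.na(i) && required)
      stop("component table is missing a required column: ", cands[1])
    i
  }
  iId <- pick(c("mol id", "mol_id", "molid"), TRUE)
  iName <- pick(c("molecule name", "name", "molecule"), TRUE)
  iDL <- pick("dl", TRUE)
  iOB <- pick(c("ob (%)", "ob", "ob(%)"), TRUE)
  iAlogP <- pick(c("alogp", "alog p"))
  iHL <- pick("hl")
  iHerb <- pick(c("herbs", "herb", "source herb"))
  out <- data.frame(mol_id = as.character(df[[iId]]),
                    name = trimws(as.character(df[[iName]])),
                    DL = numericClean(df[[iDL]]),
                    AlogP = if (!is.na(iAlogP)) numericClean(df[[iAlogP]]) else NA_real_,
                    OB = numericClean(df[[iOB]]),
                    HL = if (!is.na(iHL)) numericClean(df[[iHL]]) else NA_real_,
                    herbs = if (!is.na(iHerb)) trimws(as.character(df[[iHerb]])) else NA_character_,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$mol_id)) {
    merged <- lapply(split(out, factor(out$mol_id, levels = unique(out$mol_id))),
                     function(d) {
                       d1 <- d[1, , drop = FALSE]
                       hs <- unique(unlist(strsplit(d$herbs[!is.na(d$herbs)], ";")))
                       d1$herbs <- if (length(hs)) paste(sort(trimws(hs)), collapse = ";") else NA_character_
                       d1
                     })
    out <- do.call(rbind, merged)
    rownames(out) <- NULL
  }
  ComponentTable(out)
}

#' Write a component table as TSV
#' @param table a [ComponentTable-class]
#' @param path output path
#' @return the path, invisibly
#' @export
writeComponentTable <- function(table, path) {
  df <- componentData(table)
  out <- data.frame(`Mol ID` = df$mol_id, `Molecule name` = df$name,
                    DL = df$DL, AlogP = df$AlogP, `OB (%)` = df$OB,
                    HL = df$HL, Herbs = df$herbs, check.names = FALSE)
  writeTSV(out, path)
}

# ---- expression -------------------------------------------------------------

#' Read an expression matrix and sample groups
#'
#' @param path TSV of genes x samples, first column the gene symbol.
#' @param groupsPath two-column TSV (`sample`, `group`) with group labels
#'   `case`/`control`.
#' @return a `SummarizedExperiment` (see [makeExpressionMatrix()])
#' @export
readExpressionMatrix <- function(path, groupsPath) {
  df <- readDelimAuto(path)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- normalizeSymbols(genes)
  grp <- readDelimAuto(groupsPath)
  if (!all(c("sample", "group") %in% tolower(names(grp))))
    stop("groups file needs 'sample' and 'group' columns")
  names(grp) <- tolower(names(grp))
  groups <- setNames(as.character(grp$group), as.character(grp$sample))
  missing <- setdiff(colnames(mat), names(groups))
  if (length(missing))
    stop("no group label for sample(s): ", paste(missing, collapse = ", "))
  makeExpressionMatrix(mat, groups[colnames(mat)])
}

#' Write an expression matrix and its sample groups as TSV
#' @param se a `SummarizedExperiment` from [makeExpressionMatrix()]
#' @param path matrix output path
#' @param groupsPath groups output path
#' @return `path`, invisibly
#' @export
writeExpressionMatrix <- function(se, path, groupsPath) {
  mat <- exprValues(se)
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  writeTSV(df, path)
  writeTSV(data.frame(sample = colnames(mat),
                      group = as.character(sampleGroups(se))), groupsPath)
  invisible(path)
}

# ---- target maps ------------------------------------------------------------

#' Read a component-to-target map
#'
#' Two-column TSV (`mol_id`, `target`); duplicate pairs are collapsed and
#' target symbols uppercase-normalized.
#'
#' @param path file path
#' @return data.frame with columns `mol_id`, `target`
#' @export
readTargetMap <- function(path) {
  df <- readDelimAuto(path)
  if (ncol(df) < 2) stop("target map needs two columns (mol_id, target)")
  out <- data.frame(mol_id = as.character(df[[1]]),
                    target = normalizeSymbols(df[[2]]),
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Write a component-to-target map as TSV
#' @param map data.frame with `mol_id`, `target`
#' @param path output path
#' @return `path`, invisibly
#' @export
writeTargetMap <- function(map, path) {
  writeTSV(map[, c("mol_id", "target")], path)
}

# ---- networks ---------------------------------------------------------------

#' Read network edges from SIF or two-column TSV
#'
#' SIF lines are `source<TAB>relation<TAB>target` (the relation is ignored);
#' anything else is treated as a headerless two-column edge list. Malformed
#' lines raise an error naming the line number.
#'
#' @param path file path
#' @return data.frame with columns `from`, `to`
#' @export
readNetworkEdges <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2)
  if (length(bad))
    stop("malformed network record at line ", bad[1], " of ", path)
  isSif <- all(nf == 3)
  from <- vapply(parts, `[[`, "", 1)
  to <- vapply(parts, function(p) p[[if (isSif) 3 else 2]], "")
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Write a network in SIF format
#' @param net a [GeneNetwork-class] (or two-column data.frame)
#' @param path output path
#' @param relation SIF relation label (default `"pp"`)
#' @return `path`, invisibly
#' @export
writeNetworkSIF <- function(net, path, relation = "pp") {
  edges <- if (is(net, "GeneNetwork")) networkEdges(net) else net
  lines <- sprintf("%s\t%s\t%s", edges[[1]], relation, edges[[2]])
  writeLines(lines, path)
  invisible(path)
}

# ---- gene sets (GMT) --------------------------------------------------------

#' Read a GMT gene-set file
#'
#' Standard GMT: `set_id<TAB>description<TAB>gene1<TAB>gene2...`. The
#' description field carries the category when it is one of
#' `BP`/`CC`/`MF`/`KEGG` (the layout [writeGMT()] produces); otherwise the
#' set is categorized `custom`.
#'
#' @param path file path
#' @return a [GeneSetCollection-class]
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT record at line ", bad[1], " of ", path)
  ids <- vapply(parts, `[[`, "", 1)
  desc <- vapply(parts, `[[`, "", 2)
  sets <- lapply(parts, function(p) unique(normalizeSymbols(p[-(1:2)])))
  names(sets) <- ids
  cats <- ifelse(desc %in% c("BP", "CC", "MF", "KEGG"), desc, "custom")
  GeneSetCollection(sets, names = ids, categories = cats)
}

#' Write a gene-set collection as GMT
#' @param collection a [GeneSetCollection-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGMT <- function(collection, path) {
  info <- geneSetInfo(collection)
  sets <- geneSets(collection)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(info$set_id[i], info$category[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# ---- docking tables ---------------------------------------------------------

#' Read a molecular-docking results table
#'
#' Accepts the conventional layout `Active ingredients / Hub genes /
#' kcal\\/mol / Total interactions`, with optional `Hydrogen bonds` and
#' `Mode` columns. Unicode minus signs in energies are handled.
#'
#' @param path file path
#' @return data.frame with columns `ligand`, `receptor`, `energy`,
#'   `total_interactions` and optionally `hydrogen_bonds`, `mode_index`
#' @export
readDockingTable <- function(path) {
  df <- readDelimAuto(path)
  iLig <- matchColumn(df, c("active ingredients", "ligand", "compound"))
  iRec <- matchColumn(df, c("hub genes", "receptor", "target"))
  iE <- matchColumn(df, c("kcal/mol", "energy", "binding energy"))
  iInt <- matchColumn(df, c("total interactions", "interactions"))
  if (any(is.na(c(iLig, iRec, iE, iInt))))
    stop("docking table must have ligand, receptor, energy and interaction columns")
  out <- data.frame(ligand = trimws(as.character(df[[iLig]])),
                    receptor = normalizeSymbols(df[[iRec]]),
                    energy = numericClean(df[[iE]]),
                    total_interactions = as.integer(numericClean(df[[iInt]])),
                    stringsAsFactors = FALSE)
  iHB <- matchColumn(df, c("hydrogen bonds", "h-bonds", "hbonds"))
  if (!is.na(iHB)) out$hydrogen_bonds <- as.integer(numericClean(df[[iHB]]))
  iMode <- matchColumn(df, c("mode", "mode index", "mode_index"))
  if (!is.na(iMode)) out$mode_index <- as.integer(numericClean(df[[iMode]]))
  if (any(!is.finite(out$energy))) stop("docking energies must be finite")
  if (any(out$total_interactions < 0, na.rm = TRUE))
    stop("interaction counts must be >= 0")
  out
}

#' Write a docking table as TSV
#' @param records docking data.frame (see [readDockingTable()])
#' @param path output path
#' @return `path`, invisibly
#' @export
writeDockingTable <- function(records, path) {
  out <- data.frame(`Active ingredients` = records$ligand,
                    `Hub genes` = records$receptor,
                    `kcal/mol` = records$energy,
                    `Total interactions` = records$total_interactions,
                    check.names = FALSE)
  if (!is.null(records$hydrogen_bonds))
    out$`Hydrogen bonds` <- records$hydrogen_bonds
  if (!is.null(records$mode_index)) out$Mode <- records$mode_index
  writeTSV(out, path)
}

# ---- truth ledgers ----------------------------------------------------------

#' Write a synthetic ground-truth ledger as JSON
#' @param truth a [SyntheticTruth-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeTruth <- function(truth, path) {
  stopifnot(is(truth, "SyntheticTruth"))
  obj <- list(passing_components = truth@passingComponents,
              deg_up = truth@degUp, deg_down = truth@degDown,
              core_nodes = truth@coreNodes,
              enriched_sets = truth@enrichedSets,
              pair_correlations = truth@pairCorrelations)
  jsonlite::write_json(obj, path, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a synthetic ground-truth ledger from JSON
#' @param path file path
#' @return a [SyntheticTruth-class]
#' @export
readTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- obj$pair_correlations
  if (is.null(pc) || length(pc) == 0)
    pc <- data.frame(gene_a = character(), gene_b = character(), rho = numeric())
  new("SyntheticTruth",
      passingComponents = as.character(obj$passing_components %||% character()),
      degUp = as.character(obj$deg_up %||% character()),
      degDown = as.character(obj$deg_down %||% character()),
      coreNodes = as.character(obj$core_nodes %||% character()),
      enrichedSets = as.character(obj$enriched_sets %||% character()),
      pairCorrelations = as.data.frame(pc))
}
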