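#' Generate a complete, coherent synthetic study bundle
#'
#' Writes every input the pipeline consumes into `dir`, wired together so
#' the chain has a recoverable ground truth: the planted PPI core nodes are
#' differentially expressed, targeted by the passing components, and seed
#' the enriched gene sets, so they should re-emerge as hub targets. The
#' design emulates a 30-case / 9-control expression cohort over the node
#' set of a 600-node scale-free interactome with a 30-node planted core.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving every generator stream.
#' @param nBackground,attachM,coreSize,coreP interactome parameters
#'   (see [simulatePPI()]).
#' @param nCase,nControl,lfc,sigma expression design (see
#'   [simulateExpression()]); 100 DE genes are planted: the core plus
#'   random background genes.
#' @param nComponents,fracPassing component-table design.
#' @param nSets,nEnriched gene-set collection design.
#' @return list with `paths` (named input files), `truth` (merged
#'   [SyntheticTruth-class], also written as `truth.json`), `config`
#'   (a ready [herbnetConfig()] using relative screening thresholds and
#'   three background indicator genes) and `indicators`.
#' @export
simulateStudy <- function(dir, seed = 1, nBackground = 600, attachM = 2,
                          coreSize = 30, coreP = 0.8, nCase = 30,
                          nControl = 9, lfc = 2, sigma = 0.5,
                          nComponents = 40, fracPassing = 0.5, nSets = 20,
                          nEnriched = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  ppi <- simulatePPI(nBackground, attachM = attachM, coreSize = coreSize,
                     coreP = coreP, seed = seed,
                     coreNames = sprintf("HUB%02d", seq_len(coreSize)))
  nodes <- networkNodes(ppi$network)
  core <- truthCoreNodes(ppi$truth)
  background <- setdiff(nodes, core)

  # bundle-level wiring (which genes are DE, targeted, indicators) has its
  # own stream so the per-generator streams stay untouched
  wiring <- withr::with_seed(streamSeed(seed, "study"), {
    deExtra <- sample(background, max(0, 100 - length(core)))
    indicators <- sample(setdiff(background, deExtra), 3)
    list(deGenes = c(core, deExtra), indicators = indicators)
  })

  expr <- simulateExpression(length(nodes), nCase = nCase,
                             nControl = nControl, lfc = lfc, sigma = sigma,
                             seed = seed, genes = nodes,
                             deGenes = wiring$deGenes)
  comps <- simulateComponents(nComponents, fracPassing = fracPassing,
                              seed = seed)
  passing <- truthPassingComponents(comps$truth)

  # target map: every core gene is hit by >= 2 passing components; passing
  # components pick up extra background targets, failing ones random ones
  map <- withr::with_seed(streamSeed(seed, "targetmap"), {
    rows <- list(
      data.frame(mol_id = unlist(lapply(core, function(g)
                   sample(passing, min(2, length(passing))))),
                 target = rep(core, each = min(2, length(passing))),
                 stringsAsFactors = FALSE),
      data.frame(mol_id = sample(passing, 60, replace = TRUE),
                 target = sample(background, 60, replace = TRUE),
                 stringsAsFactors = FALSE))
    failing <- setdiff(componentData(comps$table)$mol_id, passing)
    if (length(failing))
      rows <- c(rows, list(
        data.frame(mol_id = sample(failing, 40, replace = TRUE),
                   target = sample(nodes, 40, replace = TRUE),
                   stringsAsFactors = FALSE)))
    unique(do.call(rbind, rows))
  })

  gsets <- simulateGeneSets(nodes, nSets = nSets,
                            setSizeRange = c(15, 40), plantedList = core,
                            nEnriched = nEnriched, seed = seed,
                            category = "KEGG")

  dock <- withr::with_seed(streamSeed(seed, "docking"), {
    ligands <- componentData(comps$table)$name[
      componentData(comps$table)$mol_id %in% passing]
    grid <- expand.grid(ligand = ligands[seq_len(min(5, length(ligands)))],
                        receptor = core[seq_len(min(6, length(core)))],
                        stringsAsFactors = FALSE)
    data.frame(grid,
               energy = round(runif(nrow(grid), -9.5, -3.0), 1),
               total_interactions = sample(3:14, nrow(grid), replace = TRUE),
               hydrogen_bonds = sample(0:5, nrow(grid), replace = TRUE),
               stringsAsFactors = FALSE)
  })

  truth <- mergeTruth(ppi$truth, expr$truth, comps$truth, gsets$truth)
  paths <- list(components = p("components.tsv"),
                target_map = p("target_map.tsv"),
                expression = p("expression.tsv"),
                groups = p("groups.tsv"),
                ppi = p("ppi.sif"),
                gene_sets = p("gene_sets.gmt"),
                docking = p("docking.tsv"),
                truth = p("truth.json"))
  writeComponentTable(comps$table, paths$components)
  writeTargetMap(map, paths$target_map)
  writeExpressionMatrix(expr$matrix, paths$expression, paths$groups)
  writeNetworkSIF(ppi$network, paths$ppi)
  writeGMT(gsets$collection, paths$gene_sets)
  writeDockingTable(dock, paths$docking)
  writeTruth(truth, paths$truth)

  config <- herbnetConfig(components = paths$components,
                          target_map = paths$target_map,
                          expression = paths$expression,
                          groups = paths$groups,
                          ppi = paths$ppi,
                          gene_sets = paths$gene_sets,
                          docking = paths$docking,
                          dc_min = "relative", bc_min = "relative",
                          indicators = wiring$indicators,
                          seed = seed,
                          out_dir = p("out"))
  list(paths = paths, truth = truth, config = config,
       indicators = wiring$indicators)
}
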