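#' Default pipeline configuration
#'
#' A flat key set holding every stage threshold (all finite, defaulting to
#' the conventional printed values: OB >= 30, DL >= 0.18, |log2FC| > 1,
#' q < 0.05, adjusted p < 0.05, double-median-degree stage 1, DC > 60 and
#' BC > 645 stage 2, R > 0.3 with p < 0.05, energy <= -5 kcal/mol with
#' >= 2 hydrogen bonds), the input paths and the output directory.
#' `dc_min`/`bc_min` also accept the string `"relative"` to switch stage 2
#' to its scale-free form (see [coreScreen()]).
#'
#' @param ... overrides of the default keys (unknown keys are an error,
#'   see [validateConfig()]).
#' @return a validated config list of class `herbnet_config`.
#' @export
herbnetConfig <- function(...) {
  validateConfig(list(...))
}

configDefaults <- function() {
  list(ob_min = 30, dl_min = 0.18,
       lfc_thresh = 1, q_thresh = 0.05,
       ora_p = 0.05,
       dmd_multiplier = 2, dmd_absolute = NULL,
       dc_min = 60, bc_min = 645,
       r_min = 0.3, p_max = 0.05,
       energy_max = -5, hbond_min = 2,
       seed = 1,
       indicators = character(),
       components = NULL, target_map = NULL,
       expression = NULL, groups = NULL,
       ppi = NULL, gene_sets = NULL, docking = NULL,
       out_dir = NULL)
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys are rejected by name; missing keys take their defaults;
#' scalar thresholds are type-checked. Validation is idempotent, so a
#' validated config serialized with [writeConfig()] and re-read validates
#' to the same object.
#'
#' @param config named list of overrides (possibly empty).
#' @return the completed config list of class `herbnet_config`.
#' @export
validateConfig <- function(config = list()) {
  defaults <- configDefaults()
  config <- config[!vapply(config, is.null, TRUE)]
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- defaults
  out[names(config)] <- config
  numKeys <- c("ob_min", "dl_min", "lfc_thresh", "q_thresh", "ora_p",
               "dmd_multiplier", "r_min", "p_max", "energy_max", "hbond_min",
               "seed")
  for (k in numKeys) {
    v <- out[[k]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("config key '", k, "' must be a finite numeric scalar")
    out[[k]] <- as.numeric(v)
  }
  v <- out$dmd_absolute
  if (!is.null(v) && (!is.numeric(v) || length(v) != 1 || !is.finite(v)))
    stop("config key 'dmd_absolute' must be NULL or a finite numeric scalar")
  if (!is.null(v)) out$dmd_absolute <- as.numeric(v)
  for (k in c("dc_min", "bc_min")) {
    v <- out[[k]]
    if (is.numeric(v) && length(v) == 1 && is.finite(v)) {
      out[[k]] <- as.numeric(v)
    } else if (!(is.character(v) && length(v) == 1 && v == "relative")) {
      stop("config key '", k, "' must be a finite numeric scalar or \"relative\"")
    }
  }
  for (k in c("components", "target_map", "expression", "groups", "ppi",
              "gene_sets", "docking", "out_dir")) {
    v <- out[[k]]
    if (!is.null(v) && (!is.character(v) || length(v) != 1))
      stop("config key '", k, "' must be NULL or a single path")
  }
  if (!is.character(out$indicators))
    stop("config key 'indicators' must be a character vector")
  structure(out, class = "herbnet_config")
}

#' Write / read a pipeline configuration (JSON)
#' @param config a config list from [validateConfig()]
#' @param path file path
#' @return `path` (writer) or the validated config (reader)
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$indicators <- as.character(obj$indicators %||% character())
  validateConfig(obj)
}

stageRecord <- function(name, nIn, nOut, thresholds, elapsed, status = "ok",
                        message = "") {
  list(stage = name, n_in = nIn, n_out = nOut, thresholds = thresholds,
       elapsed_s = round(elapsed, 3), status = status, message = message)
}

#' Run the full screening pipeline
#'
#' Executes the eight stages in order -- component filter, differential
#' expression, target intersection, enrichment, PPI screening cascade, hub
#' selection, coexpression, docking ranking -- writing each stage's
#' artifacts into `out_dir` before the next stage starts. A failure in
#' stage *k* leaves the artifacts of stages < *k* on disk and records the
#' failing stage in the (partial) run report. Artifacts are deterministic:
#' the same config and seed reproduce them byte for byte.
#'
#' @param config a config list from [herbnetConfig()]/[validateConfig()];
#'   all seven input paths and `out_dir` must be set.
#' @return the run report (list with one record per executed stage), also
#'   written to `out_dir/run_report.json`. The report alone carries
#'   wall-clock timings; stage artifacts contain none.
#' @export
runPipeline <- function(config) {
  config <- validateConfig(unclass(config))
  needed <- c("components", "target_map", "expression", "groups", "ppi",
              "gene_sets", "docking", "out_dir")
  for (k in needed) {
    if (is.null(config[[k]]))
      stop("config key '", k, "' must be set to run the pipeline")
    if (k != "out_dir" && !file.exists(config[[k]]))
      stop("configured input does not exist: ", config[[k]], " (", k, ")")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(seed = config$seed,
                 config = unclass(config),
                 r_version = paste(R.version$major, R.version$minor, sep = "."),
                 stages = list())
  state <- new.env(parent = emptyenv())

  stages <- list(
    filter = function() {
      tab <- readComponentTable(config$components)
      active <- filterComponents(tab, config$ob_min, config$dl_min)
      writeComponentTable(active, out("active_components.tsv"))
      state$active <- active
      c(length(tab), length(active),
        list(list(ob_min = config$ob_min, dl_min = config$dl_min)))
    },
    deg = function() {
      se <- readExpressionMatrix(config$expression, config$groups)
      deg <- runDEG(se, config$lfc_thresh, config$q_thresh)
      writeDEGTable(deg, out("deg_table.tsv"))
      sets <- callDEGs(deg, config$lfc_thresh, config$q_thresh)
      state$se <- se
      state$degs <- c(sets$up, sets$down)
      c(nrow(deg), length(state$degs),
        list(list(lfc_thresh = config$lfc_thresh, q_thresh = config$q_thresh)))
    },
    intersect = function() {
      map <- readTargetMap(config$target_map)
      activeIds <- componentData(state$active)$mol_id
      activeMap <- map[map$mol_id %in% activeIds, , drop = FALSE]
      state$drugTargets <- sort(unique(activeMap$target))
      common <- commonTargets(state$drugTargets, state$degs)
      state$common <- common
      writeTSV(data.frame(target = common), out("common_targets.tsv"))
      net <- buildBipartite(activeMap, components = activeIds, targets = common)
      writeNetworkSIF(net, out("bipartite.sif"), relation = "ct")
      writeTSV(targetDegreeRanking(net), out("target_ranking.tsv"))
      c(length(state$drugTargets), length(common), list(list()))
    },
    enrich = function() {
      coll <- readGMT(config$gene_sets)
      res <- ora(state$common, coll, pThresh = config$ora_p)
      writeEnrichmentTable(res, out("enrichment.tsv"))
      edges <- geneTermEdges(res)
      writeTSV(edges, out("gene_term_edges.tsv"))
      state$pathwayGenes <- sort(unique(edges$gene))
      c(length(coll), sum(enrichmentTable(res)$significant),
        list(list(ora_p = config$ora_p)))
    },
    screen = function() {
      net <- loadNetwork(config$ppi)
      relOrNum <- function(v) if (identical(v, "relative")) NULL else v
      casc <- screenCascade(net, dmdMultiplier = config$dmd_multiplier,
                            dmdAbsolute = config$dmd_absolute,
                            dcMin = relOrNum(config$dc_min),
                            bcMin = relOrNum(config$bc_min))
      writeNetworkSIF(casc$subnetwork, out("subnetwork.sif"))
      writeNetworkSIF(casc$core, out("core_network.sif"))
      writeCentralityTable(computeCentralities(casc$subnetwork),
                           out("subnetwork_centralities.tsv"))
      writeTSV(casc$report, out("screen_report.tsv"))
      state$coreNodes <- networkNodes(casc$core)
      c(igraph::vcount(net@graph), length(state$coreNodes),
        list(list(dmd_multiplier = config$dmd_multiplier,
                  dmd_absolute = config$dmd_absolute,
                  dc_min = config$dc_min, bc_min = config$bc_min)))
    },
    hubs = function() {
      hubRep <- selectHubs(state$coreNodes, state$drugTargets,
                           state$pathwayGenes)
      writeTSV(hubProvenance(hubRep), out("hub_provenance.tsv"))
      writeTSV(data.frame(hub = hubTargets(hubRep)), out("hub_targets.tsv"))
      state$hubs <- hubTargets(hubRep)
      c(length(state$coreNodes), length(state$hubs), list(list()))
    },
    coexpr = function() {
      mat <- exprValues(state$se)
      hubs <- intersect(state$hubs, rownames(mat))
      inds <- intersect(normalizeSymbols(config$indicators), rownames(mat))
      flags <- if (length(hubs) && length(inds))
        coexpression(state$se, hubs, inds, rMin = config$r_min,
                     pMax = config$p_max)
      else
        data.frame(hub = character(), indicator = character(), r = numeric(),
                   p = numeric(), flagged = logical(), note = character())
      writeTSV(flags, out("coexpression.tsv"))
      c(length(hubs) * length(inds), sum(flags$flagged),
        list(list(r_min = config$r_min, p_max = config$p_max)))
    },
    dock_rank = function() {
      dock <- readDockingTable(config$docking)
      kept <- applyDockingThresholds(dock, config$energy_max, config$hbond_min)
      ranked <- rankDockingPairs(kept, by = "energy")
      writeTSV(ranked, out("docking_ranked.tsv"))
      c(nrow(dock), nrow(ranked),
        list(list(energy_max = config$energy_max,
                  hbond_min = config$hbond_min)))
    })

  for (nm in names(stages)) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(stages[[nm]](), error = function(e) e)
    elapsed <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      report$stages[[nm]] <- stageRecord(nm, NA, NA, list(), elapsed,
                                         status = "error",
                                         message = conditionMessage(res))
      jsonlite::write_json(report, out("run_report.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           null = "null", force = TRUE)
      stop("pipeline stage '", nm, "' failed: ", conditionMessage(res))
    }
    report$stages[[nm]] <- stageRecord(nm, res[[1]], res[[2]], res[[3]],
                                       elapsed)
  }
  jsonlite::write_json(report, out("run_report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(report)
}
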