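#' Best binding mode for one ligand-receptor pair
#'
#' Docking engines report many poses per pair; by convention the first mode
#' is the best. When a `mode_index` column is present and contains mode 1,
#' that record is returned; otherwise the minimum-energy record wins (ties:
#' first occurrence).
#'
#' @param records data.frame of docking records for a single pair
#'   (see [readDockingTable()]).
#' @return one-row data.frame, with attribute `mode_choice` recording how
#'   it was picked.
#' @export
bestMode <- function(records) {
  if (is.null(records) || nrow(records) == 0)
    stop("bestMode requires at least one record")
  if (length(unique(paste(records$ligand, records$receptor))) > 1)
    stop("bestMode expects records for a single ligand-receptor pair")
  if (!is.null(records$mode_index) && any(records$mode_index == 1, na.rm = TRUE)) {
    out <- records[which(records$mode_index == 1)[1], , drop = FALSE]
    choice <- "first mode"
  } else {
    out <- records[which.min(records$energy), , drop = FALSE]
    choice <- "minimum energy"
  }
  attr(out, "mode_choice") <- choice
  out
}

#' Apply binding-quality thresholds to docking records
#'
#' Keeps records with `energy <= energyMax` (the threshold itself passes;
#' more negative is more favorable) and, when a `hydrogen_bonds` column is
#' present, `hydrogen_bonds >= hbondMin`. Without that column the H-bond
#' criterion cannot be evaluated and records pass it with a warning.
#'
#' @param records docking data.frame (see [readDockingTable()]).
#' @param energyMax binding-energy ceiling in kcal/mol (default -5.0).
#' @param hbondMin minimum hydrogen-bond count (default 2).
#' @return the retained rows, original order preserved.
#' @export
applyDockingThresholds <- function(records, energyMax = -5.0, hbondMin = 2) {
  if (is.null(records) || nrow(records) == 0) return(records)
  keep <- records$energy <= energyMax
  if (!is.null(records$hydrogen_bonds)) {
    keep <- keep & records$hydrogen_bonds >= hbondMin
  } else if (hbondMin > 0) {
    warning("no hydrogen_bonds column; H-bond threshold not applied")
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank ligand-receptor pairs by binding quality
#'
#' `by = "energy"` sorts ascending energy (most negative, i.e. strongest
#' binding, first), ties broken by descending interactions; `by =
#' "interactions"` sorts descending interaction count, ties broken by
#' ascending energy. Remaining ties fall back to ligand then receptor
#' lexicographic order, making the ranking a deterministic total order.
#'
#' @param records docking data.frame (see [readDockingTable()]).
#' @param by ranking criterion, `"energy"` or `"interactions"`.
#' @return the records in rank order.
#' @export
rankDockingPairs <- function(records, by = c("energy", "interactions")) {
  by <- match.arg(by)
  if (is.null(records) || nrow(records) == 0) return(records)
  ord <- if (by == "energy")
    order(records$energy, -records$total_interactions,
          records$ligand, records$receptor)
  else
    order(-records$total_interactions, records$energy,
          records$ligand, records$receptor)
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
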