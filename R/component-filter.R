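#' Filter components by oral bioavailability and drug-likeness
#'
#' Retains components with `OB >= obMin` and `DL >= dlMin` (both inclusive,
#' the standard ADME screen for orally administered herbal formulae), in
#' their original row order. Rows with a missing OB or DL value are a data
#' defect and raise an error naming the offending molecule ids.
#'
#' @param table a [ComponentTable-class].
#' @param obMin minimum oral bioavailability in percent (default 30).
#' @param dlMin minimum drug-likeness score (default 0.18).
#' @return a [ComponentTable-class] with the retained rows.
#' @export
filterComponents <- function(table, obMin = 30, dlMin = 0.18) {
  stopifnot(is(table, "ComponentTable"), is.finite(obMin), is.finite(dlMin))
  df <- componentData(table)
  if (nrow(df) == 0) return(table)
  bad <- df$mol_id[is.na(df$OB) | is.na(df$DL)]
  if (length(bad))
    stop("missing OB or DL for component(s): ", paste(bad, collapse = ", "))
  keep <- df$OB >= obMin & df$DL >= dlMin
  ComponentTable(df[keep, , drop = FALSE])
}

#' Rank components by drug-likeness
#'
#' Orders by descending DL, breaking ties by descending OB and then
#' ascending mol id (a fixed, reproducible total order), and returns the
#' first `min(k, n)` rows.
#'
#' @param table a [ComponentTable-class].
#' @param k number of top components to return (default all).
#' @return data.frame of the top-`k` components in rank order.
#' @export
rankByDL <- function(table, k = Inf) {
  stopifnot(is(table, "ComponentTable"), k >= 0)
  df <- componentData(table)
  if (nrow(df) == 0 || k == 0) return(df[integer(), , drop = FALSE])
  ord <- order(-df$DL, -df$OB, df$mol_id)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  head(out, min(k, nrow(out)))
}

#' Component-herb membership edges
#'
#' One edge per (component, herb) membership, ordered by mol id then herb
#' name. Components with no recorded herb contribute zero edges, with a
#' warning.
#'
#' @param table a [ComponentTable-class].
#' @return data.frame with columns `mol_id`, `herb`.
#' @export
herbComponentLinks <- function(table) {
  stopifnot(is(table, "ComponentTable"))
  df <- componentData(table)
  empty <- data.frame(mol_id = character(), herb = character(),
                      stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty)
  herbs <- df$herbs
  if (is.null(herbs)) herbs <- rep(NA_character_, nrow(df))
  noHerb <- is.na(herbs) | !nzchar(trimws(herbs))
  if (any(noHerb))
    warning("component(s) without herb membership: ",
            paste(df$mol_id[noHerb], collapse = ", "))
  lists <- strsplit(herbs[!noHerb], ";", fixed = TRUE)
  if (!length(lists)) return(empty)
  out <- data.frame(mol_id = rep(df$mol_id[!noHerb], lengths(lists)),
                    herb = trimws(unlist(lists)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mol_id, out$herb), , drop = FALSE]
  rownames(out) <- NULL
  out
}
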