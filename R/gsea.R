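#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov-style running sum over a ranked gene list.
#' Walking down the ranking, a set member ("hit") increments the sum by
#' `|score|^weight` normalized by the total hit weight; a non-member
#' decrements it by `1/(N - Nh)`. The enrichment score (ES) is the
#' maximum-magnitude deviation of the running sum. Significance comes from
#' gene-label permutations: set positions are redrawn uniformly `nPerm`
#' times, the NES is ES divided by the mean |ES| of the sign-matched null,
#' and the nominal p-value uses the add-one estimator `(b + 1)/(nPerm + 1)`
#' (never exactly zero).
#'
#' @param ranking named numeric vector (names = unique symbols) or
#'   two-column data.frame (`symbol`, `score`); sorted by descending score
#'   internally.
#' @param setMembers character vector; its intersection with the ranking
#'   must be nonempty and must not cover the whole ranking.
#' @param weight score-weighting exponent (0 = classic KS, 1 = weighted;
#'   default 1).
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return a [GseaResult-class].
#' @export
gseaPreranked <- function(ranking, setMembers, weight = 1, nPerm = 1000,
                          seed = 1) {
  if (is.data.frame(ranking)) {
    stopifnot(all(c("symbol", "score") %in% names(ranking)))
    scores <- setNames(as.numeric(ranking$score),
                       normalizeSymbols(ranking$symbol))
  } else {
    scores <- setNames(as.numeric(ranking), normalizeSymbols(names(ranking)))
  }
  if (anyDuplicated(names(scores))) stop("ranking symbols must be unique")
  scores <- sort(scores, decreasing = TRUE)
  N <- length(scores)
  hits <- names(scores) %in% normalizeSymbols(setMembers)
  Nh <- sum(hits)
  if (Nh < 1) stop("no set member present in the ranking")
  if (Nh >= N) stop("set must not cover the whole ranking")
  esStat <- function(hitIdx) {
    h <- logical(N); h[hitIdx] <- TRUE
    w <- abs(scores)^weight
    inc <- numeric(N)
    inc[h] <- w[h] / sum(w[h])
    inc[!h] <- -1 / (N - length(hitIdx))
    run <- cumsum(inc)
    run[which.max(abs(run))]
  }
  obsIdx <- which(hits)
  es <- esStat(obsIdx)
  nullES <- withr::with_seed(streamSeed(seed, "gsea"), {
    vapply(seq_len(nPerm), function(i) esStat(sample.int(N, Nh)), numeric(1))
  })
  same <- sign(nullES) == sign(es) & nullES != 0
  b <- sum(same & abs(nullES) >= abs(es))
  # add-one estimator over the sign-matched null, so p is never 0
  pval <- (b + 1) / (sum(same) + 1)
  nes <- if (any(same)) es / mean(abs(nullES[same])) else NA_real_
  peak <- {
    w <- abs(scores)^weight
    inc <- numeric(N)
    inc[hits] <- w[hits] / sum(w[hits])
    inc[!hits] <- -1 / (N - Nh)
    run <- cumsum(inc)
    which.max(abs(run))
  }
  leading <- if (es >= 0) names(scores)[seq_len(peak)][hits[seq_len(peak)]]
             else names(scores)[peak:N][hits[peak:N]]
  new("GseaResult", es = es, nes = nes, pValue = pval,
      leadingEdge = leading, setSize = as.integer(Nh),
      nPerm = as.integer(nPerm))
}
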