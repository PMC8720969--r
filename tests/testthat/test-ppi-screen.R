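test_that("network loading normalizes, deduplicates and drops self-loops", {
  edges <- data.frame(from = c("a", "A", "b", "c"),
                      to = c("b", "b", "a", "c"))
  expect_message(net <- loadNetwork(edges), "1 self-loop")
  expect_equal(sort(networkNodes(net)), c("A", "B"))
  expect_equal(nrow(networkEdges(net)), 1)   # duplicates collapsed
  expect_equal(networkMeta(net)$self_loops_dropped, 1)
})

test_that("a SIF round trip reproduces the graph exactly", {
  sim <- simulatePPI(60, coreSize = 8, seed = 4)
  f <- tempfile(fileext = ".sif")
  writeNetworkSIF(sim$network, f)
  back <- loadNetwork(f)
  e1 <- networkEdges(sim$network)
  e2 <- networkEdges(back)
  canon <- function(e) {
    k <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    sort(k)
  }
  expect_identical(canon(e1), canon(e2))
  # malformed record carries a line number
  writeLines(c("A\tpp\tB", "ONLYONE"), f)
  expect_error(readNetworkEdges(f), "line 2")
})

test_that("centralities match closed forms on path and star graphs", {
  path5 <- loadNetwork(data.frame(from = c("A", "B", "C", "D"),
                                  to = c("B", "C", "D", "E")))
  cn <- nodeCentralities(computeCentralities(path5))
  expect_equal(cn$BC[cn$node == "C"], 4)   # pair enumeration: 4 pairs cross C
  n <- 7
  star <- loadNetwork(data.frame(from = "HUB", to = sprintf("L%d", 1:n)))
  cs <- nodeCentralities(computeCentralities(star))
  expect_equal(cs$BC[cs$node == "HUB"], n * (n - 1) / 2)
  expect_true(all(cs$BC[cs$node != "HUB"] == 0))
  expect_equal(cs$CC[cs$node == "HUB"], n / n)  # distance 1 to all leaves
})

test_that("betweenness equals the walk-counting oracle on random graphs", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    rg <- randomTestGraph(n, runif(1, 0.2, 0.6))
    cn <- nodeCentralities(computeCentralities(rg$net))
    oracle <- walkBetweenness(rg$A)
    expect_equal(cn$BC[match(sprintf("N%02d", 1:n), cn$node)], oracle,
                 tolerance = 1e-9)
  }
})

test_that("tree betweenness totals the pairs with interior vertices", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    # random tree via preferential attachment with m = 1
    g <- igraph::sample_pa(n, m = 1, directed = FALSE)
    igraph::V(g)$name <- sprintf("T%02d", 1:n)
    net <- computeCentralities(GeneNetwork(g))
    d <- igraph::distances(g)
    # each unordered pair contributes one unit per interior vertex of its
    # (unique) path, i.e. distance - 1
    oracle <- sum(pmax(d[upper.tri(d)] - 1, 0))
    expect_equal(sum(nodeCentralities(net)$BC), oracle)
  }
})

test_that("the double-median-degree screen uses strict thresholds", {
  # a cycle is 2-regular: threshold 2 * 2 = 4, nobody strictly exceeds it
  ring <- loadNetwork(data.frame(from = sprintf("R%d", 1:6),
                                 to = sprintf("R%d", c(2:6, 1))))
  sub <- dmdScreen(ring)
  expect_equal(length(networkNodes(sub)), 0)
  expect_equal(networkMeta(sub)$dmd_threshold, 4)
  # absolute-threshold mode honored when configured
  sim <- simulatePPI(200, coreSize = 15, seed = 6)
  abs5 <- dmdScreen(sim$network, absolute = 5)
  deg <- igraph::degree(sim$network@graph)
  expect_setequal(networkNodes(abs5), names(deg)[deg > 5])
  expect_equal(networkMeta(abs5)$dmd_mode, "absolute")
})

test_that("stages are nested and outputs are induced subgraphs", {
  sim <- simulatePPI(300, coreSize = 20, seed = 9)
  casc <- screenCascade(sim$network, dcMin = NULL, bcMin = NULL)
  nodes0 <- networkNodes(sim$network)
  nodes1 <- networkNodes(casc$subnetwork)
  nodes2 <- networkNodes(casc$core)
  expect_true(all(nodes2 %in% nodes1))
  expect_true(all(nodes1 %in% nodes0))
  # induced semantics: all original edges among kept nodes survive
  e0 <- networkEdges(sim$network)
  inSub <- e0$from %in% nodes1 & e0$to %in% nodes1
  expect_equal(nrow(networkEdges(casc$subnetwork)), sum(inSub))
  # report counts equal direct recounts, non-increasing enforced
  expect_equal(casc$report$nodes,
               c(length(nodes0), length(nodes1), length(nodes2)))
  expect_true(all(diff(casc$report$nodes) <= 0))
  badStages <- list(a = casc$core, b = sim$network)
  expect_error(screenReport(badStages), "non-increasing")
})

test_that("the cascade recovers the planted core", {
  sim <- simulatePPI(600, attachM = 2, coreSize = 30, coreP = 0.8, seed = 3)
  # relative stage-2 thresholds: double-median degree again, BC > 0
  casc <- screenCascade(sim$network, dcMin = NULL, bcMin = NULL)
  core <- truthCoreNodes(sim$truth)
  got <- networkNodes(casc$core)
  recall <- length(intersect(got, core)) / length(core)
  precision <- length(intersect(got, core)) / length(got)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.8)
  # the DMD stage alone already keeps >= 90% of the core
  expect_gte(length(intersect(networkNodes(casc$subnetwork), core)) /
               length(core), 0.9)
})

test_that("core screening recomputes centralities on the subnetwork", {
  # leaf nodes of a tree have BC = 0 and must fail any bc_min >= 0
  g <- igraph::sample_pa(15, m = 1, directed = FALSE)
  igraph::V(g)$name <- sprintf("T%02d", 1:15)
  net <- GeneNetwork(g)
  core <- coreScreen(net, dcMin = 0, bcMin = 0)
  leaves <- names(which(igraph::degree(g) == 1))
  expect_length(intersect(networkNodes(core), leaves), 0)
})
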