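test_that("generators are reproducible and independent across streams", {
  a <- simulateComponents(30, fracPassing = 0.3, seed = 42)
  b <- simulateComponents(30, fracPassing = 0.3, seed = 42)
  expect_identical(componentData(a$table), componentData(b$table))
  e1 <- simulateExpression(100, nCase = 4, nControl = 4, nDE = 10, seed = 42)
  e2 <- simulateExpression(100, nCase = 4, nControl = 4, nDE = 10, seed = 42)
  expect_identical(exprValues(e1$matrix), exprValues(e2$matrix))
  p1 <- simulatePPI(100, coreSize = 10, seed = 42)
  p2 <- simulatePPI(100, coreSize = 10, seed = 42)
  expect_identical(networkEdges(p1$network), networkEdges(p2$network))
  # byte-for-byte after serialization
  f1 <- tempfile(); f2 <- tempfile()
  writeComponentTable(a$table, f1); writeComponentTable(b$table, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("component truth ledgers match the requested design exactly", {
  sim <- simulateComponents(50, fracPassing = 0.24, seed = 5)
  df <- componentData(sim$table)
  truth <- truthPassingComponents(sim$truth)
  expect_length(truth, round(0.24 * 50))
  expect_true(all(truth %in% df$mol_id))
  pass <- df$mol_id %in% truth
  # passing strictly above both thresholds, failing strictly below >= 1
  expect_true(all(df$OB[pass] > 30 & df$DL[pass] > 0.18))
  expect_true(all(df$OB[!pass] < 30 | df$DL[!pass] < 0.18))
  # passing draws live on supports wide enough to represent the reported
  # pivotal-component spread (DL 0.21-0.29, OB 30.68-69.67)
  expect_true(all(df$DL[pass] >= 0.19 & df$DL[pass] <= 0.45))
  expect_true(all(df$OB[pass] >= 30.5 & df$OB[pass] <= 70))
  expect_true(all(lengths(strsplit(df$herbs, ";")) %in% 1:3))
  expect_error(simulateComponents(-1), "nComponents")
})

test_that("null configurations give empty truth and empty artifacts", {
  expect_equal(length(simulateComponents(0, seed = 1)$table), 0L)
  e <- simulateExpression(50, nCase = 3, nControl = 3, nDE = 0, seed = 1)
  expect_length(truthDegUp(e$truth), 0)
  expect_length(truthDegDown(e$truth), 0)
  p <- simulatePPI(80, coreSize = 0, seed = 1)
  expect_length(truthCoreNodes(p$truth), 0)
  expect_equal(igraph::vcount(p$network@graph), 80)
  g <- simulateGeneSets(letters, nSets = 5, setSizeRange = c(3, 8),
                        nEnriched = 0, seed = 1)
  expect_length(truthEnrichedSets(g$truth), 0)
  expect_length(g$collection, 5)
})

test_that("expression generator plants the requested mean shifts", {
  sim <- simulateExpression(400, nCase = 30, nControl = 9, nDE = 21,
                            lfc = 2, sigma = 0.5, seed = 3)
  up <- truthDegUp(sim$truth); down <- truthDegDown(sim$truth)
  expect_length(up, 11)   # odd count: extra gene goes up
  expect_length(down, 10)
  expect_length(intersect(up, down), 0)
  lfc <- log2FoldChange(sim$matrix)
  expect_equal(unname(mean(lfc[up])), 2, tolerance = 0.3)
  expect_equal(unname(mean(lfc[down])), -2, tolerance = 0.3)
  expect_error(simulateExpression(10, nDE = 11), "nDE")
  expect_error(simulateExpression(10, nCase = 1), "samples")
})

test_that("planted PPI core nodes dominate the degree ranking", {
  sim <- simulatePPI(600, attachM = 2, coreSize = 30, coreP = 0.8, seed = 3)
  net <- sim$network
  g <- net@graph
  expect_false(igraph::is_directed(g))
  expect_true(igraph::is_simple(g))
  deg <- igraph::degree(g)
  core <- truthCoreNodes(sim$truth)
  expect_true(all(rank(-deg)[core] <= 0.1 * igraph::vcount(g)))
  expect_error(simulatePPI(10, coreSize = 10), "coreSize")
})

test_that("planted gene sets are predominantly drawn from the planted list", {
  universe <- sprintf("G%03d", 1:300)
  planted <- universe[1:40]
  sim <- simulateGeneSets(universe, nSets = 12, setSizeRange = c(10, 30),
                          plantedList = planted, nEnriched = 4, seed = 8)
  sets <- geneSets(sim$collection)
  enriched <- truthEnrichedSets(sim$truth)
  expect_length(enriched, 4)
  for (id in enriched) {
    frac <- mean(sets[[id]] %in% planted)
    expect_gte(frac, 0.6)
  }
  expect_error(simulateGeneSets(universe, 3, plantedList = "NOT_THERE",
                                nEnriched = 1, seed = 1), "subset")
})

test_that("coexpression pairs recover their planted correlations", {
  pairs <- data.frame(gene_a = c("CDK1", "MAPK1", "X1"),
                      gene_b = c("CCNB1", "CD11B", "Y1"),
                      rho = c(0.84, 0.4, 0))
  sim <- simulateCoexpression(pairs, nSamples = 4000, seed = 11)
  m <- exprValues(sim$matrix)
  expect_equal(cor(m["CDK1", ], m["CCNB1", ]), 0.84, tolerance = 0.03)
  expect_equal(cor(m["MAPK1", ], m["CD11B", ]), 0.4, tolerance = 0.05)
  expect_lt(abs(cor(m["X1", ], m["Y1", ])), 3 / sqrt(4000))
  expect_error(simulateCoexpression(
    data.frame(gene_a = "A", gene_b = "B", rho = 1), 10), "rho")
  expect_error(simulateCoexpression(
    data.frame(gene_a = "A", gene_b = "B", rho = 0.5), 2), "nSamples")
})

test_that("truth ledgers survive a JSON round trip", {
  sim <- simulatePPI(50, coreSize = 5, seed = 2)
  truth <- mergeTruth(sim$truth,
                      simulateComponents(10, seed = 2)$truth,
                      simulateCoexpression(
                        data.frame(gene_a = "A", gene_b = "B", rho = 0.3),
                        10, seed = 2)$truth)
  f <- tempfile(fileext = ".json")
  writeTruth(truth, f)
  back <- readTruth(f)
  expect_setequal(truthCoreNodes(back), truthCoreNodes(truth))
  expect_setequal(truthPassingComponents(back),
                  truthPassingComponents(truth))
  expect_equal(truthPairCorrelations(back)$rho, 0.3)
})
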