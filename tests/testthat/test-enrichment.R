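test_that("the hypergeometric tail matches combinatorial enumeration", {
  # literal enumeration over all C(20, 10) query draws for one configuration
  N <- 20; K <- 5; n <- 10; k <- 5
  universe <- seq_len(N)
  draws <- combn(N, n)
  hitsAtLeastK <- sum(colSums(draws <= K) >= k)
  oracle <- hitsAtLeastK / ncol(draws)
  expect_equal(hyperTail(k, K, n, N), oracle)
  # choose-sum oracle over a spread of random configurations
  set.seed(5)
  for (i in 1:50) {
    N <- sample(5:25, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hyperTail(k, K, n, N), chooseTail(k, K, n, N))
  }
  expect_equal(hyperTail(0, 5, 10, 20), 1)   # tail at zero
})

test_that("ORA raw p is monotone decreasing in the overlap count", {
  for (cfg in list(c(100, 20, 30), c(50, 10, 10), c(200, 40, 25))) {
    N <- cfg[1]; K <- cfg[2]; n <- cfg[3]
    p <- hyperTail(0:min(K, n), K, n, N)
    expect_true(all(diff(p) < 0))
  }
})

test_that("ORA computes the overlap statistics through the full interface", {
  universe <- sprintf("G%02d", 1:20)
  coll <- GeneSetCollection(list(S1 = universe[1:5], S2 = universe[6:20]),
                            categories = "KEGG")
  res <- ora(universe[1:10], coll, universe = universe)
  tb <- enrichmentTable(res)
  r1 <- tb[tb$set_id == "S1", ]
  expect_equal(r1$k, 5); expect_equal(r1$K, 5)
  expect_equal(r1$n, 10); expect_equal(r1$N, 20)
  expect_equal(r1$p, chooseTail(5, 5, 10, 20))
  expect_equal(r1$overlap[[1]], universe[1:5])
  # disjoint set gives p = 1
  collD <- GeneSetCollection(list(S = universe[11:20]))
  resD <- ora(universe[1:5], collD, universe = universe)
  expect_equal(enrichmentTable(resD)$p, 1)
  expect_error(ora("A", coll, universe = character()), "universe")
  expect_warning(ora(c(universe[1], "NOT_IN_UNIVERSE"), coll,
                     universe = universe), "dropped")
})

test_that("BH correction is applied within each category", {
  universe <- sprintf("G%03d", 1:100)
  sets <- list(A1 = universe[1:10], A2 = universe[11:30],
               B1 = universe[1:10], B2 = universe[31:60])
  coll <- GeneSetCollection(sets, categories = c("BP", "BP", "KEGG", "KEGG"))
  res <- ora(universe[1:15], coll, universe = universe, pThresh = 1)
  tb <- enrichmentTable(res)
  for (cat in c("BP", "KEGG")) {
    sub <- tb[tb$category == cat, ]
    expect_equal(sub$p_adjust, p.adjust(sub$p, "BH"))
  }
})

test_that("planted enriched sets occupy the top ORA ranks", {
  universe <- sprintf("G%03d", 1:400)
  planted <- universe[1:50]
  sim <- simulateGeneSets(universe, nSets = 15, setSizeRange = c(15, 40),
                          plantedList = planted, nEnriched = 5, seed = 2)
  res <- ora(planted, sim$collection, universe = universe)
  tb <- enrichmentTable(res)
  expect_setequal(tb$set_id[1:5], truthEnrichedSets(sim$truth))
  expect_true(all(tb$significant[1:5]))
})

test_that("a null collection stays below the significance threshold", {
  universe <- sprintf("G%03d", 1:400)
  planted <- universe[1:40]
  hits <- 0L
  for (seed in 1:20) {
    sim <- simulateGeneSets(universe, nSets = 10, setSizeRange = c(10, 30),
                            plantedList = planted, nEnriched = 0, seed = seed)
    res <- ora(planted, sim$collection, universe = universe)
    if (any(enrichmentTable(res)$significant)) hits <- hits + 1L
  }
  expect_lte(hits / 20, 0.05 + 3 * sqrt(0.05 * 0.95 / 20))
})

test_that("top terms and term-gene edges follow the ORA ordering", {
  universe <- sprintf("G%03d", 1:200)
  sim <- simulateGeneSets(universe, nSets = 12, setSizeRange = c(10, 25),
                          plantedList = universe[1:40], nEnriched = 6,
                          seed = 9)
  res <- ora(universe[1:40], sim$collection, universe = universe)
  sig <- significantTerms(res)
  top3 <- topTerms(res, 3)
  expect_lte(nrow(top3), 3)
  expect_equal(top3$set_id, head(sig$set_id, nrow(top3)))
  expect_identical(topTerms(res, 100)$set_id, sig$set_id)  # fewer than n
  edges <- geneTermEdges(res)
  expect_equal(nrow(edges), sum(lengths(sig$overlap)))     # counting oracle
  one <- GeneSetCollection(list(S = c("A", "B", "C")))
  resOne <- ora(c("A", "B"), one, universe = c("A", "B", "C", "D"),
                pThresh = 1)
  expect_equal(nrow(geneTermEdges(resOne)), 2)
})
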