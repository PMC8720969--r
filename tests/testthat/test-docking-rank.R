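dockPath <- system.file("extdata", "docking_results.tsv", package = "herbnet")

test_that("the printed docking table ranks quercetin-CDK1 strongest", {
  dock <- readDockingTable(dockPath)
  expect_equal(nrow(dock), 16)
  byE <- rankDockingPairs(dock, by = "energy")
  expect_equal(byE$ligand[1], "Quercetin")
  expect_equal(byE$receptor[1], "CDK1")
  expect_equal(byE$energy[1], -9.1)
  byI <- rankDockingPairs(dock, by = "interactions")
  expect_equal(byI$ligand[1], "Licochalcone A")
  expect_equal(byI$receptor[1], "MAPK1")
  expect_equal(byI$total_interactions[1], 14L)
})

test_that("every printed pair clears the binding-energy threshold", {
  dock <- readDockingTable(dockPath)
  expect_warning(kept <- applyDockingThresholds(dock), "hydrogen_bonds")
  expect_equal(nrow(kept), 16)           # weakest printed energy is -5.1
  expect_true(all(kept$energy <= -5.0))
})

test_that("threshold filtering is inclusive, column-aware and monotone", {
  recs <- data.frame(ligand = sprintf("L%d", 1:4),
                     receptor = sprintf("R%d", 1:4),
                     energy = c(-5.0, -4.9, -7.1, -6.0),
                     total_interactions = c(3L, 9L, 2L, 5L),
                     hydrogen_bonds = c(2L, 5L, 1L, 4L))
  kept <- applyDockingThresholds(recs)
  expect_equal(kept$ligand, c("L1", "L4"))   # -5.0 itself passes; L3 lacks H-bonds
  expect_equal(nrow(applyDockingThresholds(recs[0, ])), 0)
  # tightening the energy ceiling never adds a record
  for (e in c(-5, -6, -7, -8)) {
    a <- applyDockingThresholds(recs, energyMax = e)
    b <- applyDockingThresholds(recs, energyMax = e - 1)
    expect_true(all(b$ligand %in% a$ligand))
  }
  # synthetic table with known 3 passing rows
  syn <- data.frame(ligand = sprintf("L%d", 1:6), receptor = "R",
                    energy = c(-6, -5.5, -3, -4.9, -8, -2),
                    total_interactions = 1L,
                    hydrogen_bonds = c(3L, 2L, 5L, 4L, 2L, 0L))
  expect_equal(nrow(applyDockingThresholds(syn)), 3)
  oracle <- sum(syn$energy <= -5 & syn$hydrogen_bonds >= 2)
  expect_equal(nrow(applyDockingThresholds(syn)), oracle)
})

test_that("best-mode selection prefers mode 1, else the energy minimum", {
  modes <- data.frame(ligand = "L", receptor = "R",
                      energy = c(-7.0, -9.0, -6.5),
                      total_interactions = c(5L, 8L, 2L),
                      mode_index = c(1L, 2L, 3L))
  best <- bestMode(modes)
  expect_equal(best$mode_index, 1L)
  expect_equal(attr(best, "mode_choice"), "first mode")
  noMode1 <- modes[modes$mode_index != 1, ]
  best2 <- bestMode(noMode1)
  expect_equal(best2$energy, min(noMode1$energy))   # min-scan oracle
  expect_equal(attr(best2, "mode_choice"), "minimum energy")
  single <- modes[1, ]
  expect_equal(bestMode(single)$energy, -7.0)
  expect_error(bestMode(modes[0, ]), "at least one")
  expect_error(bestMode(data.frame(ligand = c("A", "B"), receptor = "R",
                                   energy = -6, total_interactions = 1L)),
               "single")
})

test_that("pair ranking is a deterministic total order", {
  set.seed(3)
  recs <- data.frame(ligand = sample(LETTERS[1:4], 12, replace = TRUE),
                     receptor = sample(c("R1", "R2"), 12, replace = TRUE),
                     energy = round(runif(12, -9, -4), 1),
                     total_interactions = sample(2:12, 12, replace = TRUE))
  r1 <- rankDockingPairs(recs, "energy")
  expect_identical(r1, rankDockingPairs(recs[sample(12), ], "energy"))
  expect_true(all(diff(r1$energy) >= 0))
  r2 <- rankDockingPairs(recs, "interactions")
  expect_true(all(diff(r2$total_interactions) <= 0))
  one <- rankDockingPairs(recs[1, ], "energy")
  expect_equal(one$ligand, recs$ligand[1])
  expect_equal(one$energy, recs$energy[1])
})
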