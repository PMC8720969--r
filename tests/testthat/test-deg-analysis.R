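test_that("log2 fold change is the difference of group means", {
  mat <- rbind(A = c(8, 8, 8, 6, 6), B = c(5, 5, 5, 5, 5))
  se <- makeExpressionMatrix(mat, c("case", "case", "case",
                                    "control", "control"))
  lfc <- log2FoldChange(se)
  expect_equal(unname(lfc["A"]), 2)
  expect_equal(unname(lfc["B"]), 0)
  sim <- simulateExpression(200, nCase = 5, nControl = 4, seed = 11)
  m <- exprValues(sim$matrix)
  grp <- as.character(sampleGroups(sim$matrix))
  oracle <- apply(m, 1, function(r) mean(r[grp == "case"]) -
                    mean(r[grp == "control"]))
  expect_equal(log2FoldChange(sim$matrix), oracle)
})

test_that("the per-gene test matches Welch's formula and t.test", {
  x <- c(7.1, 8.3, 6.9); y <- c(5.2, 5.9, 6.4)
  se <- makeExpressionMatrix(rbind(G = c(x, y)),
                             rep(c("case", "control"), each = 3))
  # closed-form Welch statistic
  v1 <- var(x) / 3; v2 <- var(y) / 3
  tt <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2)
  expect_equal(unname(geneWelchTest(se)["G"]), 2 * pt(-abs(tt), df))
  # cross-check the vectorized path against stats::t.test gene by gene
  sim <- simulateExpression(50, nCase = 6, nControl = 5, nDE = 10, seed = 4)
  m <- exprValues(sim$matrix)
  grp <- as.character(sampleGroups(sim$matrix))
  oracle <- apply(m, 1, function(r)
    t.test(r[grp == "case"], r[grp == "control"])$p.value)
  expect_equal(geneWelchTest(sim$matrix), oracle, tolerance = 1e-12)
})

test_that("degenerate zero-variance genes follow the stated conventions", {
  m <- rbind(EQ = rep(3, 6), NE = rep(c(1, 2), each = 3))
  se <- makeExpressionMatrix(m, rep(c("case", "control"), each = 3))
  expect_warning(p <- geneWelchTest(se), "zero within-group variance")
  expect_equal(unname(p["EQ"]), 1)
  expect_equal(unname(p["NE"]), 0)
})

test_that("null p-values are approximately uniform", {
  sim <- simulateExpression(5000, nCase = 30, nControl = 9, nDE = 0,
                            sigma = 0.5, seed = 21)
  p <- geneWelchTest(sim$matrix)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("BH adjustment matches the direct step-up formula", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  m <- length(p)
  ord <- order(p)
  stepup <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  oracle <- pmin(1, stepup)[order(ord)]
  expect_equal(bhAdjust(p), oracle)
  expect_equal(bhAdjust(0.37), 0.37)          # single p unchanged
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone along the sorted raw p-values
  set.seed(9)
  q <- bhAdjust(pr <- runif(100))
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
  expect_true(all(q <= 1))
})

test_that("DEG calling uses strict thresholds on both axes", {
  deg <- data.frame(gene = c("A", "B", "C", "D"),
                    log2FC = c(1.0, 1.01, -1.5, 2.0),
                    p = c(0.001, 0.001, 0.001, 0.04),
                    q = c(0.01, 0.01, 0.01, 0.05))
  sets <- callDEGs(deg)
  expect_equal(sets$up, "B")        # A sits exactly on |log2FC| = 1
  expect_equal(sets$down, "C")      # D sits exactly on q = 0.05
  expect_length(intersect(sets$up, sets$down), 0)
})

test_that("planted DE genes are recovered with high sensitivity and low FDR", {
  sim <- simulateExpression(2000, nCase = 30, nControl = 9, nDE = 100,
                            lfc = 2, sigma = 0.5, seed = 7)
  deg <- runDEG(sim$matrix)
  called <- unlist(callDEGs(deg), use.names = FALSE)
  planted <- c(truthDegUp(sim$truth), truthDegDown(sim$truth))
  sens <- length(intersect(called, planted)) / length(planted)
  fdr <- if (length(called)) length(setdiff(called, planted)) / length(called) else 0
  expect_gte(sens, 0.9)
  expect_lte(fdr, 0.1)
  # directions match the planted signs
  expect_true(all(callDEGs(deg)$up %in% truthDegUp(sim$truth)))
  expect_true(all(callDEGs(deg)$down %in% truthDegDown(sim$truth)))
})

test_that("top-by-significance equals a brute-force sort of the called DEGs", {
  sim <- simulateExpression(500, nCase = 10, nControl = 8, nDE = 60,
                            lfc = 2, sigma = 0.6, seed = 13)
  deg <- runDEG(sim$matrix)
  sets <- callDEGs(deg)
  sub <- deg[deg$gene %in% c(sets$up, sets$down), ]
  oracle <- sub$gene[order(sub$q, sub$p, -abs(sub$log2FC), sub$gene)]
  expect_equal(topBySignificance(deg, n = 20), head(oracle, 20))
  expect_equal(topBySignificance(deg, n = 1e6), oracle)  # n beyond DEG count
})
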