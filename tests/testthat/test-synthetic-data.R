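test_that("compendium generation is bit-reproducible under a fixed seed", {
  spec <- compendiumSpec(nStudies = 2, genesTotal = 60, nYoung = 4, nOld = 4,
                         seed = 7)
  a <- generateCompendium(spec)
  b <- generateCompendium(spec)
  for (nm in names(studies(a)))
    expect_identical(SummarizedExperiment::assay(studies(a)[[nm]]),
                     SummarizedExperiment::assay(studies(b)[[nm]]))
  expect_identical(plantedTruth(a), plantedTruth(b))
})

test_that("planted truth partitions the gene universe", {
  comp <- generateCompendium(compendiumSpec(nStudies = 2, genesTotal = 100,
                                            fracUp = 0.2, fracDown = 0.3,
                                            seed = 3))
  tr <- plantedTruth(comp)
  all3 <- c(tr$upGenes, tr$downGenes, tr$nullGenes)
  expect_setequal(all3, geneUniverse(comp))
  expect_equal(anyDuplicated(all3), 0L)
  expect_length(tr$upGenes, 20)
  expect_length(tr$downGenes, 30)
  expect_true(all(tr$agingReferenceSet %in% geneUniverse(comp)))
})

test_that("invalid specs fail validation naming the offending field", {
  expect_error(compendiumSpec(nYoung = 2), "nYoung")
  expect_error(compendiumSpec(fracUp = 0.7, fracDown = 0.6), "fracUp")
  expect_error(compendiumSpec(noiseSd = -1), "noiseSd")
  expect_error(compendiumSpec(nStudies = 0), "nStudies")
})

test_that("global null yields uniform per-study p-values and ~5% positives", {
  comp <- generateCompendium(compendiumSpec(nStudies = 1, genesTotal = 2000,
                                            nYoung = 10, nOld = 10,
                                            fracUp = 0, fracDown = 0,
                                            effectSize = 0, seed = 101))
  de <- runDiffExpr(comp)[[1]]
  expect_gt(suppressWarnings(ks.test(de$p, "punif"))$p.value, 0.01)
  expect_gt(mean(de$p < 0.05), 0.03)
  expect_lt(mean(de$p < 0.05), 0.07)
})

test_that("planted-partition graph respects intraP/interP extremes", {
  asg <- setNames(rep(c("A", "B", "C"), each = 5), sprintf("g%02d", 1:15))
  edges <- generatePPI(asg, intraP = 1, interP = 0, seed = 2)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE)
  cl <- igraph::components(g)
  expect_equal(cl$no, 3)
  expect_true(all(cl$csize == 5))
  expect_equal(igraph::ecount(g), 3 * choose(5, 2))  # three 5-cliques
  expect_true(all(edges$combined_score >= 900 & edges$combined_score <= 999))
  expect_error(generatePPI(asg, intraP = 0.1, interP = 0.5), "probabilities")
})

test_that("planted community edge densities match the wiring probabilities", {
  asg <- setNames(rep(sprintf("C%d", 1:5), each = 20), sprintf("g%03d", 1:100))
  edges <- generatePPI(asg, intraP = 0.3, interP = 0.02, seed = 5)
  intra <- asg[edges$protein1] == asg[edges$protein2]
  nIntraPairs <- 5 * choose(20, 2)
  nInterPairs <- choose(100, 2) - nIntraPairs
  ciIntra <- qbinom(c(0.0005, 0.9995), nIntraPairs, 0.3)
  ciInter <- qbinom(c(0.0005, 0.9995), nInterPairs, 0.02)
  expect_gte(sum(intra), ciIntra[1]); expect_lte(sum(intra), ciIntra[2])
  expect_gte(sum(!intra), ciInter[1]); expect_lte(sum(!intra), ciInter[2])
})

test_that("hub over-wiring reaches the requested degree", {
  asg <- setNames(rep("bg", 50), sprintf("g%02d", 1:50))
  asg <- setNames(sprintf("c%02d", 1:50), names(asg))  # singleton communities
  edges <- generatePPI(asg, intraP = 1, interP = 0.01, seed = 4,
                       hubGenes = "g01", hubDegree = 30)
  deg <- sum(edges$protein1 == "g01" | edges$protein2 == "g01")
  expect_gte(deg, 30)
})

test_that("noise-free qPCR tables invert exactly and noisy ones approximately", {
  tab0 <- generateQpcr("tg", foldChanges = 1, ctNoiseSd = 0, seed = 1)
  res0 <- suppressWarnings(ddct(tab0))
  expect_true(all(abs(res0$perSample$ddCt) < 1e-12))
  tab4 <- generateQpcr("tg", foldChanges = 4, ctNoiseSd = 0, seed = 1)
  res4 <- suppressWarnings(ddct(tab4))
  expect_equal(res4$groupSummary$meanFold[res4$groupSummary$group == "treated"], 4)
  tab2 <- generateQpcr("tg", foldChanges = 2, ctNoiseSd = 0.1, seed = 8)
  res2 <- ddct(tab2)
  f <- res2$groupSummary$meanFold[res2$groupSummary$group == "treated"]
  expect_gt(f, 1.7); expect_lt(f, 2.3)
  expect_error(generateQpcr("tg", foldChanges = -1), "positive")
})

test_that("compendium round-trips through the on-disk TSV/JSON layout", {
  comp <- generateCompendium(compendiumSpec(nStudies = 2, genesTotal = 40,
                                            seed = 12))
  dir <- withr::local_tempdir()
  writeCompendium(comp, dir)
  back <- readCompendium(dir)
  expect_equal(length(back), 2)
  expect_setequal(geneUniverse(back), geneUniverse(comp))
  expect_setequal(plantedTruth(back)$upGenes, plantedTruth(comp)$upGenes)
  m1 <- SummarizedExperiment::assay(studies(comp)[[1]])
  m2 <- SummarizedExperiment::assay(studies(back)[[1]])
  expect_equal(m2[rownames(m1), colnames(m1)], m1, tolerance = 1e-8)
})
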