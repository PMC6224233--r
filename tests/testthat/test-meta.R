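test_that("Fisher combination matches closed-form values", {
  expect_equal(fisherCombine(c(1, 1, 1))$X, 0)
  expect_equal(fisherCombine(c(1, 1, 1))$p, 1)
  one <- fisherCombine(0.05)  # identity for a single study
  expect_equal(one$X, -2 * log(0.05), tolerance = 1e-4)
  expect_equal(one$df, 2L)
  expect_equal(one$p, 0.05, tolerance = 1e-12)
  two <- fisherCombine(c(0.5, 0.5))
  expect_equal(two$X, 2.7726, tolerance = 1e-4)
  expect_equal(two$df, 4L)
  expect_equal(two$p, pchisq(two$X, 4, lower.tail = FALSE))
  expect_equal(two$p, 0.5966, tolerance = 1e-4)
})

test_that("Fisher handles zeros, NAs, and is monotone in each input", {
  expect_warning(z <- fisherCombine(c(0, 0.5)), "clamped")
  expect_true(z$p < 1e-100)
  withNA <- fisherCombine(c(0.1, NA, 0.2))
  expect_equal(withNA$df, 4L)  # df reduced for the missing study
  set.seed(13)
  for (i in 1:50) {
    p <- runif(4)
    j <- sample(4, 1)
    p2 <- p; p2[j] <- p2[j] * runif(1)
    expect_lte(fisherCombine(p2)$p, fisherCombine(p)$p + 1e-12)
  }
})

test_that("fixed-effect pooling matches hand computations", {
  sym <- fixedEffectCombine(c(1, 1), c(1, 1))
  expect_equal(sym$effect, 1)
  expect_equal(sym$se, 1 / sqrt(2))
  expect_equal(sym$Q, 0)
  het <- fixedEffectCombine(c(0, 2), c(1, 1))
  expect_equal(het$effect, 1)
  expect_equal(het$Q, 2)
  expect_equal(het$Qdf, 1L)
  expect_equal(het$Qp, 0.1573, tolerance = 1e-4)
  single <- fixedEffectCombine(3, 0.5)
  expect_equal(single$effect, 3)
  expect_true(is.na(single$Q))
  expect_error(fixedEffectCombine(c(1, 2), c(1, 0)), "positive")
})

test_that("fixed-effect estimate agrees with the metafor reference", {
  skip_if_not_installed("metafor")
  set.seed(17)
  for (i in 1:10) {
    e <- rnorm(5); s <- runif(5, 0.2, 2)
    mine <- fixedEffectCombine(e, s)
    ref <- metafor::rma(yi = e, sei = s, method = "FE")
    expect_equal(mine$effect, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine$se, ref$se, tolerance = 1e-8)
    expect_equal(mine$Q, ref$QE, tolerance = 1e-8)
    expect_equal(mine$Qp, ref$QEp, tolerance = 1e-8)
  }
})

test_that("pooled estimate always lies within the range of study effects", {
  set.seed(19)
  for (i in 1:500) {
    e <- rnorm(sample(2:6, 1), sd = 3)
    s <- runif(length(e), 0.1, 3)
    fe <- fixedEffectCombine(e, s)
    expect_gte(fe$effect, min(e) - 1e-12)
    expect_lte(fe$effect, max(e) + 1e-12)
  }
})

test_that("vote counting matches the spec examples and a brute-force count", {
  expect_equal(voteCount(c(0.01, 0.2, 0.04, 0.6, 0.03)), 3)
  expect_equal(voteCount(c(0.9, 0.5, 0.06)), 0)
  set.seed(23)
  for (i in 1:200) {
    p <- runif(5); p[sample(5, 1)] <- NA
    expect_identical(as.integer(voteCount(p)), bruteVotes(p))
  }
  dirs <- c("up", "up", "down", "up", "down")
  p <- c(0.01, 0.02, 0.01, 0.2, 0.9)
  expect_equal(voteCount(p, dirs, directionConsistent = TRUE), 2)
})

test_that("consensus applies the three-method AND rule with directions", {
  meta <- data.frame(gene = c("a", "b", "c"),
                     fisherP = c(1e-5, 1e-5, 0.5),
                     feP = c(1e-4, 1e-4, 0.5),
                     feEffect = c(2, -1, 0.1), feZ = c(5, -4, 0.3),
                     votes = c(3, 1, 0))
  out <- consensusGenes(meta)
  expect_true(out$consensus[1])
  expect_false(out$consensus[2])  # votes = 1 fails the >= 2 rule
  expect_false(out$consensus[3])
  expect_equal(out$direction[1:2], c("up", "down"))
})

test_that("consensus is a subset of every per-method significant list", {
  comp <- generateCompendium(compendiumSpec(nStudies = 4, genesTotal = 400,
                                            nYoung = 8, nOld = 8,
                                            effectSize = 0.9, seed = 31))
  meta <- consensusGenes(metaAnalyze(runDiffExpr(comp)))
  cons <- meta$gene[meta$consensus]
  expect_true(all(cons %in% meta$gene[meta$sigFisher]))
  expect_true(all(cons %in% meta$gene[meta$sigFe]))
  expect_true(all(cons %in% meta$gene[meta$sigVotes]))
})

test_that("sign-discordant weak genes are labeled discordant", {
  de <- list(
    s1 = data.frame(gene = c("g1", "g2"), effect = c(1, 1), se = c(0.5, 0.5),
                    p = c(0.5, 0.01)),
    s2 = data.frame(gene = c("g1", "g2"), effect = c(-1, 1.2), se = c(0.5, 0.5),
                    p = c(0.6, 0.02)))
  meta <- consensusGenes(metaAnalyze(de))
  expect_equal(meta$direction[meta$gene == "g1"], "discordant")
  expect_equal(meta$direction[meta$gene == "g2"], "up")
})

test_that("direction percentages reproduce the one-decimal convention", {
  pct <- directionPercentages(635, 625)
  expect_equal(unname(pct), c(50.4, 49.6))
  expect_equal(sum(pct), 100)
  expect_true(is.na(directionPercentages(0, 0)[["downPct"]]))
})
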