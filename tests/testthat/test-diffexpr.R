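makeExprFixture <- function(nGenes = 40, n1 = 6, n2 = 6, delta = 0, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * (n1 + n2), sd = runif(nGenes, 0.5, 2)),
              nGenes, n1 + n2,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(n1 + n2))))
  m[, seq_len(n2) + n1] <- m[, seq_len(n2) + n1] + delta
  list(mat = m, groups = rep(c("young", "old"), c(n1, n2)))
}

test_that("with d0 = 0 the moderated t equals the ordinary two-sample t", {
  fx <- makeExprFixture(nGenes = 10, seed = 3)
  res <- moderatedT(fx$mat, fx$groups, d0 = 0)
  for (i in seq_len(10)) {
    o <- bruteTwoSampleT(fx$mat[i, fx$groups == "young"],
                         fx$mat[i, fx$groups == "old"])
    expect_equal(res$tMod[i], o$t, tolerance = 1e-10)
    expect_equal(res$t[i], o$t, tolerance = 1e-10)
    expect_equal(res$p[i], o$p, tolerance = 1e-10)
  }
})

test_that("identical gene variances are a fixed point of shrinkage", {
  ## when every gene shares the variance, the prior absorbs everything
  ## (d0 = Inf), the posterior variance is the same for all genes, ordering
  ## is preserved, and - up to the small-sample factor of the log-scale
  ## method of moments, which vanishes as df grows - tMod equals t
  set.seed(9)
  n <- 60
  base <- rnorm(n)
  m <- t(vapply(1:15, function(i) base + rnorm(n, sd = 1e-9), numeric(n)))
  dimnames(m) <- list(sprintf("g%d", 1:15), sprintf("s%d", 1:n))
  res <- moderatedT(m, rep(c("young", "old"), each = n / 2))
  expect_true(is.infinite(res$d0[1]))
  expect_lt(diff(range(res$se)), 1e-8)
  expect_equal(res$tMod, res$t, tolerance = 0.02)
})

test_that("moderated t agrees with the limma reference implementation", {
  fx <- makeExprFixture(nGenes = 120, delta = 0.4, seed = 11)
  res <- moderatedT(fx$mat, fx$groups)
  design <- cbind(1, as.numeric(fx$groups == "old"))
  fit <- limma::eBayes(limma::lmFit(fx$mat, design))
  expect_equal(res$d0[1], fit$df.prior, tolerance = 1e-6)
  expect_equal(res$s02[1], fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$tMod, fit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("shrinkage pulls small-variance genes down and large-variance up", {
  fx <- makeExprFixture(nGenes = 200, delta = 0.3, seed = 21)
  res <- moderatedT(fx$mat, fx$groups)
  s2 <- res$se^0  # recompute ordinary s2 from t and effect
  s2 <- (res$effect / res$t)^2 / (1 / 6 + 1 / 6)
  small <- s2 < res$s02
  nz <- res$t != 0
  expect_true(all(abs(res$tMod)[small & nz] <= abs(res$t)[small & nz] + 1e-12))
  expect_true(all(abs(res$tMod)[!small & nz] >= abs(res$t)[!small & nz] - 1e-12))
})

test_that("zero-variance genes are reported with p = 1, not an error", {
  fx <- makeExprFixture(nGenes = 5, seed = 2)
  fx$mat[3, ] <- 7
  expect_warning(res <- moderatedT(fx$mat, fx$groups), "zero variance")
  expect_equal(res$p[3], 1)
  expect_equal(res$effect[3], 0)
})

test_that("BH adjustment matches hand step-up values and is well-behaved", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(0.3), 0.3)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.1, NaN)), "NaN")
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(200)^2
  adj <- bhFdr(p)
  expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  ## discoveries monotone non-decreasing in alpha
  alphas <- seq(0.01, 0.5, by = 0.01)
  disc <- vapply(alphas, function(a) sum(adj < a), 0L)
  expect_true(all(diff(disc) >= 0))
})

test_that("cross-study overlap returns the intersection and Venn cells", {
  ov <- studyOverlap(list(s1 = c("A", "B"), s2 = c("B", "C")))
  expect_equal(ov$intersection, "B")
  expect_setequal(names(ov$vennCounts), c("s1", "s2", "s1/s2"))
  same <- studyOverlap(list(a = c("X", "Y"), b = c("X", "Y"), c = c("X", "Y")))
  expect_setequal(same$intersection, c("X", "Y"))
  expect_error(studyOverlap(list(c("A"))), "at least 2")
})

test_that("all-study overlap on a strongly planted simulation is pure", {
  comp <- generateCompendium(compendiumSpec(
    nStudies = 5, genesTotal = 500, nYoung = 15, nOld = 15,
    fracUp = 0.05, fracDown = 0.05, effectSize = 1.5, seed = 77))
  de <- runDiffExpr(comp)
  sig <- lapply(de, significantGenes)
  ov <- studyOverlap(sig)
  tr <- plantedTruth(comp)
  planted <- c(tr$upGenes, tr$downGenes)
  expect_gt(length(ov$intersection), 0)
  expect_gte(mean(ov$intersection %in% planted), 0.95)
})
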