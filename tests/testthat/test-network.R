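test_that("zero-order construction keeps only seed-seed edges above threshold", {
  e <- data.frame(protein1 = c("A", "A", "B"), protein2 = c("B", "D", "C"),
                  combined_score = c(950, 990, 800))
  net <- buildZeroOrderNetwork(e, c("A", "B", "C"), scoreThreshold = 900)
  expect_setequal(networkNodes(net), c("A", "B"))
  expect_equal(igraph::ecount(ppiGraph(net)), 1)
  expect_equal(isolatedSeeds(net), "C")  # D is a non-seed, excluded entirely

  all0 <- buildZeroOrderNetwork(e, c("A", "B", "C"), scoreThreshold = 0)
  expect_equal(igraph::ecount(ppiGraph(all0)), 2)  # A-B and B-C, not A-D
})

test_that("node degrees equal an independent recount from the raw edge list", {
  fx <- randomGraphFixture(30, 0.15, seed = 41)
  net <- buildZeroOrderNetwork(fx$edges, fx$nodes)
  cent <- networkCentralities(net)
  for (i in seq_len(nrow(cent))) {
    g <- cent$gene[i]
    expect_equal(cent$dc[i],
                 sum(fx$edges$protein1 == g) + sum(fx$edges$protein2 == g))
  }
})

test_that("betweenness matches small-graph enumeration", {
  path <- data.frame(protein1 = c("A", "B"), protein2 = c("B", "C"),
                     combined_score = 950)
  cent <- networkCentralities(buildZeroOrderNetwork(path, c("A", "B", "C")))
  expect_equal(cent$bc[cent$gene == "B"], 1)
  expect_equal(cent$bc[cent$gene != "B"], c(0, 0))
  expect_equal(cent$dc[cent$gene == "B"], 2)

  star <- data.frame(protein1 = "X", protein2 = c("l1", "l2", "l3", "l4"),
                     combined_score = 950)
  cs <- networkCentralities(buildZeroOrderNetwork(star, c("X", paste0("l", 1:4))))
  expect_equal(cs$bc[cs$gene == "X"], choose(4, 2))
  expect_equal(cs$dc[cs$gene == "X"], 4)
})

test_that("betweenness equals the matrix-power oracle on random graphs", {
  for (seed in 1:25) {
    n <- sample(5:12, 1)
    fx <- randomGraphFixture(n, 0.3, seed = seed)
    if (nrow(fx$edges) == 0) next
    net <- buildZeroOrderNetwork(fx$edges, fx$nodes)
    cent <- networkCentralities(net)
    oracle <- bruteBetweenness(fx$adj)
    names(oracle) <- fx$nodes
    expect_equal(cent$bc, unname(oracle[cent$gene]), tolerance = 1e-9)
  }
})

test_that("hub selection applies both the degree floor and the rank cutoff", {
  tab <- data.frame(gene = sprintf("g%03d", 1:100),
                    dc = c(30, 9, rep(5, 98)),
                    bc = c(500, 400, seq(300, 3, length.out = 98)))
  tab <- tab[order(-tab$bc, -tab$dc, tab$gene), ]
  tab$rank <- seq_len(nrow(tab))
  hubs <- selectHubs(tab, dcMin = 10, topFraction = 0.10, totalGenes = 100)
  expect_equal(hubs$gene, "g001")  # g002 has top BC but fails dcMin

  lowRank <- data.frame(gene = "z", dc = 50, bc = 1, rank = 90)
  expect_equal(nrow(selectHubs(lowRank, totalGenes = 100)), 0)
})

test_that("centrality ranking is invariant to input row order", {
  fx <- randomGraphFixture(25, 0.2, seed = 57)
  shuffled <- fx$edges[sample(nrow(fx$edges)), ]
  a <- networkCentralities(buildZeroOrderNetwork(fx$edges, fx$nodes))
  b <- networkCentralities(buildZeroOrderNetwork(shuffled, rev(fx$nodes)))
  expect_equal(a$gene, b$gene)
  expect_equal(a$rank, b$rank)
})

test_that("size filter and determinism hold for module extraction", {
  tri2 <- data.frame(protein1 = c("a", "b", "c", "x", "y", "z"),
                     protein2 = c("b", "c", "a", "y", "z", "x"),
                     combined_score = 950)
  net <- buildZeroOrderNetwork(tri2, unique(unlist(tri2[, 1:2])))
  res <- findModules(net, minSize = 5, nPerm = 199, seed = 1)
  expect_equal(nrow(res$modules), 0)  # two triangles, both below min size
  expect_equal(nrow(res$components), 2)

  fx <- cliqueFixture(seed = 7)
  netC <- buildZeroOrderNetwork(fx, unique(unlist(fx[, 1:2])))
  r1 <- findModules(netC, nPerm = 199, seed = 11)
  r2 <- findModules(netC, nPerm = 199, seed = 11)
  expect_identical(r1$candidates, r2$candidates)  # same seed, same p-values
})

test_that("a planted clique is recovered as a significant module", {
  fx <- cliqueFixture(seed = 99)
  net <- buildZeroOrderNetwork(fx, unique(unlist(fx[, 1:2])))
  res <- findModules(net, minSize = 5, nPerm = 999, seed = 3)
  clique <- sprintf("n%03d", 1:5)
  hit <- vapply(res$modules$members, function(m)
    all(clique %in% strsplit(m, ",")[[1]]), TRUE)
  expect_true(any(hit))
  expect_lte(min(res$modules$p[hit]), 0.01)
})

test_that("permutation p-values are calibrated for random node sets", {
  ## for node sets NOT chosen by density optimization, the degree-matched
  ## permutation p must be valid: P(p < 0.05) <= ~0.05 on unstructured graphs
  hits <- 0L; total <- 0L
  for (seed in 1:10) {
    fx <- randomGraphFixture(60, 0.08, seed = 600 + seed)
    net <- buildZeroOrderNetwork(fx$edges, fx$nodes)
    g <- ppiGraph(net)
    comp <- igraph::components(g)
    cont <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
    set.seed(seed)
    for (r in 1:5) {
      s <- sample(cont, 6)
      p <- modulePermutationP(net, s, nPerm = 199, seed = 1000 + r)$p
      hits <- hits + (p < 0.05); total <- total + 1L
    }
  }
  expect_lte(hits / total, 0.10)
})
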