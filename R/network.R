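#' Build the zero-order PPI network on seed genes
#'
#' Induces the subgraph of a scored interaction edge list on the seed genes
#' only ("zero-order": no added interactors), keeping edges whose combined
#' score meets the threshold. Self-loops and duplicate edges are removed;
#' seeds left without any retained edge are excluded from the graph but
#' reported.
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score` (STRING convention, 0-1000), or a path to such a TSV.
#' @param seedGenes character vector of seed genes (e.g. the consensus list).
#' @param scoreThreshold minimum retained combined score; the default 900
#'   corresponds to the standard high-confidence cutoff of 0.9.
#' @return a [PPINetwork-class]. An empty graph is allowed (reported via
#'   `show`), not an error.
#' @examples
#' e <- data.frame(protein1 = c("A", "A", "B"), protein2 = c("B", "D", "C"),
#'                 combined_score = c(950, 990, 800))
#' buildZeroOrderNetwork(e, c("A", "B", "C"))
#' @export
buildZeroOrderNetwork <- function(edges, seedGenes, scoreThreshold = 900) {
  if (is.character(edges) && length(edges) == 1)
    edges <- utils::read.delim(edges)
  stopifnot(all(c("protein1", "protein2", "combined_score") %in% colnames(edges)))
  if (!length(seedGenes)) stop("seed gene list is empty")
  keep <- edges$protein1 %in% seedGenes & edges$protein2 %in% seedGenes &
    edges$combined_score >= scoreThreshold & edges$protein1 != edges$protein2
  el <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = el$protein1, to = el$protein2,
               score = el$combined_score),
    directed = FALSE)
  g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  isolated <- sort(setdiff(seedGenes, igraph::V(g)$name))
  methods::new("PPINetwork", graph = g, scoreThreshold = scoreThreshold,
               isolatedSeeds = isolated, nSeeds = length(unique(seedGenes)))
}

#' Degree and betweenness centralities for every network node
#'
#' Degree centrality (DC) is the plain edge count; betweenness centrality
#' (BC) is unnormalized shortest-path betweenness on the undirected,
#' unweighted graph (Brandes algorithm; each unordered pair counted once;
#' disconnected graphs handled per component). Nodes are ranked by BC
#' descending with ties broken by DC descending then gene ID.
#'
#' @param net a [PPINetwork-class].
#' @param directions optional named vector (`up`/`down` per gene) carried
#'   into the table, e.g. from the consensus results.
#' @return data.frame sorted by rank: `gene`, `dc`, `bc`, `rank`,
#'   `direction` (NA when not supplied).
#' @export
networkCentralities <- function(net, directions = NULL) {
  g <- ppiGraph(net)
  if (igraph::vcount(g) == 0) stop("network is empty")
  genes <- igraph::V(g)$name
  dc <- as.integer(igraph::degree(g))
  bc <- igraph::betweenness(g, directed = FALSE, weights = NA,
                            normalized = FALSE)
  ord <- order(-bc, -dc, genes)
  out <- data.frame(gene = genes, dc = dc, bc = as.numeric(bc),
                    stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  out$direction <- if (is.null(directions)) NA_character_
                   else as.character(directions[out$gene])
  rownames(out) <- NULL
  out
}

#' Select hub genes by degree and betweenness rank
#'
#' Hubs are the nodes with at least `dcMin` connections that also rank in the
#' top `topFraction` of the centrality ordering. The ranking denominator is
#' the total number of consensus genes under study (`totalGenes`), not just
#' the nodes that made it into the graph, matching the convention of ranking
#' the full significant-gene list.
#'
#' @param centralities a [networkCentralities()] table.
#' @param dcMin minimum degree ("at least 10 node degrees").
#' @param topFraction rank cutoff as a fraction of `totalGenes`.
#' @param totalGenes denominator for the top-fraction rule; defaults to the
#'   number of rows in the table.
#' @return the subset of `centralities` flagged as hubs, sorted by rank.
#' @export
selectHubs <- function(centralities, dcMin = 10, topFraction = 0.10,
                       totalGenes = nrow(centralities)) {
  maxRank <- ceiling(topFraction * totalGenes)
  out <- centralities[centralities$dc >= dcMin &
                        centralities$rank <= maxRank, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract subnetworks and permutation-significant modules
#'
#' Enumerates the connected components of the network; the largest is the
#' "continent", the rest are "islands". The continent is partitioned by
#' deterministic greedy-modularity (CNM) community detection. Every
#' candidate — island or continent community — of at least `minSize` genes
#' receives a permutation p-value: the fraction of `nPerm` random node sets
#' of the same size, drawn from the continent with degree-binned matching,
#' whose internal edge count is at least the observed one (with the +1
#' add-one correction, so the smallest attainable p is `1/(nPerm + 1)`).
#' Modules with `p < alpha` are the reported significant modules.
#'
#' @param net a [PPINetwork-class].
#' @param minSize minimum module size reported.
#' @param alpha module significance level.
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed for the permutation draws.
#' @param nBins number of degree bins for the permutation null.
#' @param method community detection for the continent: `"greedy"` (CNM,
#'   deterministic) or `"walktrap"`.
#' @return list with `components` (data.frame: id, size, type
#'   continent/island), `candidates` (all size-passing candidates with
#'   `internalEdges` and `p`), `modules` (the significant subset) and
#'   `membership` (named community label per continent node).
#' @export
findModules <- function(net, minSize = 5, alpha = 0.05, nPerm = 999,
                        seed = 1L, nBins = 5, method = c("greedy", "walktrap")) {
  method <- match.arg(method)
  g <- ppiGraph(net)
  if (igraph::vcount(g) == 0) stop("network is empty")
  if (nPerm < 100) warning("nPerm < 100: p-value resolution floor is ",
                           signif(1 / (nPerm + 1), 3))
  comp <- igraph::components(g)
  sizes <- comp$csize
  contId <- which.max(sizes)
  compTable <- data.frame(id = seq_along(sizes), size = sizes,
                          type = ifelse(seq_along(sizes) == contId,
                                        "continent", "island"))
  contNodes <- igraph::V(g)$name[comp$membership == contId]
  cont <- igraph::induced_subgraph(g, contNodes)

  ## partition the continent into communities
  cl <- if (method == "greedy") igraph::cluster_fast_greedy(cont, weights = NULL)
        else igraph::cluster_walktrap(cont, weights = NULL)
  membership <- stats::setNames(igraph::membership(cl),
                                igraph::V(cont)$name)

  candidates <- list()
  for (m in sort(unique(membership))) {
    members <- sort(names(membership)[membership == m])
    if (length(members) >= minSize)
      candidates[[length(candidates) + 1L]] <- list(
        id = sprintf("module%d", m), type = "module", members = members)
  }
  for (i in seq_along(sizes)) {
    if (i == contId || sizes[i] < minSize) next
    members <- sort(igraph::V(g)$name[comp$membership == i])
    candidates[[length(candidates) + 1L]] <- list(
      id = sprintf("island%d", i), type = "island", members = members)
  }

  ## degree-binned permutation null drawn from the continent
  set.seed(as.integer(seed))
  rows <- lapply(candidates, function(cand) {
    pm <- modulePermutationP(net, cand$members, nPerm = nPerm, seed = NULL,
                             nBins = nBins)
    data.frame(id = cand$id, type = cand$type, size = length(cand$members),
               internalEdges = pm$internalEdges, p = pm$p,
               members = paste(cand$members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  candTable <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), type = character(0), size = integer(0),
               internalEdges = integer(0), p = numeric(0),
               members = character(0))
  list(components = compTable,
       candidates = candTable,
       modules = candTable[candTable$p < alpha & candTable$size >= minSize, ,
                           drop = FALSE],
       membership = membership)
}

#' Permutation p-value for the connectivity of a gene set
#'
#' The null used for module significance: `nPerm` random node sets of the
#' same size are drawn from the continent (largest connected component) with
#' degree-binned matching — each member is replaced by a random continent
#' node from the same degree bin — and the observed internal edge count is
#' compared against the null counts. The add-one estimate
#' `p = (1 + #\{null >= observed\}) / (nPerm + 1)` is returned, so the
#' smallest attainable p is `1/(nPerm + 1)`.
#'
#' @param net a [PPINetwork-class].
#' @param members gene set to score (must intersect the network nodes).
#' @param nPerm number of permutations.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @param nBins number of degree bins.
#' @return list: `internalEdges` (observed), `p`.
#' @seealso [findModules()], which applies this to every candidate module.
#' @export
modulePermutationP <- function(net, members, nPerm = 999, seed = NULL,
                               nBins = 5) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- ppiGraph(net)
  comp <- igraph::components(g)
  contNodes <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
  cont <- igraph::induced_subgraph(g, contNodes)
  contDeg <- igraph::degree(cont)
  breaks <- unique(stats::quantile(contDeg,
                                   probs = seq(0, 1, length.out = nBins + 1)))
  if (length(breaks) < 2) breaks <- c(min(contDeg) - 1, max(contDeg))
  binOf <- function(deg) {
    b <- findInterval(deg, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(b, 1L), length(breaks) - 1L)
  }
  binPool <- split(names(contDeg), binOf(contDeg))
  el <- igraph::as_edgelist(g, names = TRUE)
  internalEdges <- function(s) sum(el[, 1] %in% s & el[, 2] %in% s)

  members <- intersect(members, igraph::V(g)$name)
  obs <- internalEdges(members)
  wantBins <- table(binOf(igraph::degree(g, members)))
  hits <- 0L
  for (b in seq_len(nPerm)) {
    draw <- unlist(lapply(names(wantBins), function(bn) {
      pool <- binPool[[bn]]
      if (is.null(pool)) pool <- names(contDeg)
      sample(pool, min(wantBins[[bn]], length(pool)))
    }), use.names = FALSE)
    draw <- unique(draw)
    if (length(draw) < length(members))
      draw <- unique(c(draw, sample(setdiff(names(contDeg), draw),
                                    length(members) - length(draw))))
    if (internalEdges(draw) >= obs) hits <- hits + 1L
  }
  list(internalEdges = obs, p = (hits + 1) / (nPerm + 1))
}

#' Export a PPI network as GraphML
#'
#' @param net a [PPINetwork-class].
#' @param path output file.
#' @export
writeGraphML <- function(net, path) {
  igraph::write_graph(ppiGraph(net), path, format = "graphml")
  invisible(path)
}
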