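#' @import methods
#' @importFrom stats rnorm runif rbinom pchisq pt pnorm qnorm quantile sd
#'   p.adjust phyper fisher.test t.test var setNames complete.cases
#' @importFrom utils head read.delim write.table combn
NULL

#' Specification of a synthetic multi-study expression compendium
#'
#' A `CompendiumSpec` fixes every parameter of the synthetic-data generator:
#' how many studies, the shared gene universe, per-study group sizes, the
#' fraction of genes truly up- or down-regulated with age, the standardized
#' log2 effect size, study-level batch variation, residual noise, and the RNG
#' seed. The generator is bit-reproducible given the seed.
#'
#' @slot nStudies integer, number of studies (>= 1).
#' @slot genesTotal integer, size of the shared gene universe.
#' @slot nYoung,nOld integer vectors (length 1 or `nStudies`) of per-study
#'   group sizes; each must be >= 3, mirroring the inclusion rule that a study
#'   needs three or more samples in both age groups.
#' @slot fracUp,fracDown proportions of genes planted as age-up / age-down;
#'   `fracUp + fracDown <= 1`.
#' @slot effectSize standardized mean shift (old minus young) on the log2
#'   scale applied to planted genes.
#' @slot studyBatchSd standard deviation of per-study, per-gene baseline
#'   offsets (batch shifts between studies).
#' @slot noiseSd residual Gaussian standard deviation on the log2 scale.
#' @slot nModules number of planted community labels used when wiring a
#'   synthetic interaction network over the regulated genes.
#' @slot refSetSize,refOverlapFrac size of the synthetic aging reference set
#'   and the fraction of it drawn from planted regulated genes.
#' @slot rawScale if `TRUE`, expression is exponentiated to a raw intensity
#'   scale (with multiplicative noise) so the normalization path is exercised.
#' @slot continuousAges if `TRUE`, ages are drawn uniformly over 20-90 with no
#'   group gap (for age-correlation follow-ups); otherwise ages come from the
#'   two-group design brackets 20-40 and 60-90.
#' @slot seed integer RNG seed.
#'
#' @seealso [compendiumSpec()] for the validated constructor,
#'   [generateCompendium()] for the generator.
#' @export
setClass("CompendiumSpec",
  representation(
    nStudies = "integer",
    genesTotal = "integer",
    nYoung = "integer",
    nOld = "integer",
    fracUp = "numeric",
    fracDown = "numeric",
    effectSize = "numeric",
    studyBatchSd = "numeric",
    noiseSd = "numeric",
    nModules = "integer",
    refSetSize = "integer",
    refOverlapFrac = "numeric",
    rawScale = "logical",
    continuousAges = "logical",
    seed = "integer"
  )
)

setValidity("CompendiumSpec", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  msgs <- character(0)
  if (length(object@nStudies) != 1L || is.na(object@nStudies) || object@nStudies < 1L)
    msgs <- c(msgs, bad("nStudies", "must be a single count >= 1"))
  if (length(object@genesTotal) != 1L || is.na(object@genesTotal) || object@genesTotal < 1L)
    msgs <- c(msgs, bad("genesTotal", "must be a single count >= 1"))
  for (f in c("nYoung", "nOld")) {
    v <- slot(object, f)
    if (!(length(v) %in% c(1L, object@nStudies)) || anyNA(v))
      msgs <- c(msgs, bad(f, "must have length 1 or nStudies with no NA"))
    else if (any(v < 3L))
      msgs <- c(msgs, bad(f, "every study needs >= 3 samples per group"))
  }
  for (f in c("fracUp", "fracDown")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      msgs <- c(msgs, bad(f, "must be a proportion in [0, 1]"))
  }
  if (!anyNA(c(object@fracUp, object@fracDown)) &&
      object@fracUp + object@fracDown > 1 + 1e-12)
    msgs <- c(msgs, bad("fracUp", "fracUp + fracDown must be <= 1"))
  for (f in c("studyBatchSd", "noiseSd")) {
    v <- slot(object, f)
    if (length(v) != 1L || is.na(v) || v < 0)
      msgs <- c(msgs, bad(f, "must be a single non-negative number"))
  }
  if (length(object@effectSize) != 1L || is.na(object@effectSize))
    msgs <- c(msgs, bad("effectSize", "must be a single finite number"))
  if (object@nModules < 1L)
    msgs <- c(msgs, bad("nModules", "must be >= 1"))
  if (object@refSetSize < 0L)
    msgs <- c(msgs, bad("refSetSize", "must be >= 0"))
  if (is.na(object@refOverlapFrac) || object@refOverlapFrac < 0 || object@refOverlapFrac > 1)
    msgs <- c(msgs, bad("refOverlapFrac", "must be a proportion in [0, 1]"))
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, bad("seed", "must be a single integer"))
  if (length(msgs)) msgs else TRUE
})

#' Construct a validated CompendiumSpec
#'
#' @param nStudies number of studies.
#' @param genesTotal size of the shared gene universe.
#' @param nYoung,nOld per-study group sizes (scalar or one per study, each >= 3).
#' @param fracUp,fracDown proportions of truly age-up / age-down genes.
#' @param effectSize log2 mean shift (old - young) for planted genes.
#' @param studyBatchSd sd of per-study gene baseline offsets.
#' @param noiseSd residual sd on the log2 scale.
#' @param nModules planted community count for the synthetic PPI wiring.
#' @param refSetSize,refOverlapFrac synthetic aging reference-set size and the
#'   fraction of it taken from planted regulated genes.
#' @param rawScale generate raw-intensity (exponentiated) data instead of log2.
#' @param continuousAges draw ages uniformly over 20-90 instead of the
#'   two-bracket design.
#' @param seed RNG seed.
#' @return A [CompendiumSpec-class] object.
#' @examples
#' spec <- compendiumSpec(nStudies = 3, genesTotal = 100, seed = 1)
#' spec
#' @export
compendiumSpec <- function(nStudies = 5, genesTotal = 2000,
                           nYoung = 15, nOld = 15,
                           fracUp = 0.10, fracDown = 0.10,
                           effectSize = 1.0,
                           studyBatchSd = 0.5, noiseSd = 1.0,
                           nModules = 5, refSetSize = 100,
                           refOverlapFrac = 0.5,
                           rawScale = FALSE, continuousAges = FALSE,
                           seed = 1L) {
  new("CompendiumSpec",
      nStudies = as.integer(nStudies), genesTotal = as.integer(genesTotal),
      nYoung = as.integer(nYoung), nOld = as.integer(nOld),
      fracUp = as.numeric(fracUp), fracDown = as.numeric(fracDown),
      effectSize = as.numeric(effectSize),
      studyBatchSd = as.numeric(studyBatchSd), noiseSd = as.numeric(noiseSd),
      nModules = as.integer(nModules), refSetSize = as.integer(refSetSize),
      refOverlapFrac = as.numeric(refOverlapFrac),
      rawScale = isTRUE(rawScale), continuousAges = isTRUE(continuousAges),
      seed = as.integer(seed))
}

setMethod("show", "CompendiumSpec", function(object) {
  cat("CompendiumSpec:", object@nStudies, "studies,",
      object@genesTotal, "genes\n")
  cat("  group sizes young/old:", paste(object@nYoung, collapse = ","), "/",
      paste(object@nOld, collapse = ","), "\n")
  cat(sprintf("  planted up/down fractions: %.3g / %.3g at log2 delta %.3g\n",
              object@fracUp, object@fracDown, object@effectSize))
  cat(sprintf("  batch sd %.3g, noise sd %.3g, seed %d\n",
              object@studyBatchSd, object@noiseSd, object@seed))
})

#' Multi-study expression compendium
#'
#' Container for a harmonized set of studies. Each study is a
#' [SummarizedExperiment::SummarizedExperiment] with one `exprs` assay
#' (genes x samples) and column metadata `sample`, `group` (`young`/`old`)
#' and `age` (years). `geneUniverse` is the set of genes the meta-analysis is
#' run over (by default the intersection of per-study gene sets). `truth`
#' holds planted ground truth for synthetic compendia (empty list otherwise).
#'
#' @slot studies named list of `SummarizedExperiment` objects.
#' @slot geneUniverse character vector of gene identifiers.
#' @slot truth list; for synthetic data: `upGenes`, `downGenes`, `nullGenes`,
#'   `moduleAssignments`, `agingReferenceSet`.
#' @seealso [generateCompendium()], [buildCompendium()], [runDiffExpr()]
#' @export
setClass("Compendium",
  representation(studies = "list", geneUniverse = "character", truth = "list")
)

setValidity("Compendium", function(object) {
  msgs <- character(0)
  if (!length(object@studies))
    msgs <- c(msgs, "compendium has no studies")
  if (!length(object@geneUniverse))
    msgs <- c(msgs, "gene universe is empty")
  for (nm in names(object@studies)) {
    se <- object@studies[[nm]]
    if (!methods::is(se, "SummarizedExperiment")) {
      msgs <- c(msgs, sprintf("study '%s' is not a SummarizedExperiment", nm))
      next
    }
    cd <- SummarizedExperiment::colData(se)
    if (!all(c("group", "age") %in% colnames(cd)))
      msgs <- c(msgs, sprintf("study '%s' lacks group/age column metadata", nm))
    if (anyDuplicated(rownames(se)))
      msgs <- c(msgs, sprintf("study '%s' has duplicated gene IDs", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn Compendium-class number of studies.
#' @param x,object a `Compendium`.
#' @export
setMethod("length", "Compendium", function(x) length(x@studies))

#' Accessors for Compendium objects
#'
#' @param x a [Compendium-class].
#' @return `studies()` the named list of per-study SummarizedExperiments;
#'   `geneUniverse()` the character vector of universe genes;
#'   `plantedTruth()` the planted-truth list (empty for real data).
#' @export
studies <- function(x) x@studies

#' @rdname studies
#' @export
geneUniverse <- function(x) x@geneUniverse

#' @rdname studies
#' @export
plantedTruth <- function(x) x@truth

setMethod("show", "Compendium", function(object) {
  ns <- vapply(object@studies, ncol, 0L)
  cat("Compendium:", length(object@studies), "studies,",
      length(object@geneUniverse), "universe genes,",
      sum(ns), "samples\n")
  for (nm in names(object@studies)) {
    cd <- SummarizedExperiment::colData(object@studies[[nm]])
    cat(sprintf("  %s: %d genes x %d samples (%d young / %d old)\n",
                nm, nrow(object@studies[[nm]]), ncol(object@studies[[nm]]),
                sum(cd$group == "young"), sum(cd$group == "old")))
  }
  if (length(object@truth))
    cat("  planted truth:", length(object@truth$upGenes), "up,",
        length(object@truth$downGenes), "down\n")
})

#' Zero-order protein-protein interaction network
#'
#' A simple undirected graph over seed genes, with STRING-convention combined
#' scores (0-1000) on the edges. Only edges whose both endpoints are seed
#' genes and whose score passes the threshold are retained ("zero-order":
#' no added interactors). Seeds that end up with no retained edge are kept in
#' `isolatedSeeds`, not in the graph.
#'
#' @slot graph an `igraph` object (simple, undirected; edge attribute `score`).
#' @slot scoreThreshold minimum retained combined score.
#' @slot isolatedSeeds seed genes with no retained interaction.
#' @slot nSeeds number of seed genes queried.
#' @seealso [buildZeroOrderNetwork()], [networkCentralities()], [findModules()]
#' @export
setClass("PPINetwork",
  representation(graph = "ANY", scoreThreshold = "numeric",
                 isolatedSeeds = "character", nSeeds = "integer")
)

setValidity("PPINetwork", function(object) {
  msgs <- character(0)
  g <- object@graph
  if (!igraph::is_igraph(g)) return("graph slot must hold an igraph object")
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (any(igraph::which_loop(g))) msgs <- c(msgs, "graph must have no self-loops")
  if (any(igraph::which_multiple(g))) msgs <- c(msgs, "graph must have no duplicate edges")
  if (igraph::ecount(g) > 0) {
    sc <- igraph::E(g)$score
    if (is.null(sc)) msgs <- c(msgs, "edges must carry a 'score' attribute")
    else if (any(sc < object@scoreThreshold))
      msgs <- c(msgs, "all retained edges must meet the score threshold")
  }
  if (length(msgs)) msgs else TRUE
})

#' Accessors for PPINetwork objects
#'
#' @param x a [PPINetwork-class].
#' @return `ppiGraph()` the underlying igraph; `networkNodes()` the gene IDs
#'   in the graph; `isolatedSeeds()` seed genes dropped as isolated.
#' @export
ppiGraph <- function(x) x@graph

#' @rdname ppiGraph
#' @export
networkNodes <- function(x) igraph::V(x@graph)$name

#' @rdname ppiGraph
#' @export
isolatedSeeds <- function(x) x@isolatedSeeds

setMethod("show", "PPINetwork", function(object) {
  g <- object@graph
  cat(sprintf("PPINetwork: %d nodes, %d edges (score >= %g)\n",
              igraph::vcount(g), igraph::ecount(g), object@scoreThreshold))
  cat(sprintf("  from %d seed genes; %d isolated seeds excluded\n",
              object@nSeeds, length(object@isolatedSeeds)))
  comp <- igraph::components(g)
  if (comp$no > 0)
    cat(sprintf("  %d connected component(s); largest (continent) has %d nodes\n",
                comp$no, max(comp$csize)))
})
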