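#' Run the full network meta-analysis pipeline
#'
#' Orchestrates all stages end-to-end: load (or simulate) the multi-study
#' compendium, normalize if the data are on the raw scale, run per-study
#' moderated-t differential expression, combine evidence with the three
#' meta-analysis methods and form the consensus list, build the zero-order
#' PPI network on the consensus genes, rank hubs and extract
#' permutation-significant modules, run gene-set over-representation and
#' reference-set odds-ratio enrichment, and (when a qPCR table is supplied)
#' the 2^-ddCt follow-up. Per-stage TSVs and a JSON manifest (seed,
#' thresholds, per-stage counts, output checksums) are written to
#' `outputDir`; identical config + seed yields identical checksums.
#'
#' @param config named list (or path to a YAML file with the same keys):
#'   \describe{
#'     \item{compendiumDir / syntheticSpec}{either a directory written by
#'       [writeCompendium()] or a list of [compendiumSpec()] arguments.}
#'     \item{edgeFile}{optional TSV edge list; for synthetic runs the network
#'       is generated from the planted truth when absent.}
#'     \item{gmtFile}{optional GMT gene sets for ORA.}
#'     \item{qpcrFile}{optional qPCR Ct TSV.}
#'     \item{normalize}{logical; apply glog + quantile normalization
#'       (default `FALSE`: data already on log2 scale).}
#'     \item{perStudyP, alphaFdr, pCombined, voteThreshold, scoreThreshold,
#'       dcMin, topFraction, minSize, alpha, nPerm}{stage thresholds
#'       (defaults 0.05, 1, 0.001, 2, 900, 10, 0.10, 5, 0.05, 999).}
#'     \item{seed}{RNG seed recorded in the manifest.}
#'   }
#' @param outputDir directory for stage outputs and `manifest.json`.
#' @return the manifest, invisibly (a named list).
#' @examples
#' \donttest{
#' cfg <- list(syntheticSpec = list(nStudies = 3, genesTotal = 300,
#'                                  nYoung = 8, nOld = 8, seed = 11),
#'             nPerm = 199, seed = 11)
#' manifest <- runPipeline(cfg, tempfile("run"))
#' manifest$counts
#' }
#' @export
runPipeline <- function(config, outputDir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  defaults <- list(perStudyP = 0.05, alphaFdr = 1, pCombined = 0.001,
                   voteThreshold = 2, scoreThreshold = 900, dcMin = 10,
                   topFraction = 0.10, minSize = 5, alpha = 0.05,
                   nPerm = 999, seed = 1L, normalize = FALSE)
  cfg <- utils::modifyList(defaults, config)
  stopifnot(cfg$pCombined > 0, cfg$pCombined <= 1,
            cfg$voteThreshold >= 0, cfg$topFraction > 0, cfg$topFraction <= 1)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[agingMetaNet] ", sprintf(...))

  ## --- load or simulate -------------------------------------------------
  if (!is.null(cfg$syntheticSpec)) {
    spec <- do.call(compendiumSpec, cfg$syntheticSpec)
    comp <- generateCompendium(spec)
    msg("simulated %d studies x %d genes (seed %d)",
        length(comp), length(geneUniverse(comp)), spec@seed)
  } else if (!is.null(cfg$compendiumDir)) {
    comp <- readCompendium(cfg$compendiumDir)
    msg("loaded %d studies from %s", length(comp), cfg$compendiumDir)
  } else stop("config needs either 'syntheticSpec' or 'compendiumDir'")

  if (isTRUE(cfg$normalize)) {
    comp@studies <- lapply(comp@studies, function(se) {
      SummarizedExperiment::assay(se, "exprs") <-
        normalizeStudy(SummarizedExperiment::assay(se, "exprs"))
      se
    })
    msg("normalized studies (glog + quantile)")
  }

  ## --- per-study differential expression --------------------------------
  deList <- runDiffExpr(comp)
  sigLists <- lapply(deList, significantGenes,
                     alphaP = cfg$perStudyP, alphaFdr = cfg$alphaFdr)
  for (nm in names(deList)) {
    utils::write.table(deList[[nm]], file.path(outputDir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    msg("DE %s: %d/%d genes significant", nm, length(sigLists[[nm]]),
        nrow(deList[[nm]]))
  }
  overlap <- if (length(sigLists) >= 2) studyOverlap(sigLists) else NULL

  ## --- three-method meta-analysis + consensus ---------------------------
  meta <- metaAnalyze(deList, perStudyP = cfg$perStudyP)
  meta <- consensusGenes(meta, pCombined = cfg$pCombined,
                         voteThreshold = cfg$voteThreshold)
  consensus <- meta$gene[meta$consensus]
  nUp <- sum(meta$consensus & meta$direction == "up")
  nDown <- sum(meta$consensus & meta$direction == "down")
  pct <- directionPercentages(nDown, nUp)
  msg("meta-analysis: Fisher %d, fixed-effect %d, votes %d -> consensus %d (%g%% down / %g%% up)",
      sum(meta$sigFisher), sum(meta$sigFe), sum(meta$sigVotes),
      length(consensus), pct[["downPct"]], pct[["upPct"]])
  if (!length(consensus))
    warning("consensus gene list is empty; network stages skipped")
  utils::write.table(meta[, setdiff(colnames(meta), "members")],
                     file.path(outputDir, "meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- network stage ----------------------------------------------------
  hubs <- NULL; modules <- NULL; net <- NULL
  if (length(consensus)) {
    edges <- if (!is.null(cfg$edgeFile)) {
      utils::read.delim(cfg$edgeFile)
    } else if (length(plantedTruth(comp))) {
      truth <- plantedTruth(comp)
      generatePPI(truth$moduleAssignments, seed = cfg$seed)
    } else NULL
    if (!is.null(edges)) {
      net <- buildZeroOrderNetwork(edges, consensus,
                                   scoreThreshold = cfg$scoreThreshold)
      if (igraph::vcount(ppiGraph(net)) > 0) {
        dirs <- stats::setNames(meta$direction, meta$gene)
        cent <- networkCentralities(net, directions = dirs)
        hubs <- selectHubs(cent, dcMin = cfg$dcMin,
                           topFraction = cfg$topFraction,
                           totalGenes = length(consensus))
        mod <- findModules(net, minSize = cfg$minSize, alpha = cfg$alpha,
                           nPerm = cfg$nPerm, seed = cfg$seed)
        modules <- mod$modules
        msg("network: %d nodes, %d edges; %d hubs; %d significant modules",
            igraph::vcount(ppiGraph(net)), igraph::ecount(ppiGraph(net)),
            nrow(hubs), nrow(modules))
        utils::write.table(cent, file.path(outputDir, "centralities.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(hubs, file.path(outputDir, "hubs.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(mod$candidates, file.path(outputDir, "modules.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeGraphML(net, file.path(outputDir, "network.graphml"))
      } else msg("zero-order network is empty at score >= %g", cfg$scoreThreshold)
    }
  }

  ## --- enrichment -------------------------------------------------------
  enrich <- NULL; refEnrich <- NULL
  background <- geneUniverse(comp)
  if (length(consensus)) {
    sets <- if (!is.null(cfg$gmtFile)) readGmt(cfg$gmtFile)
            else if (length(plantedTruth(comp)))
              list(agingReference = plantedTruth(comp)$agingReferenceSet)
            else NULL
    if (!is.null(sets)) {
      enrich <- ora(consensus, sets, background)
      utils::write.table(enrich, file.path(outputDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(plantedTruth(comp)) && !is.null(modules) && nrow(modules)) {
        refEnrich <- do.call(rbind, lapply(seq_len(nrow(modules)), function(i) {
          genesIn <- strsplit(modules$members[i], ",")[[1]]
          cbind(module = modules$id[i],
                oddsRatioEnrichment(genesIn,
                                    plantedTruth(comp)$agingReferenceSet,
                                    background))
        }))
        utils::write.table(refEnrich, file.path(outputDir, "module_or.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  ## --- qPCR follow-up ---------------------------------------------------
  qpcrRes <- NULL
  if (!is.null(cfg$qpcrFile)) {
    qpcrRes <- ddct(utils::read.delim(cfg$qpcrFile))
    utils::write.table(qpcrRes$groupSummary,
                       file.path(outputDir, "qpcr_folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- manifest ---------------------------------------------------------
  outFiles <- sort(list.files(outputDir, pattern = "\\.(tsv|graphml)$"))
  manifest <- list(
    package = "agingMetaNet",
    version = as.character(utils::packageVersion("agingMetaNet")),
    seed = cfg$seed,
    thresholds = cfg[c("perStudyP", "alphaFdr", "pCombined", "voteThreshold",
                       "scoreThreshold", "dcMin", "topFraction", "minSize",
                       "alpha", "nPerm")],
    counts = list(
      studies = length(comp),
      universeGenes = length(geneUniverse(comp)),
      perStudySignificant = vapply(sigLists, length, 0L),
      allStudyOverlap = if (is.null(overlap)) NA_integer_
                        else length(overlap$intersection),
      fisherSignificant = sum(meta$sigFisher),
      fixedEffectSignificant = sum(meta$sigFe),
      voteSignificant = sum(meta$sigVotes),
      consensus = length(consensus),
      consensusDown = nDown, consensusUp = nUp,
      downPct = unname(pct[["downPct"]]), upPct = unname(pct[["upPct"]]),
      networkNodes = if (is.null(net)) 0L else igraph::vcount(ppiGraph(net)),
      networkEdges = if (is.null(net)) 0L else igraph::ecount(ppiGraph(net)),
      hubs = if (is.null(hubs)) 0L else nrow(hubs),
      significantModules = if (is.null(modules)) 0L else nrow(modules)),
    consensusGenes = consensus,
    checksums = as.list(tools::md5sum(file.path(outputDir, outFiles))))
  names(manifest$checksums) <- outFiles
  jsonlite::write_json(manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
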