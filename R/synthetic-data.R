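#' Generate a synthetic multi-study compendium with planted truth
#'
#' Simulates per-study gene x sample log2 expression tables emulating a
#' multi-study frontal-cortex aging compendium: a shared gene universe, a
#' young (20-40 y) and an old (60-90 y) group per study, per-study batch
#' offsets, and a planted set of genes whose old-group mean is shifted by
#' `effectSize(spec)` (up) or its negative (down). All remaining genes are
#' null. The planted truth (up/down/null partitions, community labels for the
#' synthetic interaction network, and an aging reference set overlapping the
#' planted genes) is attached so downstream stages can be scored against it.
#'
#' Expression is simulated directly on the log2 scale:
#' `baseline(gene) + batch(study, gene) + delta * 1[old, planted] + noise`.
#' With `rawScale = TRUE` the matrix is exponentiated (`2^x`) and multiplied
#' by log-normal noise, yielding raw intensities for exercising the
#' normalization path.
#'
#' @param spec a [CompendiumSpec-class] (see [compendiumSpec()]).
#' @return A [Compendium-class] whose `truth` list carries `upGenes`,
#'   `downGenes`, `nullGenes`, `moduleAssignments` (gene -> community label
#'   over the planted genes) and `agingReferenceSet`.
#' @examples
#' comp <- generateCompendium(compendiumSpec(nStudies = 2, genesTotal = 50,
#'                                           seed = 7))
#' comp
#' @export
generateCompendium <- function(spec) {
  methods::validObject(spec)
  set.seed(spec@seed)
  G <- spec@genesTotal
  genes <- sprintf("G%05d", seq_len(G))
  nUp <- round(spec@fracUp * G)
  nDown <- round(spec@fracDown * G)
  regulated <- sample(genes, nUp + nDown)
  upGenes <- sort(head(regulated, nUp))
  downGenes <- sort(regulated[seq_len(nDown) + nUp])
  nullGenes <- sort(setdiff(genes, c(upGenes, downGenes)))

  baseline <- stats::setNames(rnorm(G, mean = 7, sd = 1.5), genes)
  delta <- stats::setNames(numeric(G), genes)
  delta[upGenes] <- spec@effectSize
  delta[downGenes] <- -spec@effectSize

  nY <- rep_len(spec@nYoung, spec@nStudies)
  nO <- rep_len(spec@nOld, spec@nStudies)
  studyList <- vector("list", spec@nStudies)
  names(studyList) <- sprintf("study%d", seq_len(spec@nStudies))
  for (s in seq_len(spec@nStudies)) {
    n <- nY[s] + nO[s]
    group <- c(rep("young", nY[s]), rep("old", nO[s]))
    if (spec@continuousAges) {
      age <- round(runif(n, 20, 90), 1)
      group <- ifelse(age <= 55, "young", "old")
    } else {
      age <- round(c(runif(nY[s], 20, 40), runif(nO[s], 60, 90)), 1)
    }
    sampleIds <- sprintf("%s_s%02d", names(studyList)[s], seq_len(n))
    batch <- rnorm(G, 0, spec@studyBatchSd)
    mat <- matrix(baseline + batch, nrow = G, ncol = n) +
      outer(delta, as.numeric(group == "old")) +
      matrix(rnorm(G * n, 0, spec@noiseSd), G, n)
    if (spec@rawScale)
      mat <- 2^mat * exp(matrix(rnorm(G * n, 0, 0.05), G, n))
    dimnames(mat) <- list(genes, sampleIds)
    cd <- S4Vectors::DataFrame(sample = sampleIds, study = names(studyList)[s],
                               group = group, age = age, row.names = sampleIds)
    studyList[[s]] <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat), colData = cd)
  }

  moduleAssignments <- character(0)
  if (length(regulated)) {
    moduleAssignments <- stats::setNames(
      sprintf("M%d", rep_len(seq_len(spec@nModules), length(regulated))),
      sort(regulated))
  }
  refFromPlanted <- min(round(spec@refOverlapFrac * spec@refSetSize),
                        length(regulated))
  nFromNull <- min(spec@refSetSize - refFromPlanted, length(nullGenes))
  agingRef <- sort(c(if (refFromPlanted) sample(regulated, refFromPlanted),
                     if (nFromNull) sample(nullGenes, nFromNull)))

  methods::new("Compendium", studies = studyList, geneUniverse = genes,
               truth = list(upGenes = upGenes, downGenes = downGenes,
                            nullGenes = nullGenes,
                            moduleAssignments = moduleAssignments,
                            agingReferenceSet = agingRef))
}

#' Generate a scored synthetic interaction network (planted partition)
#'
#' Draws an undirected simple graph over genes carrying community labels:
#' node pairs within the same community are connected with probability
#' `intraP`, pairs in different communities with `interP < intraP`. Each edge
#' receives an integer combined score drawn uniformly from `scoreRange`
#' (STRING convention, 0-1000; the default 900-999 keeps every synthetic edge
#' above the standard high-confidence cutoff). Designated hub genes are given
#' extra random attachments until their degree reaches `hubDegree`.
#'
#' @param assignments named character vector: gene -> community label. Genes
#'   sharing a label form a planted community; a label seen once is background.
#' @param intraP,interP within- / between-community edge probabilities,
#'   `0 <= interP < intraP <= 1`.
#' @param scoreRange integer length-2 range for combined scores.
#' @param seed RNG seed.
#' @param hubGenes genes to over-wire as hubs (may be absent from
#'   `assignments`; they are added as background nodes).
#' @param hubDegree target minimum degree for each hub gene.
#' @return A data.frame edge list with columns `protein1`, `protein2`,
#'   `combined_score`, suitable for [buildZeroOrderNetwork()].
#' @examples
#' asg <- setNames(rep(c("A", "B"), each = 4), paste0("g", 1:8))
#' edges <- generatePPI(asg, intraP = 1, interP = 0, seed = 1)
#' head(edges)
#' @export
generatePPI <- function(assignments, intraP = 0.3, interP = 0.01,
                        scoreRange = c(900L, 999L), seed = 1L,
                        hubGenes = character(0), hubDegree = 0L) {
  if (!(interP >= 0 && intraP <= 1 && interP < intraP))
    stop("edge probabilities must satisfy 0 <= interP < intraP <= 1")
  set.seed(as.integer(seed))
  genes <- union(names(assignments), hubGenes)
  lab <- stats::setNames(rep("background", length(genes)), genes)
  lab[names(assignments)] <- assignments

  edges <- list()
  comms <- split(genes, lab[genes])
  ## within-community pairs: enumerate and keep with prob intraP
  for (cm in comms) {
    if (length(cm) < 2) next
    prs <- utils::combn(sort(cm), 2)
    keep <- runif(ncol(prs)) < intraP
    if (any(keep))
      edges[[length(edges) + 1L]] <- data.frame(
        protein1 = prs[1, keep], protein2 = prs[2, keep])
  }
  ## between-community pairs: sample a binomial count of pairs, then pairs
  idx <- stats::setNames(seq_along(genes), genes)
  commIdx <- lapply(comms, function(cm) idx[cm])
  cn <- names(comms)
  if (length(cn) > 1 && interP > 0) {
    for (i in seq_len(length(cn) - 1)) for (j in seq((i + 1), length(cn))) {
      a <- commIdx[[i]]; b <- commIdx[[j]]
      nPairs <- length(a) * length(b)
      k <- rbinom(1, nPairs, interP)
      if (k == 0) next
      picks <- sample.int(nPairs, k)
      ia <- a[((picks - 1) %% length(a)) + 1]
      ib <- b[((picks - 1) %/% length(a)) + 1]
      edges[[length(edges) + 1L]] <- data.frame(
        protein1 = genes[pmin(ia, ib)], protein2 = genes[pmax(ia, ib)])
    }
  }
  el <- if (length(edges)) do.call(rbind, edges)
        else data.frame(protein1 = character(0), protein2 = character(0))

  ## over-wire requested hubs up to the target degree
  for (h in hubGenes) {
    deg <- sum(el$protein1 == h | el$protein2 == h)
    if (deg >= hubDegree) next
    partners <- sum(el$protein1 == h) + sum(el$protein2 == h)
    existing <- unique(c(el$protein2[el$protein1 == h],
                         el$protein1[el$protein2 == h]))
    candidates <- setdiff(genes, c(h, existing))
    add <- sample(candidates, min(hubDegree - deg, length(candidates)))
    if (length(add))
      el <- rbind(el, data.frame(protein1 = pmin(h, add),
                                 protein2 = pmax(h, add)))
  }
  el <- unique(el)
  el$combined_score <- if (nrow(el))
    sample(seq(scoreRange[1], scoreRange[2]), nrow(el), replace = TRUE)
  else integer(0)
  rownames(el) <- NULL
  el
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a relative-quantification experiment: the reference gene's Ct is
#' constant in expectation across groups, while each target gene's Ct in the
#' treated group is shifted by `-log2(fold)` so that the 2^-ddCt method
#' recovers the requested fold change.
#'
#' @param genes character vector of target gene names.
#' @param nControl,nTreated samples per group.
#' @param foldChanges positive fold changes (recycled along `genes`).
#' @param ctNoiseSd Gaussian Ct noise (cycles).
#' @param seed RNG seed.
#' @param refCt,targetCt expected reference / control-group target Ct.
#' @return Long-format data.frame: `sample`, `group` (`control`/`treated`),
#'   `gene`, `role` (`target`/`reference`), `ct`.
#' @examples
#' tab <- generateQpcr("Hdac1", foldChanges = 4, ctNoiseSd = 0, seed = 1)
#' ddct(tab)$groupSummary
#' @export
generateQpcr <- function(genes, nControl = 6, nTreated = 6, foldChanges = 2,
                         ctNoiseSd = 0.1, seed = 1L,
                         refCt = 18, targetCt = 25) {
  if (any(foldChanges <= 0)) stop("foldChanges must be positive")
  set.seed(as.integer(seed))
  foldChanges <- rep_len(foldChanges, length(genes))
  samples <- c(sprintf("ctl%02d", seq_len(nControl)),
               sprintf("trt%02d", seq_len(nTreated)))
  group <- rep(c("control", "treated"), c(nControl, nTreated))
  rows <- list()
  for (i in seq_along(genes)) {
    shift <- ifelse(group == "treated", -log2(foldChanges[i]), 0)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = samples, group = group, gene = genes[i], role = "target",
      ct = targetCt + shift + rnorm(length(samples), 0, ctNoiseSd))
  }
  rows[[length(rows) + 1L]] <- data.frame(
    sample = samples, group = group, gene = "reference", role = "reference",
    ct = refCt + rnorm(length(samples), 0, ctNoiseSd))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read compendium files (TSV, GMT, JSON)
#'
#' `writeCompendium()` serializes a compendium the way public expression
#' repositories are usually mirrored on disk: one expression TSV per study
#' (genes in rows, header row = sample IDs), one combined sample-metadata TSV
#' (`sample`, `study`, `group`, `age`), and, when planted truth is present, a
#' `truth.json`. `readCompendium()` reads the same layout back.
#'
#' @param comp a [Compendium-class].
#' @param dir output directory (created if needed).
#' @return `writeCompendium()` the directory, invisibly; `readCompendium()` a
#'   [Compendium-class].
#' @export
writeCompendium <- function(comp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metas <- list()
  for (nm in names(comp@studies)) {
    se <- comp@studies[[nm]]
    mat <- SummarizedExperiment::assay(se, "exprs")
    df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(nm, "_exprs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    metas[[nm]] <- as.data.frame(SummarizedExperiment::colData(se))
  }
  utils::write.table(do.call(rbind, metas), file.path(dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(comp@truth))
    jsonlite::write_json(comp@truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' @rdname writeCompendium
#' @export
readCompendium <- function(dir) {
  meta <- utils::read.delim(file.path(dir, "sample_meta.tsv"))
  studyList <- list()
  for (nm in unique(meta$study)) {
    df <- utils::read.delim(file.path(dir, paste0(nm, "_exprs.tsv")),
                            check.names = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$gene
    sm <- meta[meta$study == nm, , drop = FALSE]
    mat <- mat[, sm$sample, drop = FALSE]
    cd <- S4Vectors::DataFrame(sm, row.names = sm$sample)
    studyList[[nm]] <- SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = mat), colData = cd)
  }
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath)) {
    tr <- jsonlite::read_json(truthPath, simplifyVector = TRUE)
    if (!is.null(tr$moduleAssignments))
      tr$moduleAssignments <- unlist(tr$moduleAssignments)
    tr
  } else list()
  universe <- Reduce(intersect, lapply(studyList, rownames))
  methods::new("Compendium", studies = studyList,
               geneUniverse = universe, truth = truth)
}

#' Write or read gene sets in GMT format
#'
#' Standard GMT: one set per line — set name, description, then tab-separated
#' member genes.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional per-set description strings.
#' @return `readGmt()` returns a named list of character vectors.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGmt
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, "", 1))
}

#' Write a STRING-style scored edge list
#'
#' @param edges data.frame with `protein1`, `protein2`, `combined_score`.
#' @param path file path.
#' @export
writeEdgeList <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
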