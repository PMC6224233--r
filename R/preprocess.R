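#' Collapse probe-level values to gene level
#'
#' Multiple probes mapping to the same gene are collapsed with a summary
#' statistic (mean by default, median by option); probes absent from the map
#' are dropped and counted.
#'
#' @param probeMatrix numeric matrix, probes x samples.
#' @param probeToGene named character vector or two-column data.frame
#'   (`probe`, `gene`) mapping probe IDs to gene IDs.
#' @param rule `"mean"` or `"median"`.
#' @return gene x sample matrix with attribute `droppedProbes` (count of
#'   unmapped probes).
#' @examples
#' m <- matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' collapseProbes(m, c(p1 = "g1", p2 = "g1"))
#' @export
collapseProbes <- function(probeMatrix, probeToGene, rule = c("mean", "median")) {
  rule <- match.arg(rule)
  if (is.data.frame(probeToGene))
    probeToGene <- stats::setNames(as.character(probeToGene[[2]]),
                                   as.character(probeToGene[[1]]))
  if (!length(probeToGene)) stop("probe-to-gene map is empty")
  mapped <- rownames(probeMatrix) %in% names(probeToGene)
  if (!any(mapped)) stop("all probes unmapped")
  m <- probeMatrix[mapped, , drop = FALSE]
  gene <- probeToGene[rownames(m)]
  fun <- if (rule == "mean") colMeans else
    function(x) apply(x, 2, stats::median)
  groups <- split(seq_len(nrow(m)), gene)
  out <- do.call(rbind, lapply(groups, function(ix) fun(m[ix, , drop = FALSE])))
  dimnames(out) <- list(names(groups), colnames(probeMatrix))
  attr(out, "droppedProbes") <- sum(!mapped)
  out
}

#' Generalized-log (glog2) variance-stabilizing transform
#'
#' `glog2(x) = log2((x + sqrt(x^2 + c^2)) / 2)`. For `x >> c` this converges
#' to `log2(x)`; at `x = 0` it equals `log2(c/2)`, so zeros are handled. It is
#' monotone increasing and stabilizes the variance of intensity data the way
#' a VSN step does, with a closed form. The calibration constant `c` defaults
#' to a low quantile of the positive values.
#'
#' @param x numeric vector or matrix of raw intensities (>= 0).
#' @param c calibration constant; if `NULL`, set from `cQuantile`.
#' @param cQuantile quantile of positive values used to set `c`.
#' @return transformed values, same shape as `x`.
#' @export
glog2 <- function(x, c = NULL, cQuantile = 0.05) {
  if (any(x < 0, na.rm = TRUE)) stop("glog2 requires non-negative values")
  if (is.null(c)) {
    pos <- x[x > 0 & is.finite(x)]
    c <- if (length(pos)) stats::quantile(pos, cQuantile, names = FALSE) else 1
  }
  log2((x + sqrt(x^2 + c^2)) / 2)
}

#' Quantile-normalize the columns of a matrix
#'
#' After normalization every sample shares the same empirical distribution:
#' each sample's sorted vector equals the across-sample mean of sorted
#' vectors. Ties are handled by rank averaging, so constant columns do not
#' error. Idempotent.
#'
#' @param mat numeric matrix, genes x samples.
#' @return normalized matrix with the same dimnames.
#' @export
quantileNormalize <- function(mat) {
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Normalize one study's expression matrix
#'
#' Applies, in order, the steps of the standard microarray harmonization
#' recipe: a log2 + variance-stabilization step (implemented jointly as the
#' generalized-log [glog2()], which behaves as `log2` away from zero) and
#' quantile normalization across samples. Data already on the log2 scale can
#' skip the glog step with `steps = "quantile"`.
#'
#' @param mat genes x samples matrix.
#' @param steps character subset of `c("glog", "quantile")`, applied in the
#'   given order. `"log2"` and `"vsn"` are accepted aliases for `"glog"`
#'   (applied once).
#' @param glogQuantile quantile defining the glog calibration constant.
#' @return normalized matrix.
#' @export
normalizeStudy <- function(mat, steps = c("glog", "quantile"),
                           glogQuantile = 0.05) {
  steps[steps %in% c("log2", "vsn")] <- "glog"
  steps <- unique(match.arg(steps, c("glog", "quantile"), several.ok = TRUE))
  for (s in steps) {
    mat <- switch(s,
      glog = glog2(mat, cQuantile = glogQuantile),
      quantile = quantileNormalize(mat))
  }
  mat
}

#' Assign samples to age groups and apply the inclusion rule
#'
#' Samples are classified as `young` (ages 20-40) or `old` (60-90); samples
#' outside both brackets are excluded. A study is retained only if both
#' groups keep at least `minPerGroup` samples — the standard multi-study
#' inclusion rule. Rejection is reported, not raised.
#'
#' @param sampleMeta data.frame with columns `sample` and `age`.
#' @param youngRange,oldRange inclusive age brackets in years.
#' @param minPerGroup minimum samples per group for study retention.
#' @return list: `meta` (retained samples with a `group` column), `excluded`
#'   (sample IDs outside both brackets), `retained` (logical: study passes),
#'   `reason` (why not, or `NA`).
#' @examples
#' m <- data.frame(sample = letters[1:6], age = c(25, 35, 30, 65, 70, 80))
#' assignAgeGroups(m)$retained
#' @export
assignAgeGroups <- function(sampleMeta, youngRange = c(20, 40),
                            oldRange = c(60, 90), minPerGroup = 3) {
  if (is.null(sampleMeta$age)) stop("sample metadata must contain ages")
  age <- sampleMeta$age
  group <- rep(NA_character_, length(age))
  group[age >= youngRange[1] & age <= youngRange[2]] <- "young"
  group[age >= oldRange[1] & age <= oldRange[2]] <- "old"
  excluded <- sampleMeta$sample[is.na(group)]
  meta <- sampleMeta[!is.na(group), , drop = FALSE]
  meta$group <- group[!is.na(group)]
  nY <- sum(meta$group == "young"); nO <- sum(meta$group == "old")
  retained <- nY >= minPerGroup && nO >= minPerGroup
  list(meta = meta, excluded = as.character(excluded), retained = retained,
       reason = if (retained) NA_character_ else
         sprintf("fewer than %d samples in a group (%d young, %d old)",
                 minPerGroup, nY, nO))
}

#' Assemble a harmonized compendium from per-study experiments
#'
#' Determines the shared gene universe (intersection of per-study gene sets
#' by default, or the union of genes measured in at least `minStudies`
#' studies) and subsets every study to it, preserving any planted truth.
#'
#' @param studyList named list of `SummarizedExperiment`s (assay `exprs`,
#'   colData `group`/`age`).
#' @param universeMode `"intersection"` or `"union"`.
#' @param minStudies for union mode, minimum number of studies a gene must be
#'   measured in.
#' @param truth optional planted-truth list to carry along.
#' @return a [Compendium-class].
#' @export
buildCompendium <- function(studyList, universeMode = c("intersection", "union"),
                            minStudies = 2, truth = list()) {
  universeMode <- match.arg(universeMode)
  geneLists <- lapply(studyList, rownames)
  universe <- if (universeMode == "intersection") {
    Reduce(intersect, geneLists)
  } else {
    tab <- table(unlist(geneLists))
    names(tab)[tab >= minStudies]
  }
  if (!length(universe)) stop("gene universe is empty")
  studyList <- lapply(studyList, function(se)
    se[intersect(universe, rownames(se)), ])
  methods::new("Compendium", studies = studyList,
               geneUniverse = sort(universe), truth = truth)
}
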