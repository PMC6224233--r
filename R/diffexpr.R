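#' Invert the trigamma function
#'
#' Newton iteration on `1/trigamma`, used when estimating the prior degrees
#' of freedom of the variance prior by method of moments. Converges in a few
#' steps for any positive input.
#'
#' @param x positive values.
#' @param tol convergence tolerance.
#' @param maxIter maximum Newton iterations.
#' @return y with `trigamma(y) = x`; `Inf` where `x` is 0 (or tiny).
#' @keywords internal
trigammaInverse <- function(x, tol = 1e-8, maxIter = 50) {
  y <- 0.5 + 1 / x  # good starting value: trigamma(y) ~ 1/y for large y
  y[x > 1e7] <- 1 / sqrt(x[x > 1e7])
  for (i in seq_len(maxIter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(-dif / y, na.rm = TRUE) < tol) break
  }
  y[x < 1e-8] <- Inf
  y
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Limma-style differential expression for a two-group design. Per-gene
#' residual variances `s^2` (with `d = n1 + n2 - 2` df) are shrunk towards a
#' prior variance `s0^2` with prior df `d0`, estimated by method of moments
#' on `log(s^2)` via trigamma inversion (the Smyth 2004 contract):
#' `s_post^2 = (d0 s0^2 + d s^2) / (d0 + d)`, moderated
#' `t = effect / (s_post sqrt(1/n1 + 1/n2))` referred to a t-distribution
#' with `d + d0` df. `d0 = Inf` (all variances consistent with a common
#' value) gives full shrinkage; `d0 = 0` recovers the ordinary t-test.
#'
#' @param mat genes x samples log2 expression matrix.
#' @param groups factor/character per sample with levels including
#'   `refLevel` and `testLevel`.
#' @param refLevel,testLevel group labels; effect = mean(test) - mean(ref)
#'   (old minus young by default).
#' @param d0 override the prior df (e.g. `0` for no shrinkage); `NULL`
#'   estimates it from the data.
#' @param d0Cap cap above which the estimated prior df is treated as infinite.
#' @return data.frame (one row per gene): `gene`, `effect` (log2 old-young),
#'   `se` (posterior), `t` (ordinary), `tMod`, `df` (residual d), `d0`,
#'   `s02` (prior variance), `p`, `fdr` (Benjamini-Hochberg), `direction`.
#'   Genes with zero variance in both groups get `p = 1` with a warning.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' res <- moderatedT(m, rep(c("young", "old"), each = 5))
#' head(res)
#' @export
moderatedT <- function(mat, groups, refLevel = "young", testLevel = "old",
                       d0 = NULL, d0Cap = 1e6) {
  i1 <- which(groups == refLevel); i2 <- which(groups == testLevel)
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- apply(mat[, i1, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, i2, drop = FALSE], 1, stats::var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  effect <- m2 - m1
  scale2 <- 1 / n1 + 1 / n2

  zeroVar <- s2 <= 0
  if (any(zeroVar))
    warning(sum(zeroVar), " gene(s) with zero variance in both groups; p set to 1")

  ok <- !zeroVar & is.finite(s2)
  if (is.null(d0)) {
    ## method of moments on z = log(s^2): E z = log(s0^2) + digamma(d0/2) -
    ## log(d0/2) + [digamma(d/2) - log(d/2)]; Var z = trigamma(d/2) + trigamma(d0/2)
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e)
    rhs <- evar - trigamma(d / 2)
    if (is.na(rhs) || rhs <= 0) {
      d0 <- Inf
      s02 <- exp(mean(e))
    } else {
      d0 <- 2 * trigammaInverse(rhs)
      s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  } else {
    s02 <- if (d0 > 0) mean(s2[ok]) else NA_real_
  }
  if (is.finite(d0) && d0 > d0Cap) d0 <- Inf

  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    if (d0 == 0) s2 else (d0 * s02 + d * s2) / (d0 + d)
  tOrd <- effect / sqrt(s2 * scale2)
  tMod <- effect / sqrt(s2post * scale2)
  dfTotal <- if (is.infinite(d0)) Inf else d + d0
  p <- 2 * stats::pt(-abs(tMod), df = if (is.finite(dfTotal)) dfTotal else 1e9)
  p[zeroVar] <- 1
  tMod[zeroVar] <- 0

  out <- data.frame(
    gene = rownames(mat), effect = effect, se = sqrt(s2post * scale2),
    t = tOrd, tMod = tMod, df = d, d0 = d0, s02 = s02, p = p,
    fdr = bhFdr(p),
    direction = ifelse(effect >= 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' `stats::p.adjust`); order-preserving, adjusted values are >= raw p and
#' <= 1.
#'
#' @param pvals numeric p-values in \[0, 1\]; `NaN` is rejected.
#' @return adjusted p-values in the input order.
#' @export
bhFdr <- function(pvals) {
  if (any(is.nan(pvals))) stop("NaN p-values are not allowed")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Run per-study differential expression over a compendium
#'
#' Applies [moderatedT()] to every study restricted to the compendium's gene
#' universe.
#'
#' @param comp a [Compendium-class].
#' @param ... passed to [moderatedT()].
#' @return named list of per-study result data.frames.
#' @export
runDiffExpr <- function(comp, ...) {
  lapply(studies(comp), function(se) {
    mat <- SummarizedExperiment::assay(se, "exprs")[geneUniverse(comp), ,
                                                    drop = FALSE]
    moderatedT(mat, SummarizedExperiment::colData(se)$group, ...)
  })
}

#' Significant genes per study and their cross-study overlap
#'
#' `significantGenes()` filters one study's results at the configured p and
#' FDR thresholds; `studyOverlap()` intersects per-study significant lists
#' and reports the full Venn cell counts (one count per membership pattern).
#'
#' @param de a [moderatedT()] result data.frame.
#' @param alphaP,alphaFdr per-study p and FDR thresholds; both are applied
#'   (set `alphaFdr = 1` to use p only).
#' @return `significantGenes()`: character vector.
#' @export
significantGenes <- function(de, alphaP = 0.05, alphaFdr = 0.05) {
  de$gene[de$p < alphaP & de$fdr < alphaFdr]
}

#' @rdname significantGenes
#' @param geneLists named list (>= 2) of per-study significant gene vectors.
#' @return `studyOverlap()`: list with `intersection` (genes significant in
#'   every study) and `vennCounts` (named integer vector; names are
#'   `/`-separated study subsets).
#' @examples
#' studyOverlap(list(s1 = c("A", "B"), s2 = c("B", "C")))$intersection
#' @export
studyOverlap <- function(geneLists) {
  if (length(geneLists) < 2) stop("need at least 2 gene lists")
  genes <- unique(unlist(geneLists))
  member <- vapply(geneLists, function(g) genes %in% g,
                   logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(geneLists)))
  pattern <- apply(member, 1, function(r)
    paste(names(geneLists)[r], collapse = "/"))
  counts <- table(pattern)
  list(intersection = sort(genes[rowSums(member) == length(geneLists)]),
       vennCounts = stats::setNames(as.integer(counts), names(counts)))
}
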