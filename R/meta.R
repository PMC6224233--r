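#' Fisher's method for combining independent p-values
#'
#' `X = -2 * sum(log(p))`, referred to a chi-square distribution with `2k`
#' degrees of freedom where `k` is the number of available studies. Missing
#' p-values are skipped with df reduced accordingly; exact zeros are clamped
#' to the smallest positive double with a warning. For `k = 1` the combined
#' p equals the input p.
#'
#' @param pvals per-study p-values (NAs allowed, skipped).
#' @return list: `X`, `df`, `p`.
#' @examples
#' fisherCombine(c(0.5, 0.5))  # X = 2.7726, p ~ 0.5966
#' @export
fisherCombine <- function(pvals) {
  p <- pvals[!is.na(pvals)]
  if (!length(p)) return(list(X = NA_real_, df = 0L, p = NA_real_))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(X = X, df = df, p = stats::pchisq(X, df, lower.tail = FALSE))
}

#' Inverse-variance fixed-effect meta-analysis with Cochran's Q
#'
#' Studies are weighted by inverse squared standard error:
#' `pooled = sum(w e) / sum(w)` with `w = 1/SE^2`, `pooledSE = 1/sqrt(sum w)`.
#' Heterogeneity is summarized by Cochran's
#' `Q = sum(w (e - pooled)^2)`, referred to a chi-square with `k - 1` df.
#' The pooled z gives a two-sided p. With a single study the pooled estimate
#' is that study and Q is reported missing.
#'
#' @param effects per-study effect estimates (log2 differences).
#' @param ses per-study standard errors (> 0). NA pairs are skipped.
#' @return list: `effect`, `se`, `z`, `p`, `Q`, `Qdf`, `Qp`, `k`.
#' @examples
#' fixedEffectCombine(c(0, 2), c(1, 1))  # pooled 1, Q = 2
#' @export
fixedEffectCombine <- function(effects, ses) {
  ok <- !is.na(effects) & !is.na(ses)
  e <- effects[ok]; s <- ses[ok]
  k <- length(e)
  if (!k) return(list(effect = NA_real_, se = NA_real_, z = NA_real_,
                      p = NA_real_, Q = NA_real_, Qdf = NA_integer_,
                      Qp = NA_real_, k = 0L))
  if (any(s <= 0)) stop("standard errors must be positive")
  w <- 1 / s^2
  pooled <- sum(w * e) / sum(w)
  pooledSe <- 1 / sqrt(sum(w))
  z <- pooled / pooledSe
  if (k >= 2) {
    Q <- sum(w * (e - pooled)^2)
    Qdf <- k - 1L
    Qp <- stats::pchisq(Q, Qdf, lower.tail = FALSE)
  } else {
    Q <- NA_real_; Qdf <- NA_integer_; Qp <- NA_real_
  }
  list(effect = pooled, se = pooledSe, z = z,
       p = 2 * stats::pnorm(-abs(z)), Q = Q, Qdf = Qdf, Qp = Qp, k = k)
}

#' Vote counting across studies
#'
#' A gene's vote count is the number of studies calling it significant at
#' the per-study threshold. The direction-consistent variant counts only
#' studies agreeing with the majority sign.
#'
#' @param pvals per-study p-values (NAs skipped).
#' @param directions optional per-study `"up"`/`"down"` (or signed numbers);
#'   required for `directionConsistent = TRUE`.
#' @param threshold per-study significance level.
#' @param directionConsistent count only majority-sign studies.
#' @return integer vote count.
#' @examples
#' voteCount(c(0.01, 0.2, 0.04, 0.6, 0.03))  # 3
#' @export
voteCount <- function(pvals, directions = NULL, threshold = 0.05,
                      directionConsistent = FALSE) {
  ok <- !is.na(pvals)
  sig <- ok & pvals < threshold
  if (!directionConsistent) return(sum(sig))
  if (is.null(directions)) stop("directions needed for direction-consistent votes")
  dir <- if (is.numeric(directions)) ifelse(directions >= 0, "up", "down")
         else as.character(directions)
  sigDir <- dir[sig]
  if (!length(sigDir)) return(0L)
  majority <- names(which.max(table(sigDir)))
  sum(sigDir == majority)
}

#' Three-method meta-analysis across studies
#'
#' For every gene in the universe, combines the per-study moderated-t
#' evidence with Fisher's method, the inverse-variance fixed-effect model
#' (with Cochran's Q) and vote counting, then applies the consensus rule via
#' [consensusGenes()].
#'
#' @param deList named list of per-study [moderatedT()] result data.frames.
#' @param perStudyP per-study significance level for vote counting.
#' @param minStudies genes present in fewer studies are dropped.
#' @return data.frame, one row per gene: `gene`, `k` (studies available),
#'   `fisherX`, `fisherDf`, `fisherP`, `feEffect`, `feSe`, `feZ`, `feP`,
#'   `Q`, `Qdf`, `Qp`, `votes`.
#' @seealso [consensusGenes()] for significance flags and the consensus set.
#' @export
metaAnalyze <- function(deList, perStudyP = 0.05, minStudies = 2) {
  if (!length(deList)) stop("no study results supplied")
  genes <- sort(unique(unlist(lapply(deList, `[[`, "gene"))))
  get <- function(col) vapply(deList, function(d)
    d[[col]][match(genes, d$gene)], numeric(length(genes)))
  P <- get("p"); E <- get("effect"); S <- get("se")
  if (length(genes) == 1) { P <- rbind(P); E <- rbind(E); S <- rbind(S) }
  k <- rowSums(!is.na(P))
  keep <- k >= minStudies
  genes <- genes[keep]
  P <- P[keep, , drop = FALSE]; E <- E[keep, , drop = FALSE]
  S <- S[keep, , drop = FALSE]

  n <- length(genes)
  res <- data.frame(gene = genes, k = rowSums(!is.na(P)),
                    fisherX = NA_real_, fisherDf = NA_integer_,
                    fisherP = NA_real_, feEffect = NA_real_, feSe = NA_real_,
                    feZ = NA_real_, feP = NA_real_, Q = NA_real_,
                    Qdf = NA_integer_, Qp = NA_real_, votes = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fc <- fisherCombine(P[i, ])
    fe <- fixedEffectCombine(E[i, ], S[i, ])
    res$fisherX[i] <- fc$X; res$fisherDf[i] <- fc$df; res$fisherP[i] <- fc$p
    res$feEffect[i] <- fe$effect; res$feSe[i] <- fe$se; res$feZ[i] <- fe$z
    res$feP[i] <- fe$p; res$Q[i] <- fe$Q
    res$Qdf[i] <- if (is.na(fe$Qdf)) NA_integer_ else fe$Qdf
    res$Qp[i] <- fe$Qp
    res$votes[i] <- voteCount(P[i, ], threshold = perStudyP)
  }
  attr(res, "effects") <- E
  res
}

#' Consensus gene calls from the three meta-analysis methods
#'
#' Applies the significance rule per method — Fisher combined p below
#' `pCombined`, fixed-effect combined p below `pCombined`, and votes at or
#' above `voteThreshold` — and flags as consensus the genes significant by
#' all three. Direction is the sign of the pooled fixed-effect estimate;
#' genes whose per-study effect signs disagree while the pooled |z| is below
#' `discordantZ` are labeled `discordant`.
#'
#' @param meta a [metaAnalyze()] result (its `effects` attribute, when
#'   present, supplies per-study signs for the discordance label).
#' @param pCombined combined-p significance level (both Fisher and
#'   fixed-effect).
#' @param voteThreshold minimum votes for significance.
#' @param discordantZ |pooled z| floor below which sign-discordant genes are
#'   labeled discordant.
#' @return the input data.frame with added logicals `sigFisher`, `sigFe`,
#'   `sigVotes`, `consensus` and a `direction` column
#'   (`up`/`down`/`discordant`).
#' @export
consensusGenes <- function(meta, pCombined = 0.001, voteThreshold = 2,
                           discordantZ = 1.96) {
  meta$sigFisher <- !is.na(meta$fisherP) & meta$fisherP < pCombined
  meta$sigFe <- !is.na(meta$feP) & meta$feP < pCombined
  meta$sigVotes <- !is.na(meta$votes) & meta$votes >= voteThreshold
  meta$consensus <- meta$sigFisher & meta$sigFe & meta$sigVotes
  meta$direction <- ifelse(meta$feEffect >= 0, "up", "down")
  E <- attr(meta, "effects")
  if (!is.null(E)) {
    signs <- sign(E)
    mixed <- apply(signs, 1, function(s) {
      s <- s[!is.na(s) & s != 0]
      length(unique(s)) > 1
    })
    meta$direction[mixed & abs(meta$feZ) < discordantZ] <- "discordant"
  }
  meta
}

#' Percentage breakdown of a direction split
#'
#' Reporting helper used when summarizing a consensus list: given counts of
#' down- and up-regulated genes, returns the percentage split rounded to one
#' decimal, as conventionally printed alongside the counts.
#'
#' @param nDown,nUp counts of down- / up-regulated genes.
#' @return named numeric: `downPct`, `upPct`.
#' @examples
#' directionPercentages(635, 625)  # 50.4 / 49.6
#' @export
directionPercentages <- function(nDown, nUp) {
  total <- nDown + nUp
  if (total == 0) return(c(downPct = NA_real_, upPct = NA_real_))
  c(downPct = round(100 * nDown / total, 1),
    upPct = round(100 * nUp / total, 1))
}
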