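#' Over-representation analysis of a gene list against gene sets
#'
#' For each gene set, forms the 2x2 table of query/background membership and
#' computes the one-sided hypergeometric upper-tail p (probability of at
#' least the observed overlap), fold enrichment
#' `(a / (a + b)) / ((a + c) / N)` (query hit rate over background set rate),
#' the odds ratio with its Woolf 95% CI, and Benjamini-Hochberg FDR across
#' sets. Sets are intersected with the background first; sets with fewer
#' than `minOverlap` query hits are skipped. With `ease = TRUE` the overlap
#' is penalized by one (the jackknifed DAVID-style EASE score) before the
#' tail probability is taken.
#'
#' Cell convention: `a` = query AND set, `b` = query not in set, `c` = set
#' not in query (background only), `d` = the rest; `a + b + c + d = N`.
#'
#' @param query character vector of genes (must lie in `background`).
#' @param geneSets named list of character vectors (e.g. from [readGmt()]).
#' @param background character vector, the tested gene universe.
#' @param minOverlap minimum query hits for a set to be scored.
#' @param ease use the EASE (a - 1) penalty.
#' @return data.frame sorted by FDR then p: `set`, `a`, `b`, `c`, `d`,
#'   `foldEnrichment`, `p`, `fdr`, `or`, `ciLow`, `ciHigh`.
#' @examples
#' ora(c("g1", "g2"), list(s = c("g1", "g2", "g3")), paste0("g", 1:20))
#' @export
ora <- function(query, geneSets, background, minOverlap = 2, ease = FALSE) {
  if (!length(background)) stop("background is empty")
  if (!length(query)) stop("query is empty")
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background))
    stop("query genes must be a subset of the background")
  N <- length(background)
  nQ <- length(query)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], background)
    a <- length(intersect(query, set))
    if (a < minOverlap) return(NULL)
    b <- nQ - a
    cc <- length(set) - a
    d <- N - a - b - cc
    aEff <- if (ease) max(a - 1, 0) else a
    p <- stats::phyper(aEff - 1, length(set), N - length(set), nQ,
                       lower.tail = FALSE)
    fe <- (a / nQ) / (length(set) / N)
    orr <- woolfOddsRatio(a, b, cc, d)
    data.frame(set = nm, a = a, b = b, c = cc, d = d,
               foldEnrichment = fe, p = p,
               or = orr$or, ciLow = orr$ciLow, ciHigh = orr$ciHigh,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(set = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      foldEnrichment = numeric(0), p = numeric(0),
                      fdr = numeric(0), or = numeric(0), ciLow = numeric(0),
                      ciHigh = numeric(0)))
  out <- do.call(rbind, rows)
  out$fdr <- bhFdr(out$p)
  out <- out[order(out$fdr, out$p, out$set), ]
  rownames(out) <- NULL
  out[, c("set", "a", "b", "c", "d", "foldEnrichment", "p", "fdr",
          "or", "ciLow", "ciHigh")]
}

#' Odds ratio with Woolf confidence interval for a 2x2 table
#'
#' `OR = (a d) / (b c)`; 95% CI on the log scale,
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero, the Haldane-Anscombe correction (+0.5 to every cell) is applied and
#' flagged.
#'
#' @param a,b,c,d 2x2 cell counts.
#' @return list: `or`, `ciLow`, `ciHigh`, `corrected` (logical).
#' @keywords internal
woolfOddsRatio <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  orr <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = orr, ciLow = exp(log(orr) - 1.96 * se),
       ciHigh = exp(log(orr) + 1.96 * se), corrected = corrected)
}

#' Enrichment of a module in a reference gene set, with odds ratio
#'
#' Tests whether a module's genes are over-represented in a reference set
#' (e.g. a curated database of human aging genes) relative to a background
#' universe: the 2x2 table is module/non-module by reference/non-reference
#' over the background, summarized by the odds ratio with its Woolf 95% CI
#' and a two-sided Fisher exact p.
#'
#' @param moduleGenes character vector, the module members.
#' @param referenceSet character vector, the reference gene set.
#' @param background character vector, the tested universe (must contain the
#'   module genes).
#' @return one-row data.frame: `a`, `b`, `c`, `d`, `or`, `ciLow`, `ciHigh`,
#'   `p` (Fisher exact, two-sided), `foldEnrichment`, `corrected`.
#' @examples
#' oddsRatioEnrichment(paste0("g", 1:10), paste0("g", c(1:5, 50:59)),
#'                     paste0("g", 1:100))
#' @export
oddsRatioEnrichment <- function(moduleGenes, referenceSet, background) {
  background <- unique(background)
  moduleGenes <- unique(intersect(moduleGenes, background))
  referenceSet <- unique(intersect(referenceSet, background))
  if (length(unique(c(moduleGenes, referenceSet))) > length(background))
    stop("background smaller than the union of inputs")
  a <- length(intersect(moduleGenes, referenceSet))
  b <- length(moduleGenes) - a
  cc <- length(referenceSet) - a
  d <- length(background) - a - b - cc
  orr <- woolfOddsRatio(a, b, cc, d)
  p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                          alternative = "two.sided")$p.value
  N <- length(background)
  fe <- if (length(moduleGenes) && length(referenceSet))
    (a / length(moduleGenes)) / (length(referenceSet) / N) else NA_real_
  data.frame(a = a, b = b, c = cc, d = d, or = orr$or,
             ciLow = orr$ciLow, ciHigh = orr$ciHigh, p = p,
             foldEnrichment = fe, corrected = orr$corrected)
}
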