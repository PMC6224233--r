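#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct(target) - Ct(reference)`; per-sample
#' `ddCt = dCt - mean(dCt in the control group)` (Livak calibration to the
#' control mean); fold change = `2^-ddCt`. Group summaries report mean fold
#' +/- standard error, and groups are compared by a two-sided two-sample
#' t-test on the dCt values (the scale on which the method is linear).
#'
#' @param qpcr long-format data.frame with columns `sample`, `group`,
#'   `gene`, `role` (`target`/`reference`), `ct`; every sample needs both a
#'   target and a reference Ct.
#' @param controlGroup label of the calibrator group.
#' @return list: `perSample` (sample, group, gene, dCt, ddCt, fold),
#'   `groupSummary` (gene, group, meanFold, seFold, n), `tests` (gene,
#'   t, df, p from the t-test on dCt).
#' @examples
#' tab <- generateQpcr("Cdc42", foldChanges = 4, ctNoiseSd = 0, seed = 1)
#' ddct(tab)$groupSummary
#' @export
ddct <- function(qpcr, controlGroup = "control") {
  ref <- qpcr[qpcr$role == "reference", c("sample", "ct")]
  if (anyDuplicated(ref$sample))
    ref <- stats::aggregate(ct ~ sample, ref, mean)
  targets <- qpcr[qpcr$role == "target", , drop = FALSE]
  missing <- setdiff(unique(targets$sample), ref$sample)
  if (length(missing))
    stop("missing reference Ct for sample(s): ", paste(missing, collapse = ", "))
  targets$refCt <- ref$ct[match(targets$sample, ref$sample)]
  targets$dCt <- targets$ct - targets$refCt

  perSample <- list(); summaries <- list(); tests <- list()
  for (gn in unique(targets$gene)) {
    tg <- targets[targets$gene == gn, , drop = FALSE]
    ctrl <- tg$dCt[tg$group == controlGroup]
    if (!length(ctrl)) stop("control group '", controlGroup, "' is empty")
    tg$ddCt <- tg$dCt - mean(ctrl)
    tg$fold <- 2^(-tg$ddCt)
    perSample[[gn]] <- tg[, c("sample", "group", "gene", "dCt", "ddCt", "fold")]
    for (gr in unique(tg$group)) {
      f <- tg$fold[tg$group == gr]
      summaries[[paste(gn, gr)]] <- data.frame(
        gene = gn, group = gr, meanFold = mean(f),
        seFold = if (length(f) > 1) stats::sd(f) / sqrt(length(f)) else NA_real_,
        n = length(f))
    }
    grps <- unique(tg$group)
    if (length(grps) == 2 && all(table(tg$group) >= 2)) {
      tt <- twoGroupTest(tg$dCt, tg$group)
      tests[[gn]] <- data.frame(gene = gn, t = tt$statistic, df = tt$df,
                                p = tt$p)
    }
  }
  list(perSample = do.call(rbind, c(perSample, list(make.row.names = FALSE))),
       groupSummary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
       tests = if (length(tests))
         do.call(rbind, c(tests, list(make.row.names = FALSE))) else NULL)
}

## all permutations of 1..n, one per row (n small)
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with age
#'
#' Rho is the Pearson correlation of midranks (ties allowed). The p-value
#' uses the t-approximation `t = rho sqrt((n-2)/(1-rho^2))` with `n - 2` df;
#' for small samples (`n <= 8`, no ties) an exact two-sided permutation p is
#' computed by full enumeration instead. A constant input yields a missing
#' rho.
#'
#' @param x expression values.
#' @param ages ages (same length, n >= 4).
#' @param exactMax largest n for which the exact permutation p is used.
#' @return list: `rho`, `p`, `n`, `method` (`"exact"` or `"t-approx"`).
#' @examples
#' spearmanAge(c(1, 2, 3), c(3, 1, 2), exactMax = 0)$rho  # -0.5
#' @export
spearmanAge <- function(x, ages, exactMax = 8) {
  ok <- stats::complete.cases(x, ages)
  x <- x[ok]; ages <- ages[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(ages) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  rx <- rank(x); ry <- rank(ages)
  rho <- stats::cor(rx, ry)
  hasTies <- anyDuplicated(x) || anyDuplicated(ages)
  if (n <= exactMax && !hasTies) {
    perms <- allPerms(n)
    rhos <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = min(p, 1), n = n, method = "t-approx")
}

#' Two-group Student's t-test
#'
#' Two-sided two-sample t-test, equal-variance (Student) by default with a
#' Welch option; if both groups are essentially constant the Welch fallback
#' is attempted and, failing that, a degenerate result (t = 0, p = 1 when
#' means agree) is returned with a warning.
#'
#' @param values numeric vector.
#' @param groups two-level factor/character of the same length.
#' @param welch use Welch's unequal-variance test.
#' @return list: `statistic`, `df`, `p`.
#' @examples
#' twoGroupTest(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
twoGroupTest <- function(values, groups, welch = FALSE) {
  gl <- unique(as.character(groups))
  if (length(gl) != 2) stop("exactly two groups required")
  x <- values[groups == gl[1]]; y <- values[groups == gl[2]]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  res <- tryCatch(
    stats::t.test(x, y, var.equal = !welch),
    error = function(e) NULL)
  if (is.null(res) && !welch) {
    warning("degenerate variance; falling back to Welch's test")
    res <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                    error = function(e) NULL)
  }
  if (is.null(res)) {
    warning("data essentially constant in both groups")
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (same) 0 else Inf,
                df = length(x) + length(y) - 2,
                p = if (same) 1 else 0))
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
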