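#' Subtraction metric of injury-induced regulation (SNL-reg)
#'
#' `(SNL - sham) / ((SNL + sham) / 2)`: positive for up-regulation,
#' negative for down-regulation, zero for no change; bounded in (-2, 2).
#'
#' @param snl,sham Mean RPM of the injury (SNL) and control (sham) pools
#'   (vectorized).
#' @return Dimensionless regulation; `NA` where both means are zero.
#' @examples
#' snlRegSubtraction(8140, 9187)   # -0.121
#' snlRegSubtraction(30, 10)       #  1
#' @export
snlRegSubtraction <- function(snl, sham) {
  out <- (snl - sham) / ((snl + sham) / 2)
  out[snl == 0 & sham == 0] <- NA_real_
  out
}

#' Signed fold change
#'
#' `SNL/sham` when up-regulated, `-(sham/SNL)` when down-regulated, so
#' down-regulation reads as a negative fold rather than a positive
#' fraction; no change gives 1. Magnitude is always >= 1.
#'
#' @inheritParams snlRegSubtraction
#' @return Signed fold; `NA` where either mean is zero.
#' @examples
#' foldChangeSigned(8140, 9187)  # -1.129
#' foldChangeSigned(20, 10)      #  2
#' @export
foldChangeSigned <- function(snl, sham) {
  out <- ifelse(snl >= sham, snl / sham, -(sham / snl))
  out[snl == 0 | sham == 0] <- NA_real_
  out
}

#' Log2 fold-change ratio
#'
#' `log2(SNL / sham)` with an RPM floor applied inside the ratio only, so
#' one-sided zeros stay finite.
#'
#' @inheritParams snlRegSubtraction
#' @param floor RPM floor used inside the ratio (default 0.5).
#' @return log2 ratio; `NA` where both means are zero.
#' @export
log2FoldRatio <- function(snl, sham, floor = 0.5) {
  out <- log2(pmax(snl, floor) / pmax(sham, floor))
  out[snl == 0 & sham == 0] <- NA_real_
  out
}

.metricFun <- function(metric, floor = 0.5) {
  switch(metric,
         subtraction = snlRegSubtraction,
         log2 = function(snl, sham) log2FoldRatio(snl, sham, floor))
}

## Welch two-sample t; degenerate data fall back to p = 1 (all tied) or
## p = 0 (two distinct constants)
.welchP <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2L || length(b) < 2L) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    return(switch(alternative,
                  two.sided = 0,
                  greater = if (mean(a) > mean(b)) 0 else 1,
                  less = if (mean(a) < mean(b)) 0 else 1))
  }
  t.test(a, b, alternative = alternative)$p.value
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values (with monotonicity enforcement) plus the FDR limit:
#' the largest ordered p-value satisfying `p_(i) <= i * alpha / m`, so
#' the original rejection rule "uncorrected p <= FDR limit" can be
#' reproduced. `NA` p-values are passed through.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param alpha FDR level for the limit (default 0.05).
#' @return A list: `q` (BH q-values), `limit` (the FDR limit; 0 when no
#'   p-value passes).
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))$q   # all 0.04
#' bhFdr(c(0.005, 0.9))$q               # 0.01 0.9
#' @export
bhFdr <- function(p, alpha = 0.05) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  q <- p.adjust(p, method = "BH")
  ps <- sort(p[ok])
  m <- length(ps)
  pass <- ps <= seq_len(m) * alpha / m
  limit <- if (any(pass)) ps[max(which(pass))] else 0
  list(q = q, limit = limit)
}

#' Per-element test of injury-induced regulation (SNL-reg)
#'
#' For one line, computes per-element point estimates from the condition
#' means (subtraction metric, signed fold change and log2 ratio) and
#' tests the null of no SNL/sham difference with a Welch two-sample
#' t-test on the per-pool values, followed by BH correction over all
#' elements. The default test is two-sided; `alternative = "observed"`
#' gives the one-tailed p in the direction of the observed change (note
#' that with a data-chosen direction this doubles the effective size;
#' see the methods vignette). Both p-values are always reported.
#'
#' @param x [SmallRNAExperiment-class] of RPM values.
#' @param line Line label (e.g. `"HA"`).
#' @param metric `"subtraction"` or `"log2"`; selects the `estimate`
#'   column and the scale of the per-pool values tested (`"log2"` tests
#'   log2-transformed pool RPMs).
#' @param alternative `"two.sided"` (default) or `"observed"`.
#' @param alpha FDR level for the reported limit.
#' @param excludePools Pools to drop before testing.
#' @param floor RPM floor inside ratio metrics.
#' @return `DataFrame` per element: `shamMean`, `snlMean`, `estimate`,
#'   `snlReg`, `foldChange`, `log2Ratio`, `direction`, `p`, `pTwoSided`,
#'   `pObserved`, `q`; FDR limit in `metadata()$fdrLimit`.
#' @export
snlRegTest <- function(x, line, metric = c("subtraction", "log2"),
                       alternative = c("two.sided", "observed"),
                       alpha = 0.05, excludePools = NULL, floor = 0.5) {
  metric <- match.arg(metric)
  alternative <- match.arg(alternative)
  if (quantMode(x) == "raw")
    stop("snlRegTest expects RPM values; run toRPM() first")
  if (!is.null(excludePools)) x <- excludePools(x, excludePools)
  cd <- SummarizedExperiment::colData(x)
  if (!line %in% cd$line) stop("unknown line: ", line)
  conds <- unique(cd$condition)
  shamPools <- cd$pool[cd$line == line & cd$condition == conds[1L]]
  snlPools <- cd$pool[cd$line == line & cd$condition == conds[2L]]
  if (length(shamPools) < 2L || length(snlPools) < 2L)
    stop("need >= 2 replicate pools per condition")
  a <- SummarizedExperiment::assay(x)
  shamMean <- rowMeans(a[, shamPools, drop = FALSE])
  snlMean <- rowMeans(a[, snlPools, drop = FALSE])
  est <- .metricFun(metric, floor)(snlMean, shamMean)
  n <- nrow(a)
  p2 <- pObs <- numeric(n)
  for (i in seq_len(n)) {
    snlV <- a[i, snlPools]; shamV <- a[i, shamPools]
    if (metric == "log2") {
      snlV <- log2(pmax(snlV, floor)); shamV <- log2(pmax(shamV, floor))
    }
    p2[i] <- .welchP(snlV, shamV, "two.sided")
    dir <- if (mean(snlV) >= mean(shamV)) "greater" else "less"
    pObs[i] <- .welchP(snlV, shamV, dir)
  }
  p <- if (alternative == "two.sided") p2 else pObs
  fdr <- bhFdr(p, alpha)
  out <- DataFrame(
    shamMean = shamMean, snlMean = snlMean, estimate = est,
    snlReg = snlRegSubtraction(snlMean, shamMean),
    foldChange = foldChangeSigned(snlMean, shamMean),
    log2Ratio = log2FoldRatio(snlMean, shamMean, floor),
    direction = ifelse(snlMean >= shamMean, "up", "down"),
    p = p, pTwoSided = p2, pObserved = pObs, q = fdr$q,
    row.names = rownames(a))
  S4Vectors::metadata(out) <- list(fdrLimit = fdr$limit, line = line,
                                   metric = metric,
                                   alternative = alternative)
  out
}

## all SNL x sham pairwise estimates for one element and line
.pairwiseEstimates <- function(snlV, shamV, metricFun) {
  e <- as.vector(outer(snlV, shamV, metricFun))
  e[is.finite(e)]
}

#' Differential regulation between lines (diff-reg)
#'
#' For every element, forms all SNL x sham pairwise SNL-reg estimates
#' within each line (k_SNL x k_sham values; 9 per line at the default
#' 3+3 design), takes `diff` as the difference of the two line means,
#' and tests it with a two-tailed Welch t-test comparing the two
#' estimate sets, BH-corrected over elements. Optionally adds a
#' permutation p-value that re-splits the pooled estimate sets
#' ([diffRegPermutation()]).
#'
#' Note the pairwise estimates of one line share the line's pools and
#' are therefore positively correlated; the t-test treats them as
#' independent, which makes it anticonservative (quantified in the
#' methods vignette). When within-group variance is zero the pairwise
#' mean reduces exactly to the direct group-mean formula.
#'
#' @param x [SmallRNAExperiment-class] of RPM values.
#' @param metric `"subtraction"` or `"log2"`.
#' @param lines The two line labels compared (`diff` = first minus
#'   second); defaults to the design's lines.
#' @param excludePools Pools to drop first (e.g. a flagged outlier).
#' @param permRuns Permutation runs per element (0 = no permutation
#'   p-values).
#' @param seed Seed for the permutation draws.
#' @param permuteOn What the permutation re-splits; `"estimates"`
#'   (the pooled pairwise estimate sets).
#' @param alpha FDR level for the reported limits.
#' @param floor RPM floor inside ratio metrics.
#' @return `DataFrame` per element: per-line means/SDs of the pairwise
#'   estimates, pair counts, `diff`, `p`, `q`, and `permP`/`permQ` when
#'   `permRuns > 0`; FDR limit in `metadata()$fdrLimit`.
#' @export
diffRegPairwise <- function(x, metric = c("subtraction", "log2"),
                            lines = NULL, excludePools = NULL,
                            permRuns = 0L, seed = 1L,
                            permuteOn = "estimates",
                            alpha = 0.05, floor = 0.5) {
  metric <- match.arg(metric)
  permuteOn <- match.arg(permuteOn)
  if (quantMode(x) == "raw")
    stop("diffRegPairwise expects RPM values; run toRPM() first")
  if (!is.null(excludePools)) x <- excludePools(x, excludePools)
  cd <- SummarizedExperiment::colData(x)
  if (is.null(lines)) lines <- unique(cd$line)
  if (length(lines) != 2L) stop("exactly two lines are compared")
  conds <- unique(cd$condition)
  poolsOf <- function(ln, cn) cd$pool[cd$line == ln & cd$condition == cn]
  for (ln in lines)
    if (length(poolsOf(ln, conds[1L])) < 2L ||
        length(poolsOf(ln, conds[2L])) < 2L)
      stop("line ", ln, " needs >= 2 pools per condition")
  metricFun <- .metricFun(metric, floor)
  a <- SummarizedExperiment::assay(x)
  n <- nrow(a)
  res <- data.frame(mean1 = rep(NA_real_, n), sd1 = NA_real_, nPairs1 = 0L,
                    mean2 = NA_real_, sd2 = NA_real_, nPairs2 = 0L,
                    diff = NA_real_, p = NA_real_, permP = NA_real_)
  dropped <- 0L
  set.seed(as.integer(seed))
  permSeeds <- sample.int(.Machine$integer.max, n)
  for (i in seq_len(n)) {
    e1 <- .pairwiseEstimates(a[i, poolsOf(lines[1L], conds[2L])],
                             a[i, poolsOf(lines[1L], conds[1L])], metricFun)
    e2 <- .pairwiseEstimates(a[i, poolsOf(lines[2L], conds[2L])],
                             a[i, poolsOf(lines[2L], conds[1L])], metricFun)
    if (length(e1) < 2L || length(e2) < 2L) { dropped <- dropped + 1L; next }
    res$mean1[i] <- mean(e1); res$sd1[i] <- sd(e1); res$nPairs1[i] <- length(e1)
    res$mean2[i] <- mean(e2); res$sd2[i] <- sd(e2); res$nPairs2[i] <- length(e2)
    res$diff[i] <- mean(e1) - mean(e2)
    res$p[i] <- .welchP(e1, e2, "two.sided")
    if (permRuns > 0)
      res$permP[i] <- diffRegPermutation(e1, e2, nRuns = permRuns,
                                         seed = permSeeds[i])
  }
  fdr <- bhFdr(res$p, alpha)
  out <- DataFrame(res, row.names = rownames(a))
  colnames(out) <- c(paste0(c("mean", "sd", "nPairs"), lines[1L]),
                     paste0(c("mean", "sd", "nPairs"), lines[2L]),
                     "diff", "p", "permP")
  out$q <- fdr$q
  meta <- list(fdrLimit = fdr$limit, metric = metric, lines = lines,
               droppedElements = dropped)
  if (permRuns > 0) {
    permFdr <- bhFdr(out$permP, alpha)
    out$permQ <- permFdr$q
    meta$permFdrLimit <- permFdr$limit
  } else {
    out$permP <- NULL
  }
  S4Vectors::metadata(out) <- meta
  out
}

#' Permutation null for a difference of estimate-set means
#'
#' Pools the two estimate sets, repeatedly re-splits them at the original
#' sizes uniformly at random, and compares the absolute difference of
#' means against the observed one. The sampled p-value uses the add-one
#' correction `(1 + #{runs >= observed}) / (nRuns + 1)` so it is never
#' zero; with `exact = TRUE` all distinct splits are enumerated and the
#' exact proportion `#{splits >= observed} / #splits` is returned
#' (feasible for the 9+9 sets of the default design).
#'
#' @param e1,e2 Numeric estimate sets (non-empty).
#' @param nRuns Number of random re-splits (ignored when `exact`).
#' @param seed Seed for the re-splits.
#' @param exact Enumerate all splits instead of sampling.
#' @return The permutation p-value.
#' @examples
#' diffRegPermutation(c(0, 0, 0), c(1, 1, 1), exact = TRUE)  # 2/20 = 0.1
#' @export
diffRegPermutation <- function(e1, e2, nRuns = 1e5L, seed = 1L,
                               exact = FALSE) {
  if (!length(e1) || !length(e2)) stop("estimate sets must be non-empty")
  pooled <- c(e1, e2)
  n1 <- length(e1); n <- length(pooled)
  obs <- abs(mean(e1) - mean(e2))
  tol <- 1e-12 * max(1, obs)
  statOf <- function(idx)
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  if (exact) {
    splits <- combn(n, n1)
    stats <- apply(splits, 2, statOf)
    return(mean(stats >= obs - tol))
  }
  if (nRuns < 1L) stop("'nRuns' must be >= 1")
  set.seed(as.integer(seed))
  hits <- 0L
  for (r in seq_len(nRuns)) {
    idx <- sample.int(n, n1)
    if (statOf(idx) >= obs - tol) hits <- hits + 1L
  }
  (1 + hits) / (nRuns + 1)
}

#' Baseline expression comparison between lines
#'
#' Compares the two lines' control (sham) pools element by element: fold
#' ratio of the group means (first line over second), two-tailed Welch
#' t-test on the pool values and BH correction.
#'
#' @param x [SmallRNAExperiment-class] of RPM values.
#' @param lines The two line labels (ratio = first / second).
#' @param alpha FDR level for the reported limit.
#' @return `DataFrame` per element: the two sham means, `ratio`, `p`,
#'   `q`; FDR limit in `metadata()$fdrLimit`.
#' @export
baselineCompare <- function(x, lines = NULL, alpha = 0.05) {
  if (quantMode(x) == "raw")
    stop("baselineCompare expects RPM values; run toRPM() first")
  cd <- SummarizedExperiment::colData(x)
  if (is.null(lines)) lines <- unique(cd$line)
  if (length(lines) != 2L) stop("exactly two lines are compared")
  sham <- unique(cd$condition)[1L]
  p1 <- cd$pool[cd$line == lines[1L] & cd$condition == sham]
  p2 <- cd$pool[cd$line == lines[2L] & cd$condition == sham]
  if (length(p1) < 2L || length(p2) < 2L)
    stop("need >= 2 sham pools per line")
  a <- SummarizedExperiment::assay(x)
  m1 <- rowMeans(a[, p1, drop = FALSE])
  m2 <- rowMeans(a[, p2, drop = FALSE])
  p <- vapply(seq_len(nrow(a)), function(i)
    .welchP(a[i, p1], a[i, p2], "two.sided"), numeric(1))
  fdr <- bhFdr(p, alpha)
  ratio <- ifelse(m2 > 0, m1 / m2, NA_real_)
  out <- DataFrame(mean1 = m1, mean2 = m2, ratio = ratio, p = p, q = fdr$q,
                   row.names = rownames(a))
  colnames(out)[1:2] <- paste0(lines, "_shamMean")
  S4Vectors::metadata(out) <- list(fdrLimit = fdr$limit, lines = lines)
  out
}
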