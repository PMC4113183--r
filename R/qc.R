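setOldClass("hclust")

#' Pool-consistency report
#'
#' Result of [poolConsistency()]: the pairwise pool correlations, the
#' average-linkage dendrogram, the per-group mean coefficient of
#' variation and the advisory outlier flags with their evidence.
#'
#' @slot correlations Symmetric pool x pool Pearson correlation matrix.
#' @slot tree `hclust` object (UPGMA on distance 1 - r).
#' @slot groupCV Named numeric, per-group mean CV.
#' @slot flags Named logical, per-pool outlier flag.
#' @slot evidence `data.frame` per pool: topology criterion, group CV
#'   without the pool, and the mean CV of the other groups.
#' @exportClass ConsistencyReport
setClass("ConsistencyReport",
  representation(correlations = "matrix", tree = "hclust",
                 groupCV = "numeric", flags = "logical",
                 evidence = "data.frame"))

setValidity("ConsistencyReport", function(object) {
  msg <- NULL
  r <- object@correlations
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8 ||
      max(abs(diag(r) - 1)) > 1e-8)
    msg <- c(msg, "correlations must be symmetric with unit diagonal")
  if (any(object@groupCV < 0, na.rm = TRUE))
    msg <- c(msg, "group CVs must be >= 0")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConsistencyReport", function(object) {
  cat("ConsistencyReport:", nrow(object@correlations), "pools\n")
  cat("group mean CV:\n")
  print(round(object@groupCV, 3))
  fl <- names(object@flags)[object@flags]
  cat("flagged pools:", if (length(fl)) paste(fl, collapse = ", ")
      else "none", "\n")
})

#' Pairwise pool correlations
#'
#' Pearson correlation between the expression profiles of every pool
#' pair, computed over the shared row set. By default profiles are
#' log10(RPM + 1)-transformed first; with five decades of abundance a
#' raw-scale correlation is dominated by the few most abundant elements
#' and carries almost no replicate information (see the methods
#' vignette).
#'
#' @param x [SmallRNAExperiment-class] (RPM recommended).
#' @param transform `"log"` (default) or `"none"`.
#' @return Symmetric correlation matrix (pools x pools).
#' @export
poolCorrelations <- function(x, transform = c("log", "none")) {
  transform <- match.arg(transform)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 rows and >= 2 pools")
  a <- SummarizedExperiment::assay(x)
  if (transform == "log") a <- log10(a + 1)
  sds <- apply(a, 2, sd)
  if (any(sds == 0))
    stop("correlation undefined: zero-variance pool(s): ",
         paste(colnames(a)[sds == 0], collapse = ", "))
  cor(a)
}

#' Average-linkage (UPGMA) clustering of pools
#'
#' Agglomerative clustering of the pools with distance d = 1 - r and
#' average linkage. Merge order is deterministic; exact distance ties are
#' broken by the order in which pools appear in the correlation matrix
#' (the behaviour of [stats::hclust()]).
#'
#' @param correlations Correlation matrix from [poolCorrelations()].
#' @return An [stats::hclust] dendrogram.
#' @export
averageLinkageCluster <- function(correlations) {
  hclust(as.dist(1 - correlations), method = "average")
}

#' Per-group mean coefficient of variation
#'
#' For every element and group, CV = sample SD / mean over the group's
#' replicate pools (elements with zero group mean are skipped); the group
#' value is the mean over elements.
#'
#' @param x [SmallRNAExperiment-class].
#' @param pools Optional subset of pool ids to use (their design groups
#'   are kept); groups reduced below 2 pools are dropped with an error.
#' @return Named numeric of group mean CVs, with the elements x groups CV
#'   matrix in attribute `"perElement"`.
#' @examples
#' # element with replicate values (10, 10, 16): CV = 3.4641 / 12 = 0.2887
#' @export
groupCV <- function(x, pools = colnames(x)) {
  grp <- poolGroups(x)[pools]
  if (any(table(grp) < 2L))
    stop("every group needs >= 2 pools for a CV")
  a <- SummarizedExperiment::assay(x)[, pools, drop = FALSE]
  groups <- unique(grp)
  per <- vapply(groups, function(g) {
    sub <- a[, grp == g, drop = FALSE]
    m <- rowMeans(sub)
    s <- apply(sub, 1, sd)
    ifelse(m > 0, s / m, NA_real_)
  }, numeric(nrow(a)))
  if (nrow(a) == 1L)
    per <- matrix(per, 1L, dimnames = list(rownames(a), groups))
  out <- colMeans(per, na.rm = TRUE)
  attr(out, "perElement") <- per
  out
}

## pool index sets of every internal node of an hclust tree
.mergeClusters <- function(tree) {
  n <- nrow(tree$merge) + 1L
  clusters <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    a <- tree$merge[k, 1L]; b <- tree$merge[k, 2L]
    clusters[[k]] <- c(if (a < 0) -a else clusters[[a]],
                       if (b < 0) -b else clusters[[b]])
  }
  clusters
}

#' Advisory outlier flags for replicate pools
#'
#' A pool is flagged iff both hold: (a) topology -- the smallest
#' dendrogram cluster containing the pool and at least one of its
#' group-mates also contains a pool from another group (i.e. the pool
#' joins its group only after foreign pools are involved); and (b) CV --
#' removing the pool brings its group's mean CV down to at most
#' `cvRatioThreshold` times the mean CV of the other groups. Flags are
#' advisory; exclusion is an explicit user action ([excludePools()]).
#'
#' @param x [SmallRNAExperiment-class] used for the CVs.
#' @param tree Dendrogram from [averageLinkageCluster()] over the pools
#'   of `x`.
#' @param cvRatioThreshold Multiplier on the other groups' mean CV
#'   (default 1: reduced to at or below their level).
#' @return Named logical flags with the evidence `data.frame` in
#'   attribute `"evidence"`.
#' @export
flagOutliers <- function(x, tree, cvRatioThreshold = 1) {
  pools <- colnames(x)
  if (!identical(sort(tree$labels), sort(pools)))
    stop("tree labels must match the pools of 'x'")
  grp <- poolGroups(x)
  ord <- match(pools, tree$labels)
  clusters <- .mergeClusters(tree)
  gcv <- groupCV(x)
  flags <- setNames(logical(length(pools)), pools)
  evidence <- data.frame(pool = pools, topology = FALSE,
                         cvWithout = NA_real_, otherCV = NA_real_)
  for (i in seq_along(pools)) {
    mates <- which(grp == grp[i])
    mates <- setdiff(mates, i)
    if (!length(mates)) next
    iT <- ord[i]; matesT <- ord[mates]
    topo <- FALSE
    for (cl in clusters) {
      if (iT %in% cl && any(matesT %in% cl)) {
        topo <- any(!(cl %in% c(iT, matesT)))
        break
      }
    }
    evidence$topology[i] <- topo
    if (!topo) next
    keep <- setdiff(pools, pools[i])
    cvwo <- tryCatch(groupCV(x, keep)[[grp[i]]], error = function(e) NA_real_)
    other <- mean(gcv[setdiff(names(gcv), grp[i])])
    evidence$cvWithout[i] <- cvwo
    evidence$otherCV[i] <- other
    if (!is.na(cvwo) && cvwo <= cvRatioThreshold * other)
      flags[i] <- TRUE
  }
  attr(flags, "evidence") <- evidence
  flags
}

#' Replicate-pool consistency check
#'
#' Runs the full QC stage: pairwise pool correlations, UPGMA clustering
#' on d = 1 - r, per-group mean CVs and advisory outlier flags.
#'
#' @inheritParams poolCorrelations
#' @inheritParams flagOutliers
#' @return A [ConsistencyReport-class].
#' @export
poolConsistency <- function(x, transform = c("log", "none"),
                            cvRatioThreshold = 1) {
  r <- poolCorrelations(x, transform)
  tree <- averageLinkageCluster(r)
  cv <- groupCV(x)
  flags <- flagOutliers(x, tree, cvRatioThreshold)
  new("ConsistencyReport", correlations = r, tree = tree,
      groupCV = setNames(as.numeric(cv), names(cv)), flags = flags,
      evidence = attr(flags, "evidence"))
}

#' Export a consistency dendrogram in Newick format
#'
#' @param report A [ConsistencyReport-class] (or an `hclust` tree).
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
consistencyNewick <- function(report, file = NULL) {
  tree <- if (methods::is(report, "ConsistencyReport")) report@tree else report
  phy <- ape::as.phylo(tree)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
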