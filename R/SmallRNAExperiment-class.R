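#' SmallRNAExperiment: elements x pools expression container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding
#' one assay of small-RNA abundances (raw counts or RPM), with the pool
#' design in `colData` and a `quantMode` flag recording the normalization
#' state (`"raw"`, `"rpm_reads_level"` or `"rpm_within_library"`). Row
#' names are unique sequences (reads-level matrices) or canonical
#' identifiers (per-identifier matrices).
#'
#' @slot quantMode Character scalar, one of `"raw"`,
#'   `"rpm_reads_level"`, `"rpm_within_library"`.
#' @aliases SmallRNAExperiment-class
#' @exportClass SmallRNAExperiment
setClass("SmallRNAExperiment",
  contains = "SummarizedExperiment",
  representation(quantMode = "character"),
  prototype(quantMode = "raw")
)

.QUANT_MODES <- c("raw", "rpm_reads_level", "rpm_within_library")

setValidity("SmallRNAExperiment", function(object) {
  msg <- NULL
  if (length(object@quantMode) != 1L || !object@quantMode %in% .QUANT_MODES)
    msg <- c(msg, paste0("quantMode must be one of: ",
                         paste(.QUANT_MODES, collapse = ", ")))
  if (length(SummarizedExperiment::assays(object)) < 1L) {
    msg <- c(msg, "an assay is required")
  } else {
    a <- SummarizedExperiment::assay(object)
    if (!is.numeric(a)) msg <- c(msg, "assay values must be numeric")
    else if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "assay values must be >= 0")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("pool", "line", "condition", "replicate", "group")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste0("colData must carry the pool design columns: ",
                         paste(need, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a SmallRNAExperiment
#'
#' @param counts Numeric matrix, elements (rows, named) x pools (columns).
#'   Column names must match `design$pool` (order is taken from the
#'   matrix).
#' @param design Pool design as returned by [poolDesign()].
#' @param quantMode `"raw"` (counts) or one of the RPM modes.
#' @param rowData Optional [S4Vectors::DataFrame] of per-element metadata.
#' @return A [SmallRNAExperiment-class] object.
#' @examples
#' d <- poolDesign(replicates = 2)
#' m <- matrix(rpois(8 * 5, 40), 5, 8, dimnames = list(paste0("el", 1:5), d$pool))
#' se <- SmallRNAExperiment(m, d)
#' quantMode(se)
#' @export
SmallRNAExperiment <- function(counts, design = poolDesign(),
                               quantMode = "raw", rowData = NULL) {
  .checkDesign(design)
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) colnames(counts) <- design$pool
  if (!setequal(colnames(counts), design$pool))
    stop("column names of 'counts' must match the design pool ids")
  cd <- design[match(colnames(counts), design$pool), , drop = FALSE]
  rownames(cd) <- cd$pool
  assayName <- if (quantMode == "raw") "counts" else "rpm"
  args <- list(assays = setNames(list(counts), assayName), colData = cd)
  if (!is.null(rowData)) args$rowData <- rowData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  new("SmallRNAExperiment", se, quantMode = quantMode)
}

#' @describeIn SmallRNAExperiment Normalization state of the assay.
#' @param x A `SmallRNAExperiment`.
#' @export
quantMode <- function(x) x@quantMode

#' @describeIn SmallRNAExperiment Group label (`<line>_<condition>`) of
#'   each pool, as a character vector named by pool.
#' @export
poolGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(as.character(cd$group), cd$pool)
}

#' @describeIn SmallRNAExperiment Drop pools (columns) from the
#'   experiment; values of the remaining pools are untouched.
#' @param pools Character vector of pool ids to drop.
#' @export
excludePools <- function(x, pools) {
  bad <- setdiff(pools, colnames(x))
  if (length(bad)) stop("unknown pool(s): ", paste(bad, collapse = ", "))
  x[, !(colnames(x) %in% pools)]
}

#' @describeIn SmallRNAExperiment Per-group means of the assay
#'   (elements x groups matrix).
#' @export
groupMeans <- function(x) {
  a <- SummarizedExperiment::assay(x)
  grp <- poolGroups(x)
  groups <- unique(grp)
  out <- vapply(groups,
                function(g) rowMeans(a[, grp == g, drop = FALSE]),
                numeric(nrow(a)))
  if (nrow(a) == 1L) out <- matrix(out, nrow = 1L,
                                   dimnames = list(rownames(a), groups))
  out
}

setMethod("show", "SmallRNAExperiment", function(object) {
  cat("SmallRNAExperiment (", object@quantMode, ")\n", sep = "")
  cat(nrow(object), " elements x ", ncol(object), " pools; groups: ",
      paste(unique(poolGroups(object)), collapse = ", "), "\n", sep = "")
  callNextMethod()
})
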