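#' Reads-per-million normalization
#'
#' Converts raw counts to RPM independently per pool, in one of the two
#' normalization modes: `"reads_level"` divides by the pool's grand total
#' over all rows, `"within_library"` divides each row by the total of all
#' rows assigned to the same reference library in that pool. Values are
#' kept in floating point; no rounding is applied.
#'
#' @param x [SmallRNAExperiment-class] of raw counts.
#' @param mode `"reads_level"` or `"within_library"`.
#' @param libraryAssignment For `"within_library"`: character/factor of
#'   length `nrow(x)` giving each row's library (no `NA`s). Defaults to
#'   `rowData(x)$library` when present.
#' @return A [SmallRNAExperiment-class] with RPM values and the matching
#'   `quantMode`.
#' @examples
#' d <- poolDesign(replicates = 2)
#' m <- matrix(c(5, 15, 80), 3, 8, dimnames = list(paste0("s", 1:3), d$pool))
#' assay(toRPM(SmallRNAExperiment(m, d)))[, 1]  # 50000 150000 800000
#' @export
toRPM <- function(x, mode = c("reads_level", "within_library"),
                  libraryAssignment = NULL) {
  mode <- match.arg(mode)
  if (quantMode(x) != "raw") stop("'x' must hold raw counts")
  counts <- SummarizedExperiment::assay(x)
  if (mode == "reads_level") {
    denom <- matrix(colSums(counts), nrow(counts), ncol(counts),
                    byrow = TRUE)
  } else {
    if (is.null(libraryAssignment))
      libraryAssignment <- SummarizedExperiment::rowData(x)$library
    if (is.null(libraryAssignment) || length(libraryAssignment) != nrow(x) ||
        anyNA(libraryAssignment))
      stop("within-library normalization requires a library assignment ",
           "for every row")
    libTotals <- rowsum(counts, group = as.character(libraryAssignment))
    denom <- libTotals[as.character(libraryAssignment), , drop = FALSE]
  }
  zero <- colSums(denom == 0) > 0
  if (any(zero))
    stop("zero normalization total in pool(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  rpm <- counts / denom * 1e6
  out <- SmallRNAExperiment(
    rpm, design = as(SummarizedExperiment::colData(x), "DataFrame"),
    quantMode = paste0("rpm_", mode),
    rowData = SummarizedExperiment::rowData(x))
  S4Vectors::metadata(out) <- S4Vectors::metadata(x)
  out
}

#' Abundance filter on an RPM matrix
#'
#' Keeps the rows expressed at `threshold` RPM or more in at least
#' `minPools` pools (default: RPM >= 10 in >= 3 of the pools); abundance
#' in fewer pools cannot rescue a row. Applied after normalization.
#'
#' @param x [SmallRNAExperiment-class] of RPM values.
#' @param threshold RPM threshold (inclusive).
#' @param minPools Minimum number of pools at or above the threshold.
#' @return The filtered experiment.
#' @export
abundanceFilter <- function(x, threshold = 10, minPools = 3L) {
  if (quantMode(x) == "raw")
    stop("abundanceFilter expects an RPM matrix; run toRPM() first")
  if (minPools > ncol(x))
    stop("'minPools' (", minPools, ") exceeds the number of pools (",
         ncol(x), ")")
  keep <- rowSums(SummarizedExperiment::assay(x) >= threshold) >= minPools
  x[keep, ]
}
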