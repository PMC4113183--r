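#' Write / read an expression matrix as TSV
#'
#' The TSV carries a `# quantMode: <mode>` header line so the
#' normalization state survives the round trip.
#'
#' @param x [SmallRNAExperiment-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeExpressionTSV <- function(x, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# quantMode: ", quantMode(x)), con)
  df <- data.frame(id = rownames(x), SummarizedExperiment::assay(x),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeExpressionTSV
#' @param design Pool design matching the file's columns.
#' @export
readExpressionTSV <- function(file, design = poolDesign()) {
  first <- readLines(file, n = 1L)
  mode <- if (startsWith(first, "# quantMode:"))
    trimws(sub("# quantMode:", "", first)) else "raw"
  df <- read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1L]]
  SmallRNAExperiment(m, design, quantMode = mode)
}

#' Pipeline run configuration
#'
#' Collects and validates everything one end-to-end run needs. Either a
#' synthetic configuration (`synthetic`) or a counts TSV (`countsFile`)
#' supplies the input matrix.
#'
#' @param synthetic A [syntheticConfig()] (or `NULL` when reading
#'   `countsFile`).
#' @param countsFile Path to a counts TSV ([writeExpressionTSV()]
#'   format).
#' @param design Pool design (used with `countsFile`; the synthetic
#'   config carries its own).
#' @param libraries Optional list of [ReferenceLibrary-class] for the
#'   annotation stage (skipped when `NULL`).
#' @param rpmMode Normalization mode, see [toRPM()].
#' @param rpmThreshold,minPools Abundance filter settings.
#' @param metric Regulation metric, see [diffRegPairwise()].
#' @param excludePools Pools excluded in the secondary analysis; `NULL`
#'   means "exclude whatever QC flags".
#' @param permRuns Permutation runs per element (0 disables).
#' @param alpha FDR level.
#' @param seed Master seed.
#' @return Validated configuration list of class `"runConfig"`.
#' @export
runConfig <- function(synthetic = syntheticConfig(), countsFile = NULL,
                      design = poolDesign(), libraries = NULL,
                      rpmMode = "reads_level", rpmThreshold = 10,
                      minPools = 3L, metric = "subtraction",
                      excludePools = NULL, permRuns = 0L,
                      alpha = 0.05, seed = 1L) {
  if (is.null(synthetic) && is.null(countsFile))
    stop("either 'synthetic' or 'countsFile' is required")
  if (!is.null(synthetic) && !inherits(synthetic, "syntheticConfig"))
    stop("'synthetic' must be a syntheticConfig()")
  if (!is.null(countsFile) && !file.exists(countsFile))
    stop("countsFile not found: ", countsFile)
  design <- if (!is.null(synthetic)) synthetic$design else design
  .checkDesign(design)
  if (minPools > nrow(design))
    stop("'minPools' exceeds the number of pools")
  if (!metric %in% c("subtraction", "log2")) stop("unknown metric")
  if (!rpmMode %in% c("reads_level", "within_library"))
    stop("unknown rpmMode")
  if (!is.null(excludePools) && !all(excludePools %in% design$pool))
    stop("unknown pool in 'excludePools'")
  structure(list(synthetic = synthetic, countsFile = countsFile,
                 design = design, libraries = libraries, rpmMode = rpmMode,
                 rpmThreshold = rpmThreshold, minPools = as.integer(minPools),
                 metric = metric, excludePools = excludePools,
                 permRuns = as.integer(permRuns), alpha = alpha,
                 seed = as.integer(seed)),
            class = "runConfig")
}

#' Run the full pipeline
#'
#' Orchestrates simulate/load, (optional) annotation, RPM normalization
#' with abundance filtering, pool-consistency QC and the regulation
#' statistics, writing every stage's table plus a JSON manifest to
#' `outdir`. The diff-reg analysis is reported twice -- with all pools
#' and with the excluded pools dropped -- mirroring the dual
#' presentation of discretionary outlier exclusion. Identical
#' configuration and seed give identical outputs.
#'
#' @param config A [runConfig()].
#' @param outdir Output directory (created; existing files overwritten).
#' @return The manifest list, invisibly. Stage outputs: `counts.tsv`,
#'   `annotation.tsv` (when libraries are given), `rpm.tsv`,
#'   `qc_report.tsv`, `dendrogram.nwk`, `snlreg_<line>.tsv`,
#'   `diffreg_all.tsv`, `diffreg_excluded.tsv`, `baseline.tsv`,
#'   `manifest.json`.
#' @export
runPipeline <- function(config, outdir) {
  stopifnot(inherits(config, "runConfig"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  log <- file.path(outdir, "run.log")
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(msg, "\n", file = log, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    say("stage ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  manifest <- list(seed = config$seed, metric = config$metric)

  truth <- NULL
  x <- stage("input", {
    if (!is.null(config$synthetic)) {
      sim <- generateCounts(config$synthetic)
      truth <- sim$truth
      sim$experiment
    } else {
      readExpressionTSV(config$countsFile, config$design)
    }
  })
  writeExpressionTSV(x, file.path(outdir, "counts.tsv"))
  manifest$input <- list(elements = nrow(x), pools = ncol(x),
                         readsPerPool = unname(colSums(
                           SummarizedExperiment::assay(x))))

  libraryAssignment <- NULL
  if (!is.null(config$libraries)) {
    annRes <- stage("annotate", annotateMatrix(x, config$libraries))
    ann <- annRes$annotation
    write.table(data.frame(sequence = rownames(ann), as.data.frame(ann)),
                file.path(outdir, "annotation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$annotation <- list(
      assigned = sum(!is.na(ann$identifier)),
      unassigned = sum(is.na(ann$identifier)),
      identifiers = if (is.null(annRes$byIdentifier)) 0L
                    else nrow(annRes$byIdentifier))
    x <- annRes$readsLevel
    libraryAssignment <- ann$library
  }

  rpm <- stage("quantify", {
    r <- toRPM(x, config$rpmMode, libraryAssignment)
    abundanceFilter(r, config$rpmThreshold, config$minPools)
  })
  writeExpressionTSV(rpm, file.path(outdir, "rpm.tsv"))
  manifest$quantify <- list(mode = config$rpmMode,
                            retained = nrow(rpm), of = nrow(x))

  qc <- stage("qc", poolConsistency(rpm))
  write.table(qc@evidence, file.path(outdir, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  consistencyNewick(qc, file.path(outdir, "dendrogram.nwk"))
  flagged <- names(qc@flags)[qc@flags]
  manifest$qc <- list(groupCV = as.list(round(qc@groupCV, 4)),
                      flagged = flagged)
  excluded <- if (is.null(config$excludePools)) flagged
              else config$excludePools

  stage("stats", {
    lines <- unique(config$design$line)
    for (ln in lines) {
      sr <- snlRegTest(rpm, ln, config$metric, alpha = config$alpha)
      write.table(data.frame(element = rownames(sr), as.data.frame(sr)),
                  file.path(outdir, paste0("snlreg_", ln, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$snlReg[[ln]] <- list(
        tested = sum(!is.na(sr$p)),
        significant = sum(sr$q <= config$alpha, na.rm = TRUE))
    }
    runDiff <- function(excl, fname) {
      dr <- diffRegPairwise(rpm, config$metric, excludePools = excl,
                            permRuns = config$permRuns,
                            seed = config$seed, alpha = config$alpha)
      write.table(data.frame(element = rownames(dr), as.data.frame(dr)),
                  file.path(outdir, fname), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      list(tested = sum(!is.na(dr$p)),
           significant = sum(dr$q <= config$alpha, na.rm = TRUE))
    }
    manifest$diffReg <- list(
      allPools = runDiff(NULL, "diffreg_all.tsv"),
      excluded = c(list(pools = excluded),
                   if (length(excluded))
                     runDiff(excluded, "diffreg_excluded.tsv")
                   else runDiff(NULL, "diffreg_excluded.tsv")))
    bl <- baselineCompare(rpm, alpha = config$alpha)
    write.table(data.frame(element = rownames(bl), as.data.frame(bl)),
                file.path(outdir, "baseline.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest$baseline <- list(
      significant = sum(bl$q <= config$alpha, na.rm = TRUE))
  })

  if (!is.null(truth)) {
    jsonlite::write_json(
      list(spikes = truth$spikes, outlierPool = truth$outlierPool),
      file.path(outdir, "ground_truth.json"), auto_unbox = TRUE,
      digits = NA, null = "null")
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("done")
  invisible(manifest)
}
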