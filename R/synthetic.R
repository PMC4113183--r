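#' Configuration for the synthetic small-RNA data generator
#'
#' The generator emulates the statistical structure of the profiled DRG
#' small-RNA data: heavy-tailed (log-normal) abundances spanning several
#' orders of magnitude, negative-binomial replicate noise at a target
#' coefficient of variation, a subtle line-baseline dispersion, shared
#' (non-differential) injury effects on a fraction of elements,
#' line-specific injury spike-ins (the differential-regulation ground
#' truth), and an optional outlier pool with a perturbed composition.
#'
#' @param nElements Number of RNA elements to simulate.
#' @param design Pool design ([poolDesign()]); first line carries the
#'   line-baseline factors and (by default) the spike-ins, second
#'   condition is the injury condition.
#' @param totalReads Target reads per pool (column sums are approximately
#'   this value).
#' @param abundanceMeanlog,abundanceSdlog Log-normal parameters of the
#'   relative abundance law (only the shape matters; abundances are
#'   rescaled to RPM).
#' @param cv Target within-group coefficient of variation of replicate
#'   counts. Counts are negative-binomial with total CV equal to `cv`
#'   wherever the mean allows (Poisson noise is the floor for rare
#'   elements). `NULL` gives pure Poisson noise; `0` gives deterministic
#'   (noise-free) counts.
#' @param lineSd Sdlog of the per-element line-baseline factor
#'   (line 1 vs line 2); 0 disables.
#' @param injuryFraction,injurySdLog Fraction of elements with a shared
#'   (same in both lines, hence non-differential) injury effect, and the
#'   sdlog of those log-normal effect folds.
#' @param spikes Either `NULL` (draw spike-ins from the settings below) or
#'   a `data.frame(element, line, fold)` of explicit line-specific injury
#'   effects (`fold` strictly positive; `element` = row index or name).
#' @param spikeFraction,spikeFoldRange,spikeLine,spikeMinRPM Automatic
#'   spike-in settings: fraction of elements spiked, fold magnitude range
#'   (applied up or down at random), affected line, and the minimum true
#'   RPM of eligible elements.
#' @param outlierPool Optional pool id to perturb (e.g. `"HA_SNL1"`).
#' @param outlierFraction,outlierInflation The perturbation multiplies a
#'   random `outlierFraction` of elements in that pool by i.i.d. factors
#'   drawn uniformly from `[1/outlierInflation, outlierInflation]`.
#' @param adapter 3' adapter sequence used when emitting raw reads.
#' @param seed Random seed; the same configuration and seed give
#'   bit-identical output.
#' @return A validated configuration list of class `"syntheticConfig"`.
#' @seealso [generateCounts()], [emitFastq()]
#' @export
syntheticConfig <- function(nElements = 500L,
                            design = poolDesign(),
                            totalReads = 1e6,
                            abundanceMeanlog = log(100),
                            abundanceSdlog = 2,
                            cv = 0.2,
                            lineSd = 0.1,
                            injuryFraction = 0.25,
                            injurySdLog = 0.5,
                            spikes = NULL,
                            spikeFraction = 0.05,
                            spikeFoldRange = c(1.5, 3),
                            spikeLine = NULL,
                            spikeMinRPM = 1000,
                            outlierPool = NULL,
                            outlierFraction = 0.3,
                            outlierInflation = 3,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            seed = 1L) {
  .checkDesign(design)
  nElements <- as.integer(nElements)
  if (is.na(nElements) || nElements < 1L) stop("'nElements' must be >= 1")
  if (!is.numeric(totalReads) || totalReads <= 0)
    stop("'totalReads' must be positive")
  if (min(table(design$group)) < 2L)
    stop("every group needs >= 2 replicate pools")
  if (!is.null(cv) && (!is.numeric(cv) || cv < 0)) stop("'cv' must be >= 0")
  if (!is.null(spikes)) {
    if (!all(c("element", "line", "fold") %in% names(spikes)))
      stop("'spikes' needs columns element, line, fold")
    if (any(spikes$fold <= 0)) stop("spike folds must be strictly positive")
    if (!all(spikes$line %in% design$line))
      stop("spike lines must appear in the design")
  }
  if (!is.null(outlierPool)) {
    if (!outlierPool %in% design$pool) stop("unknown outlier pool")
    if (outlierInflation < 1) stop("'outlierInflation' must be >= 1")
  }
  if (is.null(spikeLine)) spikeLine <- design$line[1L]
  structure(list(
    nElements = nElements, design = design, totalReads = totalReads,
    abundanceMeanlog = abundanceMeanlog, abundanceSdlog = abundanceSdlog,
    cv = cv, lineSd = lineSd,
    injuryFraction = injuryFraction, injurySdLog = injurySdLog,
    spikes = spikes, spikeFraction = spikeFraction,
    spikeFoldRange = spikeFoldRange, spikeLine = spikeLine,
    spikeMinRPM = spikeMinRPM,
    outlierPool = outlierPool, outlierFraction = outlierFraction,
    outlierInflation = outlierInflation,
    adapter = adapter, seed = as.integer(seed)
  ), class = "syntheticConfig")
}

#' Generate a synthetic count matrix with known ground truth
#'
#' Draws per-pool counts around group means built from the configured
#' abundance, line, injury and spike-in structure, and returns them
#' together with the ground truth needed for parameter-recovery tests.
#'
#' @param config A [syntheticConfig()] object.
#' @return A list with elements
#'   \describe{
#'     \item{experiment}{[SmallRNAExperiment-class] of raw counts
#'       (elements x pools).}
#'     \item{truth}{List: `meanRPM` (elements x groups true RPM),
#'       `spikes` (`data.frame(element, line, fold)` of the truly
#'       differentially regulated elements; `fold` < 1 means
#'       down-regulation), `outlierPool` and `outlierFactors`.}
#'   }
#' @examples
#' sim <- generateCounts(syntheticConfig(nElements = 50, seed = 7))
#' sim$experiment
#' head(sim$truth$spikes)
#' @export
generateCounts <- function(config) {
  if (!inherits(config, "syntheticConfig"))
    config <- do.call(syntheticConfig, as.list(config))
  set.seed(config$seed)
  n <- config$nElements
  design <- config$design
  lines <- unique(design$line)
  conditions <- unique(design$condition)
  injCond <- conditions[length(conditions)]
  groups <- unique(design$group)

  w <- rlnorm(n, config$abundanceMeanlog, config$abundanceSdlog)
  baseRPM <- 1e6 * w / sum(w)
  elements <- sprintf("el%0*d", nchar(n), seq_len(n))

  lineFac <- if (config$lineSd > 0) rlnorm(n, 0, config$lineSd) else rep(1, n)
  inj <- rep(1, n)
  nInj <- round(config$injuryFraction * n)
  if (nInj > 0) {
    idx <- sample.int(n, nInj)
    inj[idx] <- rlnorm(nInj, 0, config$injurySdLog)
  }

  ## group mean RPM: line factor on line 1, shared injury effect on the
  ## injury condition of both lines
  mu <- matrix(0, n, length(groups), dimnames = list(elements, groups))
  for (g in groups) {
    ln <- design$line[match(g, design$group)]
    cn <- design$condition[match(g, design$group)]
    v <- baseRPM
    if (ln == lines[1L]) v <- v * lineFac
    if (cn == injCond) v <- v * inj
    mu[, g] <- v
  }

  ## line-specific spike-ins: the differential-regulation ground truth
  spikes <- config$spikes
  if (is.null(spikes)) {
    nSpike <- round(config$spikeFraction * n)
    cand <- which(baseRPM >= config$spikeMinRPM)
    nSpike <- min(nSpike, length(cand))
    if (nSpike > 0) {
      el <- sort(sample(cand, nSpike))
      fold <- runif(nSpike, config$spikeFoldRange[1L], config$spikeFoldRange[2L])
      up <- sample(c(TRUE, FALSE), nSpike, replace = TRUE)
      spikes <- data.frame(element = elements[el],
                           line = config$spikeLine,
                           fold = ifelse(up, fold, 1 / fold))
    } else {
      spikes <- data.frame(element = character(), line = character(),
                           fold = numeric())
    }
  } else {
    spikes <- as.data.frame(config$spikes)
    if (is.numeric(spikes$element)) spikes$element <- elements[spikes$element]
  }
  for (k in seq_len(nrow(spikes))) {
    g <- paste0(spikes$line[k], "_", injCond)
    mu[spikes$element[k], g] <- mu[spikes$element[k], g] * spikes$fold[k]
  }

  ## fixed sequencing depth: rescale every group column to the target total
  mu <- sweep(mu, 2, colSums(mu), "/") * config$totalReads
  trueRPM <- mu * 1e6 / config$totalReads

  outlierFactors <- NULL
  if (!is.null(config$outlierPool)) {
    m <- round(config$outlierFraction * n)
    idx <- sample.int(n, m)
    fac <- runif(m, 1 / config$outlierInflation, config$outlierInflation)
    outlierFactors <- data.frame(element = elements[idx], factor = fac)
  }

  counts <- matrix(0, n, nrow(design),
                   dimnames = list(elements, design$pool))
  for (p in design$pool) {
    m <- mu[, .groupOf(design, p)]
    if (!is.null(config$outlierPool) && p == config$outlierPool) {
      i <- match(outlierFactors$element, elements)
      m[i] <- m[i] * outlierFactors$factor
    }
    counts[, p] <- .drawCounts(m, config$cv)
  }

  truth <- list(meanRPM = trueRPM, spikes = spikes,
                outlierPool = config$outlierPool,
                outlierFactors = outlierFactors)
  list(experiment = SmallRNAExperiment(counts, design, quantMode = "raw"),
       truth = truth)
}

## count law: NB with total CV = cv where the mean allows, Poisson floor
## below; cv = NULL -> Poisson, cv = 0 -> noise-free rounding
.drawCounts <- function(m, cv) {
  n <- length(m)
  if (!is.null(cv) && cv == 0) return(round(m))
  x <- numeric(n)
  if (is.null(cv)) return(rpois(n, m))
  pois <- cv^2 <= 1 / pmax(m, .Machine$double.eps)
  if (any(!pois)) {
    size <- 1 / (cv^2 - 1 / m[!pois])
    x[!pois] <- rnbinom(sum(!pois), mu = m[!pois], size = size)
  }
  if (any(pois)) x[pois] <- rpois(sum(pois), m[pois])
  x
}

#' Simulate element sequences with the tri-modal small-RNA size profile
#'
#' Draws unique random RNA sequences whose lengths follow the three size
#' classes seen in DRG small-RNA data: 17--18 nt, 21--23 nt (the miRNA
#' mode) and 32--34 nt.
#'
#' @param n Number of sequences.
#' @param seed Random seed.
#' @param modeWeights Probabilities of the three size classes.
#' @return Named character vector of unique RNA sequences (names
#'   `el...`, matching [generateCounts()] row names for equal `n`).
#' @export
simulateSequences <- function(n, seed = 1L, modeWeights = c(0.2, 0.6, 0.2)) {
  set.seed(as.integer(seed))
  classes <- list(17:18, 21:23, 32:34)
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    cls <- sample.int(3L, k, replace = TRUE, prob = modeWeights)
    len <- vapply(classes[cls], function(v) sample(v, 1L), integer(1))
    seqs <- vapply(len, function(L)
      paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = ""),
      character(1))
    out <- unique(c(out, seqs))
  }
  out <- out[seq_len(n)]
  names(out) <- sprintf("el%0*d", nchar(n), seq_len(n))
  out
}

#' Emit per-pool raw reads (FASTQ) from a count matrix
#'
#' Writes one FASTQ file per pool in which every read is an element
#' sequence followed by the 3' adapter, replicated to the element's count
#' in that pool. Optional corruption emulates library artefacts: 3'
#' non-templated A/U additions (inserted between the insert and the
#' adapter), a single adapter substitution, or adapter truncation below
#' the detectable length.
#'
#' @param x [SmallRNAExperiment-class] of raw counts.
#' @param sequences Named character vector (RNA or DNA) of element
#'   sequences, 16--41 nt, names covering `rownames(x)`.
#' @param adapter Adapter sequence (written in DNA).
#' @param dir Output directory (created if needed).
#' @param ntaRate Fraction of reads receiving a +1/+2 nt 3' A/U addition
#'   before the adapter.
#' @param adapterMismatchRate Fraction of reads whose adapter carries one
#'   random substitution.
#' @param adapterTruncateRate Fraction of reads whose adapter is truncated
#'   to `truncateTo` nt (9 nt by default, below the 10-nt detection
#'   minimum, so such reads are rejected downstream).
#' @param truncateTo Length the adapter is truncated to.
#' @param qualityChar Constant Phred quality character.
#' @param seed Random seed for the corruption draws.
#' @return Invisibly, a named character vector of file paths (one per
#'   pool).
#' @export
emitFastq <- function(x, sequences, adapter = "TGGAATTCTCGGGTGCCAAGG",
                      dir = tempdir(), ntaRate = 0,
                      adapterMismatchRate = 0, adapterTruncateRate = 0,
                      truncateTo = 9L, qualityChar = "I", seed = 1L) {
  counts <- SummarizedExperiment::assay(x)
  if (quantMode(x) != "raw") stop("emitFastq needs raw counts")
  if (!all(rownames(counts) %in% names(sequences)))
    stop("'sequences' must cover all row names of 'x'")
  seqs <- chartr("Uu", "Tt", toupper(sequences[rownames(counts)]))
  len <- nchar(seqs)
  if (any(len < 16L | len > 41L))
    stop("element sequences must be 16-41 nt")
  adapter <- chartr("Uu", "Tt", toupper(adapter))
  set.seed(as.integer(seed))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- setNames(file.path(dir, paste0(colnames(counts), ".fastq")),
                    colnames(counts))
  for (p in colnames(counts)) {
    cnt <- counts[, p]
    inserts <- rep(seqs, times = cnt)
    nr <- length(inserts)
    adp <- rep(adapter, nr)
    if (nr > 0) {
      nta <- runif(nr) < ntaRate
      if (any(nta)) {
        add <- vapply(which(nta), function(i)
          paste(sample(c("A", "T"), sample(1:2, 1L), replace = TRUE),
                collapse = ""), character(1))
        inserts[nta] <- paste0(inserts[nta], add)
      }
      trunc <- runif(nr) < adapterTruncateRate
      if (any(trunc)) adp[trunc] <- substr(adapter, 1L, truncateTo)
      mism <- runif(nr) < adapterMismatchRate & !trunc
      if (any(mism)) {
        adp[mism] <- vapply(adp[mism], function(a) {
          pos <- sample.int(nchar(a), 1L)
          old <- substr(a, pos, pos)
          substr(a, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
          a
        }, character(1), USE.NAMES = FALSE)
      }
    }
    readSeqs <- paste0(inserts, adp)
    reads <- Biostrings::DNAStringSet(readSeqs)
    names(reads) <- sprintf("%s_read%06d", p, seq_len(max(nr, 0)))
    quals <- Biostrings::BStringSet(strrep(qualityChar, nchar(readSeqs)))
    Biostrings::writeXStringSet(reads, files[[p]], format = "fastq",
                                qualities = quals)
  }
  invisible(files)
}
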