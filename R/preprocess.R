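#' Trim the 3' adapter from raw reads
#'
#' Scans each read left to right for the adapter and returns the 5'
#' portion preceding it. The adapter is detected at the leftmost position
#' where its prefix matches the read over at least `minOverlap`
#' consecutive bases with at most `maxMismatch` substitutions; when the
#' adapter occurrence runs off the read's 3' end the full overlapping
#' stretch (still >= `minOverlap`) must match within the same mismatch
#' budget. Reads in which no adapter is detected are rejected (`NA`).
#'
#' Matching is substitution-only (no indels) and case-insensitive;
#' `U`/`T` are treated as equivalent.
#'
#' @param reads Character vector of raw read sequences.
#' @param adapter Adapter sequence, length >= `minOverlap`.
#' @param minOverlap Minimum detected adapter length (default 10 nt).
#' @param maxMismatch Maximum substitutions in the detected stretch
#'   (default 1).
#' @return Character vector of trimmed inserts; `NA` where no adapter was
#'   detected. A zero-length insert (adapter at position 1) is returned
#'   as `""`.
#' @examples
#' trimAdapter("ACGTACGTACGTACGTACGTAA" , "AAGGCCTTGG")  # no adapter -> NA
#' trimAdapter(paste0("ACGTACGTACGTACGT", "TGGAATTCTCGG"), "TGGAATTCTCGGGTGCCAAGG")
#' @export
trimAdapter <- function(reads, adapter, minOverlap = 10L, maxMismatch = 1L) {
  if (any(!nzchar(reads)) || any(is.na(reads)))
    stop("empty or NA read")
  adapter <- chartr("Uu", "Tt", toupper(adapter))
  if (nchar(adapter) < minOverlap)
    stop("adapter must be at least ", minOverlap, " nt")
  reads0 <- chartr("Uu", "Tt", toupper(reads))
  lens <- nchar(reads0)
  maxLen <- max(lens)
  aChars <- strsplit(adapter, "")[[1]]
  aLen <- length(aChars)

  ## reads as a padded character matrix (rows = reads)
  mat <- matrix(NA_character_, length(reads0), maxLen)
  sp <- strsplit(reads0, "")
  for (i in seq_along(sp)) mat[i, seq_len(lens[i])] <- sp[[i]]

  cut <- rep(NA_integer_, length(reads0))
  ## leftmost adapter start: iterate candidate start positions; a
  ## position is only viable if >= minOverlap read bases remain
  for (p in seq_len(max(0L, maxLen - minOverlap + 1L))) {
    open <- which(is.na(cut) & lens - p + 1L >= minOverlap)
    if (!length(open)) next
    span <- min(aLen, maxLen - p + 1L)
    cols <- mat[open, p:(p + span - 1L), drop = FALSE]
    mm <- rowSums(cols != rep(aChars[seq_len(span)], each = length(open)),
                  na.rm = TRUE)
    hit <- mm <= maxMismatch
    cut[open[hit]] <- p
  }
  out <- rep(NA_character_, length(reads0))
  ok <- !is.na(cut)
  out[ok] <- substr(reads0[ok], 1L, cut[ok] - 1L)
  out
}

#' Length filter for trimmed sequences
#'
#' Keeps sequences whose length is within the retained small-RNA range
#' (16--41 nt by default; both bounds inclusive).
#'
#' @param seqs Character vector of trimmed sequences (`NA` allowed; never
#'   kept).
#' @param minLen,maxLen Inclusive length bounds.
#' @return Logical vector, `TRUE` for sequences to keep.
#' @export
lengthFilter <- function(seqs, minLen = 16L, maxLen = 41L) {
  n <- nchar(seqs)
  !is.na(seqs) & n >= minLen & n <= maxLen
}

#' Collapse edited reads into a unique-sequence count matrix
#'
#' Sorts the retained reads of every pool into unique sequences and their
#' per-pool multiplicities ("reads-level" counts). `T` is mapped to `U`
#' on ingest; all internal sequences are RNA.
#'
#' @param readsPerPool Named list (names = pool ids of `design`) of
#'   character vectors of edited reads.
#' @param design Pool design ([poolDesign()]).
#' @return A [SmallRNAExperiment-class] of raw counts, one row per
#'   distinct sequence (row names are the RNA sequences).
#' @export
collapseReads <- function(readsPerPool, design = poolDesign()) {
  .checkDesign(design)
  if (!setequal(names(readsPerPool), design$pool))
    stop("names of 'readsPerPool' must match the design pool ids")
  readsPerPool <- lapply(readsPerPool, function(r)
    chartr("Tt", "Uu", toupper(r[!is.na(r)])))
  seqs <- sort(unique(unlist(readsPerPool, use.names = FALSE)))
  counts <- matrix(0L, length(seqs), nrow(design),
                   dimnames = list(seqs, design$pool))
  for (p in design$pool) {
    tab <- table(readsPerPool[[p]])
    counts[names(tab), p] <- as.integer(tab)
  }
  SmallRNAExperiment(counts, design, quantMode = "raw")
}

#' Read one pool's FASTQ file
#'
#' @param file FASTQ path (uncompressed or gzipped).
#' @return Character vector of read sequences (DNA as stored).
#' @export
readPoolFastq <- function(file) {
  as.character(Biostrings::readDNAStringSet(file, format = "fastq"))
}

#' Edit raw FASTQ pools into a collapsed reads-level matrix
#'
#' Runs the full editing stage per pool: adapter trimming
#' ([trimAdapter()]), 16--41 nt length filtering ([lengthFilter()]) and
#' collapsing to unique sequences ([collapseReads()]). Quality scores are
#' ignored.
#'
#' @param files Named character vector of FASTQ paths (names = pool ids).
#' @param adapter Adapter sequence.
#' @param design Pool design.
#' @param minLen,maxLen Retained length range (applied after trimming).
#' @return A [SmallRNAExperiment-class] of collapsed counts with a
#'   per-pool editing log in `metadata(x)$editing` (reads in, with
#'   adapter, retained).
#' @export
preprocessPools <- function(files, adapter, design = poolDesign(),
                            minLen = 16L, maxLen = 41L) {
  .checkDesign(design)
  if (!setequal(names(files), design$pool))
    stop("names of 'files' must match the design pool ids")
  log <- data.frame(pool = design$pool, input = 0L, trimmed = 0L,
                    retained = 0L)
  kept <- setNames(vector("list", nrow(design)), design$pool)
  for (p in design$pool) {
    raw <- readPoolFastq(files[[p]])
    trimmed <- if (length(raw)) trimAdapter(raw, adapter) else character(0)
    keep <- lengthFilter(trimmed, minLen, maxLen)
    kept[[p]] <- trimmed[keep]
    log[log$pool == p, c("input", "trimmed", "retained")] <-
      c(length(raw), sum(!is.na(trimmed)), sum(keep))
  }
  x <- collapseReads(kept, design)
  S4Vectors::metadata(x)$editing <- log
  x
}
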