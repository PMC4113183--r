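#' Ordered reference library for seed-alignment annotation
#'
#' One of the ranked libraries (known rat miRNAs, all-species miRNAs,
#' RefSeq, Rfam, tRNA, repeats, piRNA) that reads are mapped against in
#' precedence order. Each library carries its own mismatch budget for the
#' 20-nt seed alignment (1 for the rank-1 known miRNAs, 2 for putative
#' homologs, configurable otherwise).
#'
#' @slot name Library label.
#' @slot rank Integer precedence (1 = first searched).
#' @slot sequences Named character vector of RNA consensus sequences
#'   (names = canonical identifiers, unique within the library).
#' @slot mismatchBudget Integer >= 0.
#' @exportClass ReferenceLibrary
setClass("ReferenceLibrary",
  representation(name = "character", rank = "integer",
                 sequences = "character", mismatchBudget = "integer"))

setValidity("ReferenceLibrary", function(object) {
  msg <- NULL
  if (length(object@rank) != 1L || is.na(object@rank) || object@rank < 1L)
    msg <- c(msg, "rank must be a positive integer")
  if (length(object@mismatchBudget) != 1L || object@mismatchBudget < 0L)
    msg <- c(msg, "mismatchBudget must be >= 0")
  if (length(object@sequences) == 0L)
    msg <- c(msg, "library has no entries")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msg <- c(msg, "entry identifiers must be present and unique")
  if (any(!nzchar(object@sequences)))
    msg <- c(msg, "consensus sequences must be non-empty")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ReferenceLibrary-class Constructor.
#' @param name Library label.
#' @param rank Precedence rank (1 = searched first).
#' @param sequences Named character vector (or `RNAStringSet` /
#'   `DNAStringSet`) of consensus sequences; `T` is converted to `U`.
#' @param mismatchBudget Seed mismatch budget for this library.
#' @export
referenceLibrary <- function(name, rank, sequences, mismatchBudget = 0L) {
  if (methods::is(sequences, "XStringSet"))
    sequences <- setNames(as.character(sequences), names(sequences))
  sequences <- setNames(chartr("Tt", "Uu", toupper(sequences)),
                        names(sequences))
  new("ReferenceLibrary", name = name, rank = as.integer(rank),
      sequences = sequences, mismatchBudget = as.integer(mismatchBudget))
}

#' Read a reference library from FASTA
#'
#' @param file FASTA path; the first whitespace-delimited token of each
#'   header is the identifier.
#' @inheritParams referenceLibrary
#' @return A [ReferenceLibrary-class].
#' @export
readLibraryFasta <- function(file, name, rank, mismatchBudget = 0L) {
  s <- Biostrings::readDNAStringSet(file)
  names(s) <- vapply(strsplit(names(s), "\\s+"), `[`, character(1), 1L)
  referenceLibrary(name, rank, s, mismatchBudget)
}

setMethod("show", "ReferenceLibrary", function(object) {
  cat("ReferenceLibrary '", object@name, "' (rank ", object@rank,
      ", budget ", object@mismatchBudget, "): ",
      length(object@sequences), " entries\n", sep = "")
})

#' Seed alignment of a read against a consensus sequence
#'
#' Aligns only the first `seedLength` nt of the read (its full length if
#' shorter) to the consensus, sense strand, ungapped,
#' substitution-only. Bases beyond the seed never count, so 3'
#' non-templated additions cannot produce mismatches. The seed may start
#' at any offset within `maxOffset` nt of the consensus 5' end; seed
#' positions falling outside the consensus count as mismatches. The
#' minimal mismatch count over all offsets is reported.
#'
#' @param read Read sequence (RNA or DNA).
#' @param consensus Consensus sequence (non-empty).
#' @param budget Maximum seed mismatches for a hit.
#' @param seedLength Seed length (default 20 nt).
#' @param maxOffset Maximum 5' offset of the seed on the consensus
#'   (default 2, matching the isomiR 5'-fluctuation tolerance).
#' @return A list: `hit` (logical), `mismatches` (minimum over offsets),
#'   `offset` (the minimizing offset; read position 1 aligns to consensus
#'   position `1 + offset`).
#' @examples
#' seedAlign("ACGUACGUACGUACGUACGUUU", "ACGUACGUACGUACGUACGU", budget = 1)
#' @export
seedAlign <- function(read, consensus, budget, seedLength = 20L,
                      maxOffset = 2L) {
  if (is.na(consensus) || !nzchar(consensus)) stop("empty consensus")
  if (budget < 0) stop("'budget' must be >= 0")
  read <- chartr("Tt", "Uu", toupper(read))
  consensus <- chartr("Tt", "Uu", toupper(consensus))
  seed <- substr(read, 1L, min(seedLength, nchar(read)))
  sChars <- strsplit(seed, "")[[1]]
  cChars <- strsplit(consensus, "")[[1]]
  k <- length(sChars)
  best <- Inf; bestOff <- NA_integer_
  for (off in seq.int(-maxOffset, maxOffset)) {
    pos <- seq_len(k) + off
    inside <- pos >= 1L & pos <= length(cChars)
    mm <- sum(!inside) + sum(sChars[inside] != cChars[pos[inside]])
    if (mm < best) { best <- mm; bestOff <- off }
  }
  list(hit = best <= budget, mismatches = best, offset = bestOff)
}

## best (library entry, mismatches) for one sequence, or NULL
.bestLibraryHit <- function(seq, lib, seedLength, maxOffset) {
  ids <- names(lib@sequences)
  mm <- vapply(lib@sequences, function(cons)
    seedAlign(seq, cons, budget = lib@mismatchBudget,
              seedLength = seedLength, maxOffset = maxOffset)$mismatches,
    numeric(1))
  hit <- mm <= lib@mismatchBudget
  if (!any(hit)) return(NULL)
  ids <- ids[hit]; mm <- mm[hit]
  ## lowest mismatch count wins, remaining ties to the lexicographically
  ## first identifier
  o <- order(mm, ids)
  list(identifier = ids[o[1L]], mismatches = mm[o[1L]])
}

#' Annotate a reads-level matrix against ordered libraries
#'
#' Tests every unique sequence against the libraries in rank order and
#' assigns it at the first library with a seed-alignment hit; assigned
#' sequences are removed from the input to later libraries, so no
#' sequence is counted twice. Sequences hitting no library are retained,
#' unnamed, in the reads-level matrix. IsomiRs (distinct sequences
#' assigned to one identifier) are summed into a per-identifier matrix.
#'
#' @param x [SmallRNAExperiment-class] whose row names are sequences.
#' @param libraries List of [ReferenceLibrary-class] objects; ranks must
#'   be unique and are used as precedence order.
#' @param seedLength,maxOffset Passed to [seedAlign()].
#' @return A list:
#'   \describe{
#'     \item{annotation}{`DataFrame` (one row per sequence): `library`,
#'       `rank`, `identifier`, `mismatches` (`NA` when unassigned).}
#'     \item{readsLevel}{`x` with the annotation attached as `rowData`.}
#'     \item{byIdentifier}{[SmallRNAExperiment-class] of per-identifier
#'       counts (isomiR counts summed), with `rowData` columns
#'       `library` and `rank`.}
#'   }
#' @export
annotateMatrix <- function(x, libraries, seedLength = 20L, maxOffset = 2L) {
  ranks <- vapply(libraries, function(l) l@rank, integer(1))
  if (anyDuplicated(ranks)) stop("library ranks must be unique")
  libraries <- libraries[order(ranks)]
  seqs <- rownames(x)
  ann <- DataFrame(library = rep(NA_character_, length(seqs)),
                   rank = rep(NA_integer_, length(seqs)),
                   identifier = rep(NA_character_, length(seqs)),
                   mismatches = rep(NA_integer_, length(seqs)),
                   row.names = seqs)
  pending <- seq_along(seqs)
  for (lib in libraries) {
    if (!length(pending)) break
    assigned <- logical(length(pending))
    for (j in seq_along(pending)) {
      hitRes <- .bestLibraryHit(seqs[pending[j]], lib, seedLength, maxOffset)
      if (!is.null(hitRes)) {
        i <- pending[j]
        ann$library[i] <- lib@name
        ann$rank[i] <- lib@rank
        ann$identifier[i] <- hitRes$identifier
        ann$mismatches[i] <- as.integer(hitRes$mismatches)
        assigned[j] <- TRUE
      }
    }
    pending <- pending[!assigned]
  }
  readsLevel <- x
  SummarizedExperiment::rowData(readsLevel) <- ann

  idx <- which(!is.na(ann$identifier))
  byId <- NULL
  if (length(idx)) {
    counts <- SummarizedExperiment::assay(x)[idx, , drop = FALSE]
    idCounts <- rowsum(counts, group = ann$identifier[idx])
    meta <- unique(data.frame(identifier = ann$identifier[idx],
                              library = ann$library[idx],
                              rank = ann$rank[idx]))
    meta <- meta[match(rownames(idCounts), meta$identifier), ]
    byId <- SmallRNAExperiment(
      idCounts,
      design = as(SummarizedExperiment::colData(x), "DataFrame"),
      quantMode = quantMode(x),
      rowData = DataFrame(library = meta$library, rank = meta$rank,
                          row.names = rownames(idCounts)))
  }
  list(annotation = ann, readsLevel = readsLevel, byIdentifier = byId)
}

#' Cluster aligned reads around shared start positions
#'
#' Groups precomputed (position, sequence, count) tuples into candidate
#' clusters, allowing a window of `window` nt around the start position
#' of the most frequent read of each cluster (novel-miRNA candidate
#' preprocessing; genome extraction and hairpin folding happen upstream
#' and are not part of this package).
#'
#' @param reads `data.frame` with columns `start`, `sequence`, `count`.
#' @param window Start-position window around the anchor (default 2 nt).
#' @return List of clusters as returned by [readCluster()].
#' @export
clusterReads <- function(reads, window = 2L) {
  stopifnot(all(c("start", "sequence", "count") %in% names(reads)))
  reads <- reads[order(-reads$count, reads$start), , drop = FALSE]
  clusters <- list()
  while (nrow(reads)) {
    anchor <- reads$start[1L]
    member <- abs(reads$start - anchor) <= window
    clusters[[length(clusters) + 1L]] <-
      readCluster(reads[member, , drop = FALSE])
    reads <- reads[!member, , drop = FALSE]
  }
  clusters
}

#' Build a read cluster around its most frequent read
#'
#' @param members `data.frame` with columns `start`, `sequence`, `count`.
#' @param overhangs Optional named integer vector `c(p5 = , p3 = )` of
#'   the 3' overhang lengths of the two precursor arms, precomputed from
#'   the hairpin structure (only needed for the rat-specific candidate
#'   rule).
#' @return A list of class `"readCluster"`: `anchor` (start of the most
#'   frequent read), `mostFrequent` (row), `members`, `overhangs`.
#' @export
readCluster <- function(members, overhangs = NULL) {
  stopifnot(all(c("start", "sequence", "count") %in% names(members)),
            nrow(members) >= 1L)
  top <- members[order(-members$count, members$start), , drop = FALSE][1L, ]
  structure(list(anchor = top$start, mostFrequent = top,
                 members = members, overhangs = overhangs),
            class = "readCluster")
}

#' Threshold filters for novel-miRNA candidate clusters
#'
#' Applies the candidate acceptance rules: (i) read count of the most
#' frequent read >= 10, (ii) its length between 20 and 23 nt, (iii) 5'
#' start fluctuation of cluster members within 2 nt of the anchor; for
#' rat-specific candidates additionally (iv) both precursor arms show
#' perfect 2-nt 3' overhangs.
#'
#' @param cluster A [readCluster()] object.
#' @param ratSpecific Apply the overhang rule (requires
#'   `cluster$overhangs`).
#' @param minCount,lengthRange,maxFluctuation Rule thresholds.
#' @return A list: `pass` (logical) and `reasons` (character vector of
#'   violated rules, empty on pass).
#' @export
novelCandidateFilter <- function(cluster, ratSpecific = FALSE,
                                 minCount = 10L, lengthRange = c(20L, 23L),
                                 maxFluctuation = 2L) {
  stopifnot(inherits(cluster, "readCluster"))
  reasons <- character(0)
  if (cluster$mostFrequent$count < minCount)
    reasons <- c(reasons, "count")
  lenTop <- nchar(cluster$mostFrequent$sequence)
  if (lenTop < lengthRange[1L] || lenTop > lengthRange[2L])
    reasons <- c(reasons, "length")
  if (max(abs(cluster$members$start - cluster$anchor)) > maxFluctuation)
    reasons <- c(reasons, "fluctuation")
  if (ratSpecific) {
    oh <- cluster$overhangs
    if (is.null(oh) || length(oh) != 2L || any(is.na(oh)))
      reasons <- c(reasons, "overhang-unknown")
    else if (!all(oh == 2L))
      reasons <- c(reasons, "overhang")
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}
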