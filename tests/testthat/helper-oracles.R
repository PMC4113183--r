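# Independent brute-force oracles used to cross-check the package's
# implementations. Each is written as plainly (and differently) as
# possible: correctness over speed.

# Benjamini-Hochberg step-up q-values straight from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) m * ps[j] / j)
    q[i] <- min(1, cand)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Seed alignment by naive triple loop over offsets and seed positions.
seedAlignOracle <- function(read, consensus, seedLength = 20L,
                            maxOffset = 2L) {
  read <- chartr("T", "U", toupper(read))
  consensus <- chartr("T", "U", toupper(consensus))
  k <- min(seedLength, nchar(read))
  best <- Inf
  for (off in -maxOffset:maxOffset) {
    mm <- 0L
    for (j in seq_len(k)) {
      cpos <- j + off
      rc <- substr(read, j, j)
      cc <- if (cpos >= 1 && cpos <= nchar(consensus))
        substr(consensus, cpos, cpos) else ""
      if (rc != cc) mm <- mm + 1L
    }
    if (mm < best) best <- mm
  }
  best
}

# Leftmost adapter position by naive scanning (substitution-only).
trimOracle <- function(read, adapter, minOverlap = 10L, maxMismatch = 1L) {
  read <- chartr("Uu", "Tt", toupper(read))
  adapter <- chartr("Uu", "Tt", toupper(adapter))
  for (p in seq_len(nchar(read))) {
    L <- min(nchar(adapter), nchar(read) - p + 1L)
    if (L < minOverlap) next
    mm <- 0L
    for (j in seq_len(L))
      if (substr(read, p + j - 1L, p + j - 1L) != substr(adapter, j, j))
        mm <- mm + 1L
    if (mm <= maxMismatch) return(substr(read, 1L, p - 1L))
  }
  NA_character_
}

# Exact permutation p-value by bitmask enumeration of all subsets of the
# pooled values with the size of the first set.
permOracle <- function(e1, e2) {
  pooled <- c(e1, e2)
  n <- length(pooled)
  n1 <- length(e1)
  obs <- abs(mean(e1) - mean(e2))
  total <- 0L
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) != n1) next
    total <- total + 1L
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12 * max(1, obs)) hits <- hits + 1L
  }
  hits / total
}

# Random RNA string of a given length.
randomRNA <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# RPM experiment in which every pool of a group carries the group mean
# (zero within-group variance), from a groups x elements list.
groupMeanRPM <- function(means, design = poolDesign()) {
  elements <- rownames(means)
  m <- matrix(0, nrow(means), nrow(design),
              dimnames = list(elements, design$pool))
  for (p in design$pool)
    m[, p] <- means[, design$group[match(p, design$pool)]]
  SmallRNAExperiment(m, design, quantMode = "rpm_reads_level")
}
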