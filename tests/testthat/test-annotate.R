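test_that("seed alignment ignores bases beyond the seed (NTA tolerance)", {
  cons <- "UGUAAACAUCCCCGACUGGAAG"            # 22 nt
  expect_true(seedAlign(cons, cons, budget = 0)$hit)
  expect_identical(seedAlign(cons, cons, budget = 0)$mismatches, 0L)
  # 3' non-templated UU addition falls outside the 20-nt seed
  expect_true(seedAlign(paste0(cons, "UU"), cons, budget = 0)$hit)
  # a mismatch at seed position 21 would count for shorter seeds only
  mutated <- cons
  substr(mutated, 21, 21) <- "A"
  expect_true(seedAlign(mutated, cons, budget = 0)$hit)
})

test_that("mismatch budgets separate known-miRNA from homolog matching", {
  cons <- "UGUAAACAUCCCCGACUGGAAG"
  read <- cons
  substr(read, 3, 3) <- "C"
  substr(read, 9, 9) <- "G"
  expect_false(seedAlign(read, cons, budget = 1)$hit)
  expect_true(seedAlign(read, cons, budget = 2)$hit)
  expect_identical(seedAlign(read, cons, budget = 2)$mismatches, 2L)
})

test_that("seed alignment errors on an empty consensus", {
  expect_error(seedAlign("ACGUACGUACGUACGUA", "", budget = 1), "empty")
  expect_error(seedAlign("ACGUACGUACGUACGUA", "ACGU", budget = -1), ">= 0")
})

test_that("seed alignment equals the brute-force Hamming oracle", {
  set.seed(33)
  for (i in 1:150) {
    rlen <- sample(16:25, 1)
    clen <- sample(18:40, 1)
    read <- randomRNA(rlen)
    cons <- randomRNA(clen)
    if (runif(1) < 0.5) {       # half the cases: reads derived from cons
      off <- sample(0:2, 1)
      read <- substr(cons, 1 + off, min(clen, off + rlen))
      if (nchar(read) < 16) read <- paste0(read, randomRNA(16 - nchar(read)))
      pos <- sample(nchar(read), 1)
      substr(read, pos, pos) <- sample(c("A", "C", "G", "U"), 1)
    }
    budget <- sample(0:2, 1)
    got <- seedAlign(read, cons, budget = budget)
    wantMM <- seedAlignOracle(read, cons)
    expect_identical(got$mismatches, as.integer(wantMM))
    expect_identical(got$hit, wantMM <= budget)
  }
})

test_that("library precedence assigns at the first hit and removes it", {
  mir <- "UGUAAACAUCCCCGACUGGAAG"
  trna <- "GCAUUGGUGGUUCAGUGGUAGAAUUCUCGC"
  libs <- list(
    referenceLibrary("known-rat-miRNA", 1, c(`rno-miR-x` = mir),
                     mismatchBudget = 1),
    referenceLibrary("trna", 5, c(`tRNA-Gly` = trna, `tRNA-Amb` = mir),
                     mismatchBudget = 0))
  d <- poolDesign(replicates = 2)
  seqs <- c(mir, paste0(mir, "UU"), trna, randomRNA(22))
  cnt <- matrix(1L, 4, 8, dimnames = list(seqs, d$pool))
  cnt[2, ] <- 3L
  res <- annotateMatrix(SmallRNAExperiment(cnt, d), libs)
  ann <- res$annotation
  # a sequence hitting both libraries goes to the higher-ranked miRNA
  expect_identical(ann[mir, "identifier"], "rno-miR-x")
  expect_identical(ann[mir, "library"], "known-rat-miRNA")
  # isomiR (NTA variant) maps to the same identifier; counts add up
  expect_identical(ann[paste0(mir, "UU"), "identifier"], "rno-miR-x")
  idCounts <- SummarizedExperiment::assay(res$byIdentifier)
  expect_equal(unname(idCounts["rno-miR-x", "HA_sham1"]), 4)
  expect_identical(ann[trna, "identifier"], "tRNA-Gly")
  # unmatched sequences stay, unnamed, in the reads-level matrix
  expect_true(is.na(ann[seqs[4], "identifier"]))
  expect_identical(nrow(res$readsLevel), 4L)
  # partition: assigned + unassigned = all; total counts conserved
  expect_identical(sum(!is.na(ann$identifier)) + sum(is.na(ann$identifier)),
                   nrow(cnt))
  expect_equal(sum(idCounts) +
                 sum(cnt[is.na(ann$identifier), , drop = FALSE]),
               sum(cnt))
})

test_that("permuting ranks only moves sequences that hit both libraries", {
  mir <- "UGUAAACAUCCCCGACUGGAAG"
  other <- "CCGUAAACAUCCCCGACUGGAAGAA"
  libA <- referenceLibrary("A", 1, c(idA = mir), 1)
  libB <- referenceLibrary("B", 2, c(idB = mir, idOnlyB = other), 1)
  d <- poolDesign(replicates = 2)
  cnt <- matrix(1L, 2, 8, dimnames = list(c(mir, other), d$pool))
  x <- SmallRNAExperiment(cnt, d)
  fwd <- annotateMatrix(x, list(libA, libB))$annotation
  libA2 <- referenceLibrary("A", 2, c(idA = mir), 1)
  libB2 <- referenceLibrary("B", 1, c(idB = mir, idOnlyB = other), 1)
  rev <- annotateMatrix(x, list(libA2, libB2))$annotation
  expect_identical(fwd[mir, "identifier"], "idA")
  expect_identical(rev[mir, "identifier"], "idB")     # double hit moves
  expect_identical(fwd[other, "identifier"],
                   rev[other, "identifier"])           # single hit stays
})

test_that("intra-library ties go to fewest mismatches then first identifier", {
  cons <- "UGUAAACAUCCCCGACUGGAAG"
  near <- cons
  substr(near, 5, 5) <- "G"
  lib <- referenceLibrary("L", 1,
                          c(zzz = cons, aaa = near, bbb = cons), 1)
  d <- poolDesign(replicates = 2)
  cnt <- matrix(1L, 1, 8, dimnames = list(cons, d$pool))
  ann <- annotateMatrix(SmallRNAExperiment(cnt, d), list(lib))$annotation
  # exact matches (bbb, zzz) beat the 1-mismatch entry; 'bbb' wins the tie
  expect_identical(ann[cons, "identifier"], "bbb")
  expect_identical(ann[cons, "mismatches"], 0L)
})

test_that("duplicate identifiers within a library are refused", {
  expect_error(referenceLibrary("L", 1,
                                setNames(c("ACGU", "GGCC"), c("a", "a"))),
               "unique")
})

test_that("novel-candidate thresholds accept boundary values and name failures", {
  members <- data.frame(start = c(100, 101, 99),
                        sequence = c(strrep("A", 22), strrep("C", 21),
                                     strrep("G", 22)),
                        count = c(10, 3, 2))
  cl <- readCluster(members)
  expect_identical(cl$anchor, 100)
  ok <- novelCandidateFilter(cl)
  expect_true(ok$pass)
  expect_length(ok$reasons, 0L)
  # too-short most frequent read
  members19 <- members
  members19$sequence[1] <- strrep("A", 19)
  bad <- novelCandidateFilter(readCluster(members19))
  expect_false(bad$pass)
  expect_identical(bad$reasons, "length")
  # low count and excessive fluctuation both reported
  membersBad <- data.frame(start = c(100, 104), count = c(9, 1),
                           sequence = c(strrep("A", 22), strrep("C", 22)))
  worse <- novelCandidateFilter(readCluster(membersBad))
  expect_setequal(worse$reasons, c("count", "fluctuation"))
  # rat-specific candidates need perfect 2-nt 3' overhangs on both arms
  clOH <- readCluster(members, overhangs = c(p5 = 2L, p3 = 1L))
  rs <- novelCandidateFilter(clOH, ratSpecific = TRUE)
  expect_false(rs$pass)
  expect_identical(rs$reasons, "overhang")
  clOK <- readCluster(members, overhangs = c(p5 = 2L, p3 = 2L))
  expect_true(novelCandidateFilter(clOK, ratSpecific = TRUE)$pass)
})

test_that("read clustering uses a 2-nt window around the top read", {
  reads <- data.frame(start = c(50, 51, 52, 53, 80),
                      sequence = replicate(5, randomRNA(22)),
                      count = c(20, 5, 4, 3, 7))
  cls <- clusterReads(reads)
  expect_length(cls, 3L)
  expect_identical(cls[[1]]$anchor, 50)
  expect_identical(sort(cls[[1]]$members$start), c(50, 51, 52))
  expect_identical(cls[[2]]$anchor, 80)   # next most frequent
  expect_identical(cls[[3]]$members$start, 53)
})
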