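---
title: "Methods: differential regulation of small RNAs across contrasting lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential regulation of small RNAs across contrasting lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirDiffReg)
```

## The problem and the design

Nerve injury changes the expression of thousands of transcripts in
primary sensory neurons, but most of those changes track generic injury
responses (regeneration, metabolism, apoptosis) rather than pain. The
strategy this package implements sharpens a genome-wide small-RNA screen
by contrasting two rat selection lines with near-identical genetic
background but opposite neuropathic-pain phenotype: a high-autotomy (HA,
pain-prone) and a low-autotomy (LA, pain-resistant) line. Dorsal root
ganglia are profiled after spinal nerve ligation (SNL) or sham surgery,
in three biological replicate pools per line x condition — a 12-pool,
2 x 2 x 3 design (`poolDesign()`). The quantity of interest is not
injury-induced regulation itself (*SNL-reg*) but its **difference
between the lines** (*diff-reg*): elements regulated equally in both
lines are injury-generic, whereas differential regulation co-segregates
with the pain phenotype.

## Read editing

Raw reads are edited in three steps (`trimAdapter()`, `lengthFilter()`,
`collapseReads()`):

1. **Adapter trimming.** The 3' adapter is detected at the leftmost
   read position where at least 10 nt of the adapter prefix match with
   at most one substitution; when the adapter occurrence runs off the
   read's 3' end, the whole overlapping stretch (still >= 10 nt) must
   match within the same budget. Matching is substitution-only — the
   rule describes a mismatch budget, not a gapped alignment. Reads with
   no detected adapter are discarded.
2. **Length filter.** Trimmed inserts outside 16–41 nt are removed
   (both bounds inclusive; the cap is applied after trimming).
3. **Collapsing.** Retained reads are sorted into unique sequences with
   per-pool multiplicities; `T` is mapped to `U` on ingest so all
   internal sequences are RNA. Quality scores are ignored (the editing
   procedure defines no quality filter).

The result is the "reads-level" matrix: unique sequences x pools, held
in a `SmallRNAExperiment` (a `SummarizedExperiment` with the pool
design in `colData` and a `quantMode` flag).

## Annotation by seed alignment

Reads are assigned identities by aligning only their first 20 nt (the
"seed") against ordered reference libraries (`seedAlign()`,
`annotateMatrix()`). Ignoring everything beyond the seed makes the
mapping robust to 3' non-templated additions (NTAs, post-transcriptional
A/U tailing) and other 3' isomiR variation, which would otherwise
accumulate mismatches against the consensus. Alignment is sense-strand,
ungapped and substitution-only. Mismatch budgets are per library —
1 for known mature miRNAs of the target species, 2 when searching for
putative homologs, configurable elsewhere.

Libraries are searched in precedence order (known rat miRNAs, then
all-species miRNAs, then RefSeq, Rfam, tRNA, repeats, piRNA); a
sequence assigned at one library is removed from the input to all later
ones, so nothing is counted twice. Unassigned sequences remain,
unnamed, in the reads-level matrix and participate in all downstream
statistics. Distinct sequences mapping to one identifier (isomiRs) are
summed into a per-identifier matrix.

Choices the mapping description leaves open, and what this package
does:

* Reads shorter than 20 nt use their full length as the seed,
  preserving the "ignore the 3' end" intent.
* The seed may start within +/-2 nt of the consensus 5' end
  (`maxOffset`, configurable), matching the 5' fluctuation tolerance
  used for isomiRs elsewhere in the analysis; seed bases falling
  outside the consensus count as mismatches.
* Ties inside one library go to the fewest mismatches, then to the
  lexicographically first identifier — a deterministic, documented
  rule for a case the original description does not address.

Candidate novel miRNAs are screened by `clusterReads()` (a 2-nt window
around the start of the most frequent read) and
`novelCandidateFilter()`: most-frequent-read count >= 10, length
20–23 nt, 5' fluctuation <= 2 nt, and — for candidates with no homolog
in any species — perfect 2-nt 3' overhangs on both precursor arms.
Genome extraction, hairpin folding and the machine-learning candidate
classifier are upstream tools and out of scope; the filter consumes
precomputed positions and overhangs.

## Normalization and abundance filtering

`toRPM()` converts counts to reads-per-million independently per pool,
in either of two modes: *reads-level* (denominator = the pool's grand
total) or *within-library* (denominator = the pool total of the rows
assigned to the same library). RPM values stay in floating point; no
rounding happens before filtering. `abundanceFilter()` then keeps
elements with RPM >= 10 in at least 3 of the 12 pools — prevalence
cannot be rescued by abundance, so a huge element seen in only two
pools is dropped.

## Pool-consistency QC

The QC premise is that replicate pools within a group should resemble
each other more than pools across groups. `poolConsistency()` computes
pairwise Pearson correlations between pool profiles, clusters pools by
UPGMA on the distance d = 1 − r, computes per-group mean coefficients
of variation (CV = sample SD / mean per element, averaged over
elements), and raises advisory outlier flags.

**Why correlations default to log10(RPM + 1) profiles.** Small-RNA
abundances span about five decades, and the most abundant element alone
can carry >10% of a pool. On the raw scale, a Pearson correlation
between two pools is then determined by a handful of elements — its
effective sample size is a few, not a few hundred — and the dendrogram
degenerates into noise. Working on log profiles (the convention of the
clustering tool family this stage mirrors, whose heat-map displays are
likewise standardized per element) restores the contribution of the
full profile. `transform = "none"` is available for strict raw-scale
behaviour.

**The outlier rule.** A pool is flagged only if two independent
criteria agree:

* *(a) topology* — the smallest dendrogram cluster containing the pool
  and at least one of its group-mates also contains a foreign pool,
  i.e. the pool joins its own group only after other groups are mixed
  in; and
* *(b) variance* — removing the pool brings its group's mean CV down
  to at most `cvRatioThreshold` (default 1) times the mean CV of the
  other groups.

Flags are advisory: exclusion is an explicit user action
(`excludePools()`), and the regulation statistics are intended to be
reported both with and without the excluded pool, as `runPipeline()`
does.

A limitation worth stating plainly: with 3 replicates per group,
criterion (b) is a knife-edge comparison. After removing a true
outlier, the remaining 2-pool CV is an unbiased but very noisy estimate
centred exactly at the other groups' level; the rule detects reliably
only through the downward small-sample bias of a 2-replicate standard
deviation, and that same bias produces occasional flags on perfectly
clean data (our seeded property tests quantify both rates). The plain
sample SD is used deliberately — CV = SD/mean is how the quantity is
defined in this analysis — and users who need a stricter rule can lower
`cvRatioThreshold`.

## Regulation statistics

### SNL-reg

Because there is no unique measure of regulation, two metrics are
computed for every element and line from the condition means:

* the **subtraction metric** `(SNL − sham) / ((SNL + sham) / 2)`,
  bounded in (−2, 2), zero iff the means are equal, antisymmetric in
  its arguments; it tolerates one-sided zeros (reaching +/-2 at the
  edges); and
* the **log2 ratio** `log2(SNL / sham)`, with an RPM floor (default
  0.5) applied only inside the ratio so one-sided zeros stay finite;
  the floor is never applied to the subtraction metric.

For reporting, the signed fold change (`SNL/sham` if up,
`−(sham/SNL)` if down) is also computed, so down-regulation reads as a
negative fold rather than a positive fraction. All three metrics agree
in sign. Rather than printing one metric for some elements and the
other metric for others, every output row carries both.

`snlRegTest()` tests the per-element null of no SNL/sham difference
with a Welch two-sample t-test on the per-pool values (log2-transformed
pool values when the log2 metric is selected), then applies
Benjamini–Hochberg correction across elements. The original analysis
used a one-tailed test without stating the direction; with no
pre-specified direction per element, a one-tailed test whose direction
is chosen from the observed sign is exactly a two-sided test at twice
the level, and our null simulations place its size near 0.10 rather
than 0.05. The package therefore defaults to the calibrated two-sided
p-value and reports the observed-direction one-tailed p alongside
(`alternative = "observed"` swaps which one drives the q-values).

### diff-reg

`diffRegPairwise()` implements the pairwise-estimate construction: for
each element and line, SNL-reg is evaluated for **every** SNL x sham
pool pair — 3 x 3 = 9 estimates per line at the default design — and
*diff-reg* is the difference of the two line means (first line minus
second). The two estimate sets are compared with a two-tailed Welch
t-test (the unequal-variance form is the conservative default where the
original description says only "t-test"), BH-corrected across elements.
When within-group variance is zero the pairwise mean collapses exactly
to the direct group-mean formula, which is how the published worked
examples are reproduced digit for digit.

The construction has a statistical property users should know: the 9
estimates of a line share its 3 + 3 pools, so they are positively
correlated, while the t-test treats them as independent draws. The
variance of the mean of the 9 estimates is (sa² + sb²)/3 (sa, sb the
SNL and sham noise contributions), whereas the t-test's standard error
estimates (sa² + sb²)/12 on average — an understatement of about a
factor 4 in variance, i.e. null t-statistics roughly twice too large.
The parameter-recovery property tests compute the consequence on the
generator's conditions: sensitivity for true line-specific spike-ins is
high (>= 0.95 across seeds), but the realized false-discovery
proportion at q <= 0.05 is far above the nominal level (~0.7). The
package implements the published construction faithfully and documents
the behaviour rather than silently substituting a different test; the
permutation null below and the `sdHA`/`sdLA` columns give users the
raw material for more conservative calls.

### Permutation null

`diffRegPermutation()` pools the two estimate sets, re-splits them at
the original sizes uniformly at random, and compares the absolute
difference of means with the observed one. Sampled p-values use the
add-one correction `(1 + hits) / (nRuns + 1)`, so they are never zero
at finite run counts; `exact = TRUE` enumerates all distinct splits
(the 9 + 9 default gives choose(18, 9) = 48620 splits, well within
reach), and the test suite verifies the sampler against exhaustive
enumeration. The default run count is 10^5, configurable upward; the
re-splitting acts on the pairwise estimates (the construction the
estimates define), which shares their correlation caveat.

### Multiple testing

`bhFdr()` returns BH step-up q-values (via `p.adjust`, with
monotonicity by construction) plus the *FDR limit* — the largest
ordered p with `p_(i) <= i * alpha / m` — so the original rejection
phrasing "uncorrected p <= FDR limit" can be reproduced exactly. The
test suite checks the q-values against a brute-force step-up oracle on
an exhaustive grid of short p-value lists.

### Baseline comparison

`baselineCompare()` contrasts the two lines' sham pools (fold ratio of
means, two-tailed Welch test, BH), the control analysis establishing
that constitutive expression differences between the lines are rare.

## The synthetic-data generator

The original sequencing data are not deposited, so `generateCounts()`
supplies matrices with the statistical structure the analysis assumes,
plus the ground truth needed for parameter-recovery tests. Defaults
were chosen once, from the published summaries, and define the
conditions under which the test suite runs:

* **Abundance law**: log-normal relative abundances (sdlog 2),
  matching the heavy right skew over ~5 decades of the observed RPM
  distribution (6 to ~140,000); rescaled so each group's expected pool
  total is `totalReads`.
* **Depth**: `totalReads = 10^6` per pool, a scaled-down stand-in for
  the ~12.3 x 10^6 reads of the real pools that conveniently makes
  counts ~ RPM; tests that need full realism can raise it.
* **Replicate noise**: negative binomial, parameterized by a target
  total CV (default 0.2, the observed across-group average), with
  Poisson noise as the floor for rare elements; `cv = NULL` gives pure
  Poisson, `cv = 0` noise-free rounding.
* **Line baseline**: a per-element log-normal factor (sdlog 0.1)
  between the lines — individually undetectable at n = 3 (consistent
  with the near-identical observed baselines) but collectively enough
  to give the lines the coherent identity the QC clustering premise
  requires.
* **Shared injury effects**: 25% of elements get a log-normal
  (sdlog 0.5) injury fold applied equally in both lines, emulating the
  sizeable nominal-but-non-differential regulation the screen observed;
  these are invisible to diff-reg by construction.
* **Spike-ins (the diff-reg ground truth)**: 5% of elements receive a
  line-specific injury fold, drawn from 1.5–3x (up or down), placed on
  elements with true RPM >= 1000 by default.
* **Outlier pool** (optional): a random 30% of elements in one pool
  are multiplied by i.i.d. factors from `[1/f, f]` (default f = 3),
  reproducing a compositional distortion without modelling its cause.
* **Sequences**: `simulateSequences()` draws unique random RNA with
  the tri-modal length profile of DRG small RNAs (17–18, 21–23,
  32–34 nt); `emitFastq()` turns a count matrix into per-pool raw
  reads (insert + adapter, optional NTA / adapter-corruption rates),
  which is how the editing stage is tested end to end — at zero
  corruption the round trip reproduces the source matrix exactly.

What the generator does **not** emulate: sequencing errors beyond
adapter corruption, genome coordinates and strandedness, correlated
biological noise across elements, batch structure, and isomiR families
derived from shared precursors. Tests passing on this generator
therefore validate the pipeline's arithmetic and its statistical
calibration under clean assumptions — they do not certify performance
on real libraries.

## Numerical and reproducibility choices

* All randomness flows from explicit seeds; the same configuration and
  seed give bit-identical matrices, reads and permutation p-values.
* Degenerate t-tests (zero variance in both groups) report p = 1 when
  the means tie and p = 0 otherwise, instead of erroring.
* Elements with all-zero means in a comparison are reported as `NA`
  and excluded from BH (which then uses the reduced m).
* Pairwise diff-reg pairs whose subtraction denominator is zero are
  dropped; an element needs >= 2 valid pairs per line to be tested.
* Exact permutation comparisons use a relative tolerance of 1e-12 when
  counting splits at least as extreme as observed.
* The test suite runs the heavier property checks at deliberately
  modest problem sizes — 200 elements x 20 seeds for parameter
  recovery, 100 seeded runs for each QC rate, 500-element defaults
  elsewhere — sizes at which the Monte-Carlo bands in the assertions
  are meaningful.

## Known limitations

* The diff-reg t-test inherits the anticonservatism of the pairwise
  construction (discussed above); treat its q-values as a ranking and
  lean on effect sizes and the permutation output for calibrated
  claims.
* The outlier flag cannot be simultaneously sensitive and specific at
  3 replicates per group (the knife-edge discussed above); it is
  advisory by design.
* Within-library normalization requires a complete library assignment;
  unassigned sequences are only supported in reads-level mode.
* The novel-candidate stage covers the threshold filters only; genome
  alignment, hairpin folding and classifier scoring are upstream of
  this package.
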