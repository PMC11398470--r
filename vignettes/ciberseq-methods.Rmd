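---
title: "Models and methods behind ciberseq"
author: "ciberseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ciberseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciberseq)
```

## The assay and what the package computes

A dual-barcoded CRISPRi expression-reporter screen links every dual-sgRNA
construct in a genome-wide library to a pair of random 25-nt barcodes, one
embedded in each of two reporter transcripts: a pathway reporter read in
the "red" (mCherry-linked) channel and a constitutive control read in the
"ir" (iRFP-linked) channel. The phenotype of a knockdown is read out as
the abundance of its expressed barcodes in RNA sequencing — the red:ir
ratio isolates reporter-specific regulation from cell-intrinsic effects.
Each construct carries several independently barcoded plasmid isolates
(about 8 on average), giving internal replication per guide.

`ciberseq` implements the complete computational side of such screens:

1. **Lookup construction** (`parseLongReads()`, `buildLookup()`): long
   reads of the linearized plasmid pool are parsed into
   (bc_red, bc_ir, guide cassette) triples; exact barcode pairs are
   grouped and majority-voted into a lookup table.
2. **Tag extraction** (`extractTags()`): amplicon reads yield a UMI (the
   first bases, added at reverse transcription) and a barcode located
   against a constant anchor.
3. **Molecule counting** (`countMolecules()`): directional error-network
   collapse of barcodes, then UMI deduplication.
4. **Tabulation** (`tabulateCounts()`, `filterLowAbundance()`,
   `matchToConstructs()`, `aggregateByConstruct()`): the barcode-by-library
   molecule count matrix, the mean-count filter, barcode-to-construct
   annotation and per-construct sums.
5. **Differential testing** (`screenContrast()`, `nbWaldTest()`,
   `estimateBaseline()`): negative-binomial Wald tests of condition and
   channel contrasts, with optional control-screen normalization.
6. **Simulation** (`simConfig()`, `simulateLibrary()`,
   `simulateScreen()`): a generative model with recorded ground truth, so
   every stage above is testable end to end without external data.

## Read parsing and the lookup table

Anchors are located by exhaustive substring scan under Hamming distance
(leftmost-best, ties to the smaller offset), trying the forward strand
first, then the reverse complement. Indel alignment is deliberately
omitted: the mismatch budget (default 2 per anchor) is meant for
substitution errors, and a substitution-only scan is simple enough to be
checked against a brute-force oracle position by position. Reads with `N`
inside an extracted element are rejected as ambiguous rather than
wildcard-matched.

`buildLookup()` groups parsed reads by *exact* 25-mer barcode-pair
identity. Barcode reads containing errors form spurious singleton pairs
and are expected to fail the support threshold (default `minSupport = 3`)
rather than be corrected — in a random 25-nt space, near-collisions
between true barcodes are vanishingly rare, so correction would buy
nothing and risk linking errors to the wrong construct.

The guide cassette is treated differently, because here errors hurt in
the opposite direction: a read with a single substitution inside the
~40-nt cassette produces a *distinct minority key* for a perfectly good
barcode pair. Left alone, the majority fraction ("purity") of every pair
converges to the probability that a read's cassette is error-free, and a
purity threshold of 0.9 would discard essentially the whole library at
realistic long-read error rates. We therefore collapse observed guide
keys over their *global* read counts with the same directional rule used
for barcodes (below), with tolerance `guideKeyDist = 3`: a true key
recurs across all of a construct's barcode pairs, an error key is almost
surely a global singleton, and different constructs' cassettes differ at
many positions. Purity then measures what it should: genuine mixtures of
unrelated cassettes (chimeras), which still fail `minPurity` (default
0.9). Any barcode string appearing in more than one surviving link is a
collision and removes every link involving it. This is vote aggregation
over an error network, not read polishing — no consensus sequence is ever
constructed.

## Directional collapse and UMI deduplication

"Highly similar" barcodes are operationalized the way UMI error networks
are usually built: a directed edge $a \to b$ exists when
$\mathrm{Hamming}(a,b) \le d$ (default $d = 1$) and
$\mathrm{reads}(a) \ge 2\,\mathrm{reads}(b) - 1$, and every node is
absorbed into the root of its best absorber (highest count, then
lexicographically smallest), processing nodes in decreasing-count order.
The count criterion encodes the generative asymmetry: an error variant of
an abundant sequence is rare relative to its source, while two genuinely
distinct sequences of comparable abundance stay separate. Neighbour
candidates come from exact-match buckets over $d+1$ disjoint segments of
the sequence (pigeonhole: two sequences within distance $d$ agree on at
least one segment), so the result provably equals the all-pairs
construction at near-linear cost; the test suite checks that equality on
hundreds of random instances against an independent $O(n^2)$ oracle.

UMI deduplication applies the same rule to the UMIs of each canonical
barcode after merging absorbed barcodes' UMI tables; the molecule count
is the number of canonical UMIs. Reads are conserved exactly through
collapse, and per barcode
molecules $\le$ distinct UMIs $\le$ reads.

## Count matrix, filter, aggregation

The barcode-by-library matrix takes the union of barcodes over libraries
(zeros for absences). Barcodes with an arithmetic mean count below 32
across *all* columns — both channels, all samples — are discarded; a mean
of exactly 32 is kept (the rule discards strictly below the threshold).
The filter applies to deduplicated molecule counts, which is the matrix
the downstream model sees; it runs before matching and aggregation, and
it is idempotent. Counts removed by the filter, and counts of barcodes
absent from the lookup, are tracked per library so that a conservation
ledger can assert exactly:

  raw column sums = construct sums + filtered + unmatched.

Construct-level counts are exact integer sums over member barcodes per
channel, with the contributing barcode number recorded.

## The negative-binomial model

Molecule counts are modelled as
$K_{ij} \sim \mathrm{NB}(\mu_{ij},\ \alpha_i)$ with variance
$\mu_{ij} + \alpha_i \mu_{ij}^2$ and
$\log \mu_{ij} = o_{ij} + x_j^\top \beta_i$, where $o_{ij}$ contains the
log size factor of library $j$ (median-of-ratios over features positive
in every library, rescaled to geometric mean 1) plus any baseline offset
(below). Coefficients are fit per feature by IRLS with fixed dispersion;
the reported effect is a single coefficient or contrast
$c^\top\beta / \log 2$ (a log2 fold change), with Wald
$z = \mathrm{log2FC}/\mathrm{SE}$ and a two-sided normal p-value.
P-values are adjusted by Benjamini–Hochberg step-up; a feature is
*significant* at `padj < alpha` (default 0.01) and a *hit* if also
`|log2FC| > lfcThreshold` (default 1.5, strict). Features with all-zero
counts or a non-converged fit get `NA` statistics; their displayed
log2FC comes from a least-squares fit on `log2(normalized + 0.5)` — the
pseudo-count is used for reporting only, never for testing.

### Dispersion estimation

With 2–3 replicates per condition a per-feature dispersion estimate is
extremely noisy, so estimates are stabilized across features:

* **Per feature**: method of moments on normalized counts,
  $\hat\alpha_i = (s_i^2 - \bar\mu_i)/\bar\mu_i^2$, with the variance
  pooled within design cells (column groups sharing an expected mean).
* **Trend**: a power law $\alpha(\mu) = a_0\,\mu^{a_1}$. The exponent is
  fit by least squares of $\log\hat\alpha$ on $\log\bar\mu$ over features
  with positive estimates; because truncation at zero biases that
  regression's level, the scale $a_0$ is re-calibrated by moment
  matching so that the mean of the trend equals the mean of the *raw*
  (untruncated, possibly negative) estimates. This keeps the trend
  essentially unbiased: for Poisson data it collapses to ~0, and in
  simulations with known $\alpha$ it recovers the true value across the
  mean range.
* **Shrinkage**: the final dispersion is
  $\exp\{w \log \mathrm{trend} + (1-w)\log \max(\hat\alpha_i,
  \mathrm{trend})\}$ with $w = 0.5$. Estimates *below* the trend are
  raised to it before combining: at screen-scale replication a
  below-trend estimate is far better explained by sampling noise than by
  genuinely low dispersion, and testing a feature at an under-estimated
  dispersion inflates its Wald statistic — in a 40,000-feature null
  screen, even a modest fraction of such features produces spurious
  BH discoveries. With the trend floor, the per-barcode null screen is
  calibrated (empirical sd of $z$ ≈ 0.98, near-uniform p-values) and the
  global-null BH guarantee (no discovery with probability ~0.99) holds.
  Features above the trend keep (part of) their own estimate, which is
  the conservative direction.

This is a deliberately simplified relative of the DESeq2 workflow: no
Cox–Reid adjustment, no posterior (MAP) shrinkage, no independent
filtering, no count-outlier replacement. `aggregateByConstruct()` output
can be exported to a TSV that DESeq2 ingests directly, for external
cross-checking; the package's own tests compare the IRLS fits against
fixed-dispersion GLM references instead.

### Contrasts and pairing

Three contrasts cover the screen designs:

* `condition_effect` — A vs B within one channel, design
  `~ replicate + condition` (replicates absorb batch shifts).
* `channel_ratio` — red vs ir within a condition, on a pair-level matrix
  (one row per construct or barcode pair, red columns carrying the red
  member's counts), design `~ sample_id + channel`: the sample factor
  absorbs the pairing, so the channel coefficient is a within-sample
  ratio estimated with count-level uncertainty. A per-pair ratio-of-
  normalized-counts t-test would discard that uncertainty structure,
  which is why it was rejected.
* `interaction` — the change of the red:ir ratio between conditions,
  via an explicit red-in-condition-A indicator on top of
  `~ sample_id + channel` (the factor-coded interaction is collinear
  with the sample effects).

A single barcode exists in exactly one channel, so channel contrasts are
defined only at pair/construct level.

### Baseline normalization

In a control screen both reporters are driven by identical constitutive
promoters, so each pair's log2 red:ir ratio $\beta_0$ is pure
barcode-intrinsic bias (observed up to ~8-fold). `estimateBaseline()`
estimates $\beta_0$ per pair (or construct) from such a screen;
`screenContrast(..., baseline = )` then adds $\beta_0 \log 2$ to the
red-channel offsets, treating it as known. Its SE is reported but not
propagated into the downstream test — a documented limitation,
acceptable because the control screen is typically much deeper than the
bias it measures. Whether such normalization should enter as an offset
or as a covariate is genuinely open; the offset was chosen because it
keeps the feature's design full-rank at any replication and makes
"normalize to the control screen" exactly reproducible from a single
table.

## The simulator

`simulateScreen()` is molecule-first: construct abundance is log-normal
(`abundance_sdlog` 0.5), barcode-pair share within a construct is
symmetric Dirichlet, expected molecules are `depth * share`, the red
channel is scaled by $2^{\mathrm{effect} + \beta_0}$, and molecule
counts are NB with the configured dispersion. Only then is each molecule
given a UMI, PCR-duplicated (geometric, duplicates share the UMI), and
each read given i.i.d. substitution errors — so the pre-error molecule
table is the exact dedup truth. Two representational choices matter:

* UMIs are drawn from a parity-check code (last base = sum of the others
  mod 4), giving any two distinct molecules' UMIs Hamming distance ≥ 2.
  Without this, two genuinely distinct molecules occasionally sit at
  distance 1 and the directional rule merges them, making "exact
  recovery" an ill-posed target. The code costs 2 bits of UMI diversity
  and does not interact with error absorption (an error variant is still
  distance 1 from its source).
* Barcodes are rejection-sampled to global uniqueness; with 25-nt random
  barcodes no minimum-distance construction is needed.

Defaults mirror the screen the package models: 2,000 constructs at desk
scale (the full library is 21,554), 100 non-targeting controls (989 at
full scale), 8 barcode pairs per construct on average (zero-truncated
Poisson), NB dispersion 0.05, PCR duplication rate 0.5, substitution
error 0.5%, long-read error 1%, per-pair baseline bias SD 0.35. The
dispersion and duplication rate are stated assumptions — the source
screens publish no estimates — and are configurable.

What the simulator does *not* emulate: indels and quality-score
structure, index hopping, strand- or position-dependent error profiles,
cell-level effects (infection multiplicity, selection bottlenecks,
knockdown heterogeneity), and any correlation between barcode sequence
and expression other than the planted baseline bias. Passing tests on
simulated data therefore demonstrate the *computational* correctness of
the pipeline under its stated generative model, not robustness to every
artifact of real libraries.

## Problem sizes and study conditions used in the tests

The validation suite runs, among others:

* a null screen of ~20,800 barcode pairs (2,600 constructs), 2
  conditions × 3 replicates, dispersion 0.05, baseline bias SD 0.35 —
  expecting zero BH discoveries at `padj < 0.01` across ~19,000 tested
  barcodes, the in-silico analogue of a dual-constitutive control screen
  in which none of 167,916 barcodes moved;
* planted-effect screens: 100 of 2,000 constructs at log2FC −2 on the
  red channel, 3 replicates, at a coverage of ~500 molecules per barcode
  per library (the source screens maintain >500× coverage per barcode),
  expecting ≥95% of planted constructs called as hits and zero false
  hits over five seeds. At several-fold lower coverage the mean<32
  abundance filter starts deleting entire knocked-down constructs (their
  red barcodes drop four-fold), which is a coverage shortfall of the
  scenario rather than a property of the test;
* lookup reconstruction from 1,000 constructs × 5 error-free long reads
  (exact set equality with truth) and at 1% error (no mis-assignment,
  ≥99% construct recovery);
* collapse/dedup equality with a brute-force directional oracle on 500
  random instances of up to 200 sequences.

These scales keep the statistical behaviour of the full-size screen
(tens of thousands of tests, the same thresholds) while the heavy
string-level stages are exercised end-to-end at sizes where FASTQ
round-trips take seconds; the equivalence of the count-level and
FASTQ-level entries is itself asserted exactly (zero-error identity) and
approximately (≥99% recovery at 0.5% error with zero mis-assignment).

## Numerical details and degenerate inputs

* IRLS: initialized from log counts with a 0.5 pseudo-count, linear
  predictor clamped to ±30, convergence at max |Δβ| < 1e−8, 100
  iteration cap; non-convergence flags the feature (`NA` p).
* Size factors: error if no feature is positive everywhere, with an
  explicit `pseudoReference = TRUE` fallback (0.5 pseudo-count
  reference) that the caller must opt into.
* Dispersion: fewer than 10 positive per-feature estimates falls back to
  the global median, with a warning; `alphaFloor = 1e-8` bounds all
  dispersions away from zero.
* Ties in the directional network are broken by higher count, then
  lexicographically smaller sequence; anchor-scan ties by the leftmost
  offset — all deterministic, so re-runs are byte-identical.
* Empty inputs: an empty parsed-read stream yields an empty lookup (not
  an error); an empty UMI table yields molecule count 0; an empty
  control screen is an error.

## Known limitations

* The Wald test with trend-floored moment dispersions is mildly
  conservative for features whose true dispersion is below the trend,
  and, like any normal-approximation test at 3 replicates, its extreme
  tail (|z| > 5) is only approximately calibrated; at tens of thousands
  of tests the global-null BH guarantee is the ~99%-probability
  statement above, not a certainty.
* Baseline SEs are not propagated (offset treated as known).
* Long-read parsing assumes substitution-dominated errors; libraries
  sequenced with indel-prone chemistries would need an alignment-based
  parser, which is out of scope.
* The collapse method implements the directional rule only; cluster or
  adjacency variants are not provided (the `method` argument is an enum
  left extensible on purpose).
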