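---
title: "Methods: scoring pooled Bar-seq lifespan and growth screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring pooled Bar-seq lifespan and growth screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barseqls)
```

## The measurement model

A barcoded deletion library is aged (or grown) as a single pool, and each
mutant's relative abundance is tracked by sequencing the two strain-specific
20-bp barcodes (the *uptag* and *downtag*) that flank its deletion cassette.
Because every sample is a snapshot of pool *composition*, the quantity a
sample measures for mutant $g$ is a proportion, not an absolute viability:
mutants dying faster than the pool average become depleted, mutants dying
slower become enriched.

For tag $k \in \{\mathrm{up}, \mathrm{dn}\}$ of gene $g$ in sample $i$, with
raw read count $c_{gki}$ and sample depth
$d_i = \sum_{g,k} c_{gki}$ (matched reads), the depth-normalized
fold-change against the replicate's reference sample $0$ is

$$\mathrm{fc}_{gki} = \frac{c_{gki}/d_i}{c_{gk0}/d_0}.$$

The reference is the first timepoint of each time course: the start of
quiescence ($t = 0$ weeks) for the chronological-lifespan (CLS) screen, and
the 120-minute sample for the growth screen.

The two tags are then combined into a single per-gene fold-change by a
read-weighted mean. The uptag's weight at timepoint $i$ is its share of the
gene's reads at timepoints $i$ and $0$ combined,

$$w_{\mathrm{up}} = \frac{\mathrm{Up}_i + \mathrm{Up}_0}
  {\mathrm{Up}_i + \mathrm{Dn}_i + \mathrm{Up}_0 + \mathrm{Dn}_0},
  \qquad w_{\mathrm{dn}} = 1 - w_{\mathrm{up}},$$

$$\mathrm{fc}_{gi} = w_{\mathrm{up}}\,\mathrm{fc}_{g,\mathrm{up},i}
  + w_{\mathrm{dn}}\,\mathrm{fc}_{g,\mathrm{dn},i}.$$

This down-weights the noisier tag: the tag with fewer reads contributes
proportionally less. The combination is convex, so the combined value always
lies between the two tag fold-changes.

The **lifespan score** (and identically the **growth score**) of a gene is

$$S_g = \operatorname*{mean}_{\text{replicates } r}\;
        \operatorname*{median}_{\text{non-reference timepoints } i}\;
        \mathrm{fc}_{gi}^{(r)}.$$

A mutant behaving exactly like the pool average has $S_g = 1$ at every
depth. Calls use strict thresholds on the score: long-lived when
$S_g > 1.44$, short-lived/sick flag when $S_g < 0.14$.

### Filtering

Tag-timepoints with fewer than `min_reads = 10` raw reads are excluded, and
this floor is applied to the reference timepoint too: a ratio against an
unreliably measured (or zero) denominator is meaningless. A gene-timepoint
remains usable when at least one tag survives the floor — necessary because
a substantial minority of genes have only one decoded tag — and the
surviving tag then takes weight 1. A replicate contributes to the score when
it has at least `min_valid_timepoints = 1` valid non-reference timepoint;
genes scorable in a single replicate are scored from it and flagged
`single_replicate`. Genes with no valid replicate are `not_scored`. Every
parameter sits in `scoring_config()`.

Two readings of the replicate/median order are possible (pool both
replicates' timepoints into one median, or median per replicate then
average). We take the median per replicate and then average, following the
order in which the procedure is stated; with two replicates and four aged
timepoints the difference is small and has no effect on rank-based
downstream use.

### Raw versus normalized weights

The tag-weighting formula is stated on raw read counts, and that is the
default (`weight_mode = "raw"`). Raw-count weights mix counts from two
samples, so they are *not* exactly invariant when a single sample's counts
are rescaled (e.g. by resequencing the same library deeper); the
fold-changes themselves are invariant because they are depth-normalized.
`weight_mode = "normalized"` applies the same formula to depth-normalized
counts, which restores exact per-sample rescaling invariance. The package's
invariance tests use the normalized mode; the default remains the raw form
for fidelity to the established procedure. In practice the two agree
closely whenever sample depths are within a few-fold of each other.

## The barcode reference database and read matching

Counting runs are 50-cycle single-end reads over a PCR amplicon with fixed
anatomy. The reference database expands every decoded tag against the
multiplex index set into one 51-nt entry per index:

    4 nt multiplex index | 18 nt universal primer | 20 nt tag | 9 nt universal primer

A read is assigned to the entry whose first 42 nt (index + primer + tag —
the discriminating region; the trailing primer is constant and incompletely
covered) lie within Hamming distance 1 of the read's first 42 nt.
Mismatches beyond position 42 are ignored. Only unique assignments are
counted:

* exactly one entry at the minimum distance → assigned (a distance-0 hit
  beats distance-1 hits — best-unique semantics, the standard best-hit
  behavior of short-read aligners);
* two or more entries at the minimum distance → ambiguous, discarded;
* no entry within distance 1 → unmatched.

Reads shorter than 42 nt are flagged and counted as unmatched. Identical
entry sequences (possible with degenerate tags) are retained and flagged;
any read hitting them is necessarily ambiguous. Since the multiplex index
lies inside the matched 42 nt, demultiplexing is implicit; there is no
separate index-mismatch rule. The model is substitution-only (no indels),
matching 1-mismatch ungapped alignment. The implementation indexes the two
21-nt halves of every entry (a read within distance 1 must match at least
one half exactly) and verifies candidates; the test suite proves it
equivalent to an exhaustive Hamming scan.

## Barcode decoding

Decode runs are 101-cycle reads segmented at fixed offsets into 4-nt index,
18-nt primer, 20-nt barcode, 26-nt spacer and 33-nt flanking genomic
sequence. Reads are grouped by *exact* barcode — no merging of near-identical
barcodes, since a 1-mismatch merge would also merge genuinely distinct tags;
sequencing-error singletons are instead removed by a minimum cluster size
(`min_cluster = 2`). Each cluster's flank consensus (per-position majority,
alphabetical tie-break for determinism) is compared with the expected flanks;
the cluster is assigned to the unique nearest (gene, tag kind) when that
distance is at most `d_max = 3` and the runner-up is strictly farther. The
threshold tolerates one to three errors in 33 nt while keeping the chance of
crossing to another gene's flank negligible; no criterion is inherited from
prior work, so both knobs are exposed as parameters rather than constants.
Conflicting decodes (two barcodes assigned to one gene/tag) are kept and
flagged rather than silently resolved.

## Viability curves and median lifespan

Colony-forming-unit counts are converted to plating efficiency relative to
the reference timepoint (reference = 100%; values above 100% are legitimate
for pools, where nutrients released by dead cells can allow transient
regrowth). Median chronological lifespan is estimated by an order-2
polynomial least-squares fit of viability against time — pooling replicate
points rather than averaging curves, so replicate scatter propagates into
the fit — and is defined as the smallest root of $\hat v(t) = 50$ inside
the observed time range (the first downward crossing of 50%). If the fitted
curve never reaches 50% in range, the estimate is refused rather than
extrapolated. The estimate rescales exactly with the time unit.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_trajectories()` generate a ground-truthed pool:

* **Design**: 1000 mutants, two biological replicates, five timepoints
  (0/4/8/12/14 weeks for CLS, 120/230/340/460/550 minutes for growth),
  $10^6$ matched reads per sample. These mirror the screen design this
  package targets; tests and the acceptance analyses use these sizes (with
  smaller pools for sequence-level round trips, 200–500 genes at
  $2\times10^5$ reads, purely to keep runtimes in seconds).
* **Tag presence**: both/up-only/dn-only mix 1871:254:348, the observed
  decode yields of the library generation this package models.
* **Initial abundance**: log-normal with `sdlog = 0.5` — a robotically
  pooled library with roughly two-fold colony-to-colony variation. The
  *real* library is much more dispersed (a quarter of mutants fall below
  single-read detection at typical depths, reflecting strain loss and
  decode failure); that deep tail is deliberately not modeled, because it
  mostly removes genes from the analysis rather than changing the scores of
  analyzable genes.
* **Survival**: per-gene weekly survival $s_g$, bulk $\mathrm{Beta}(8,2)$
  plus a 5% long-lived fraction with $s_g = 1$; pool proportions are
  $p_g(t) \propto p_g(0)\, s_g^t$, renormalized each timepoint — survival
  acts multiplicatively and Bar-seq sees only the renormalized composition.
  Growth mode replaces $s_g^t$ by $2^{a_g t}$ with
  $a_g \sim N(0, 8\times10^{-4})$ doublings/minute, i.e. mutants differ by
  up to roughly ±1 doubling over the 430-minute course.
* **Reads**: multinomial sampling at fixed depth (gene proportion × a
  per-gene Beta(20,20) up:dn split to exercise the weighting), then
  sequence-level read emission with iid per-base substitution error
  (default 0.001, the right order for modern short-read platforms).

All randomness flows from one integer seed; every artifact is bit-for-bit
reproducible. Not modeled: PCR duplicates/jackpots, medium replacement and
nutrient recycling, regrowth-on-plate bias, oligo-synthesis errors in the
barcodes, indels. Consequently, a passing simulation validates the
*statistical machinery* — normalization, weighting, filtering, scoring,
matching, decoding — not the wet-lab robustness of the assay.

Two calibration notes, measured under exactly these defaults (seeded, in
`tests/testthat/test-acceptance.R`): in a zero-death pool the maximum
per-gene score deviation from 1 is ≈0.14 (99% of genes are within 0.08) —
the extreme is the lowest-abundance gene at ≈3.6σ of its own multinomial
noise — and the long-lived calls recover the entire top survival decile
while also including high-but-mortal survivors, ≈25% of the pool. Both are
properties of the chosen abundance spread and survival mixture, not of the
scoring code.

## Numerical and degenerate-input choices

* Hamming comparisons treat `N` as mismatching everything, including `N`:
  an uncalled base never supports a match.
* Threshold calls use strict inequalities (a score of exactly 1.44 is not
  long-lived).
* Deterministic orderings throughout: database entries by (gene, tag kind,
  index position); score tables by descending score; consensus ties
  alphabetically.
* Empty inputs: empty FASTQ warns and yields zero counts; a sample with no
  matched reads is kept with depth 0 and flagged; an empty tag table or
  index set refuses to build a database; a missing reference sample is an
  error, not a silent skip.
* Pearson p-values come from the usual $t$ approximation with $n-2$ df
  (`stats::cor.test`); enrichment is the one-sided hypergeometric upper
  tail (`stats::phyper`).

## Known limitations

* Substitution-only matching cannot rescue reads with indels near the tag.
* Exact-barcode clustering undercounts reads for tags whose errors recur
  (deep clusters shed ~18% of reads to singletons at 1% error); this
  affects decode sensitivity, not counting-run quantification.
* Scores are ratios of proportions: a uniformly dying pool (all $s_g$
  equal) yields scores of 1 for everyone — the method measures *relative*
  lifespan only, by construction.
* With raw-count weights, extreme depth imbalance between samples shifts
  tag weights slightly (see above); use the normalized mode when comparing
  runs of very different depth.
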