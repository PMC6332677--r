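---
title: "Rank-based gene-pair signatures: methods and design notes"
author: "reosig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
```

## The statistic: relative expression orderings

For two genes $A$ and $B$ measured in the same sample, the relative
expression ordering (REO) is the event $A > B$.  REOs use no between-sample
information, so they are unchanged by any strictly increasing per-sample
transformation — log transforms, positive rescaling, additive batch shifts,
monotone normalisation curves.  That is the property that makes REO-based
signatures portable across microarray platforms and laboratories where
absolute intensities are not comparable, and it is the property this
package's invariance tests assert literally (bit-identical stable-pair
sets, concordance scores and predictions before and after distortion).

**Stable pairs.** In a dataset with $n$ samples, the ordered pair $(A, B)$
is a *stable REO pair* when

$$\frac{\#\{\text{samples with } A > B\}}{n} > t,$$

with $t = 0.95$ by default.  Both inequalities are strict: a tie in
expression counts as "not higher" (so ties can never create reciprocal
stability), and support exactly equal to $t$ fails — 19 of 20 samples is
support $0.95$, which is *not more than* $0.95$.  For $t > 0.5$ at most one
direction of a pair can be stable.  For $G$ genes there are $G(G-1)/2$
unordered pairs, so `detect_stable_pairs()` streams over gene blocks
(`block_size` caps the per-block counter allocation) with a compiled
counting kernel; results are contractually bit-identical to the naive
all-pairs loop, which the tests enforce against an independent R oracle up
to 200 genes.

**Characteristic pairs.** The characteristic set of a tumour class is the
intersection of its datasets' stable sets with *matching direction*; a
direction conflict removes the pair.

## Concordance and its null

Two stable-pair lists that overlap in $k$ unordered pairs, $s$ of them with
the same direction, have concordance score $s/k \times 100\%$.  Under the
null that directions agree by chance with probability $P_e$ (default 0.5),
the probability of observing at least $s$ agreements is the upper binomial
tail

$$P = P(X \ge s) = 1 - \sum_{i=0}^{s-1} \binom{k}{i} P_e^{\,i}
(1-P_e)^{\,k-i}, \qquad X \sim \mathrm{Binomial}(k, P_e).$$

`binomial_tail()` evaluates this through the regularized incomplete beta
function (via `pbinom`), which remains accurate for $k$ in the hundreds of
millions — overlap counts of that magnitude arise when whole-genome pair
sets are compared.  Tails far below double precision are available in log
space; the print method floors the display at `< 2.2e-16` but the stored
value is exact in log space.  A subtlety worth recording: the textbook form
of this tail carries the exponent $k-i$ on $(1-P_e)$; one sometimes sees it
misprinted with a constant exponent, which is not a valid probability mass
function, and this package implements the standard form only.  At $s = 0$
the sum is empty and the tail is exactly 1.  When two lists share no pairs
($k = 0$) the score is undefined; the result is flagged rather than
invented, with $P = 1$.

`per_sample_concordance()` applies the same counting to a single sample
against a reference direction set: the percent of evaluable reference pairs
realized in that sample, ties discordant, pairs with absent genes excluded
from the denominator and counted separately.  This is the per-metastasis
statistic used to ask whether metastases retain the orderings of their
tissue of origin.

## Signature selection

Given the two classes' characteristic sets, `find_reversed_pairs()` keeps
the pairs stable in opposite directions — the only pairs that carry
between-class information.  Candidates are then ordered by two scores:

1. **Gene appearance frequency** in the reversed set, descending.  A gene
   recurring in many reversed pairs is a strong, redundant marker of the
   class difference.
2. **Average within-sample rank difference** for a pair $(i, j)$:
   $$\Delta \overline{R}_{ij} = \frac{\sum_{n=1}^{N_1} |R_{n,i} - R_{n,j}|
   + \sum_{m=1}^{N_2} |R_{m,i} - R_{m,j}|}{N_1 + N_2},$$
   where $R_{n,i}$ is gene $i$'s rank within training profile $n$ (ranks
   ascending, 1 = lowest, ties averaged; the direction convention is
   irrelevant because only absolute differences enter).  A pair far apart
   in every profile is robust to noise in either gene.

Walking down the frequency-ordered gene list, each gene contributes its
largest-$\Delta \overline{R}$ reversed pair not already contributed by an
earlier gene, so a shared partner introduces a new pair rather than a
duplicate; a gene whose pairs are exhausted contributes nothing.  All ties
(frequency, $\Delta \overline{R}$) break lexicographically on gene
identifiers: the selection is fully deterministic, which we consider part
of the method's contract.  Ranks are computed on the intersected gene
universe of the pooled training collections; universe intersection is an
explicit step (`intersect_gene_universe()`), never applied silently,
because it changes rank denominators.

`scan_odd_sizes()` evaluates the first $n = 1, 3, 5, \dots$ candidates as a
majority-vote classifier on the pooled training samples and reports percent
accuracy (pooled across classes, with per-class accuracies alongside).  The
chosen size is the smallest odd $n$ attaining the maximum scanned accuracy
— the start of the accuracy plateau.  On cleanly separable data this is
$n = 1$ by construction: a single perfect pair classifies every training
sample, and no larger signature can beat 100%.  Larger chosen sizes arise
only when individual pairs err on some training samples while the vote over
more pairs does not; with noise applied independently per gene this is a
narrow regime, so small chosen sizes on clean synthetic data are expected
behaviour, not a defect.

## Classification

A signature is an ordered list of directed pairs in the class-1 direction
plus two labels.  Each evaluable pair votes class 1 iff the sample's
`gene_high` value strictly exceeds its `gene_low` value; the sample is
assigned class 1 iff strictly more than half of the evaluated pairs so
vote.  With an odd evaluated count there are no ties; with an even count
(possible when signature genes are absent from a platform) an exact half
goes to class 2 under the strict rule.  Missing-gene pairs are skipped and
counted, shrinking the denominator — the permissive behaviour needed to
apply one signature across array platforms with different gene coverage —
and `strict = TRUE` refuses to classify instead.  `published_signature()`
ships the fixed five-pair colorectal-versus-lung signature (GUCY2C, CDH17,
FABP1, KRT20, USH1C, each paired above SLC34A2, a dominant lung marker);
because all five pairs share the same low gene, any sample in which
SLC34A2 is maximal receives zero class-1 votes.

## The synthetic-data generator

`generate_two_class()` emulates the structure the pipeline needs to be
tested against, with all randomness a deterministic function of the
configuration (seed included):

- Background gene means are uniform on a log2-like range (4–12), shared
  between classes; per-entry Gaussian noise with SD `noise_sd` (default
  0.4) is added to every value.  Most background orderings are therefore
  stable and identical in both classes.
- Each planted reversed pair occupies its own narrow stratum *above* the
  background range, the two genes at centre $\pm$ offset with the signs
  swapped between classes — the pattern of dominant tissue markers, which
  sit at the top of the expression distribution.  Keeping the strata
  disjoint from the background and from each other guarantees that the
  planted pairs are the *only* orderings that reverse between classes;
  when planted genes instead sit inside the background range, every
  background gene whose mean falls between the two swapped means also
  reverses, contaminating recovery.
- The offset is the larger of `rank_gap` (default 1, in expression units)
  and the normal-CDF calibration $\sigma\, z_{\text{stability}} / \sqrt2$,
  which makes the planted ordering hold in exactly the `stability`
  fraction of samples in expectation when the calibration binds
  (`rank_gap = 0`); the tests verify the calibration empirically at
  $n = 100$ samples per class.
- `batch_shift` adds a constant to the class-2 dataset (and subtracts it
  from metastasis samples); it must not, and does not, change any result.
- `generate_metastasis()` draws samples from the class-1 model on a
  separate seeded stream, then swaps the values of a fixed
  `metastasis_admixture` fraction of planted pairs (rounded to a whole
  count, chosen at random per sample), giving exact control of the
  per-sample concordance: admixture 0.2 with 5 planted pairs yields
  exactly 80%.

What the generator does **not** emulate: probe-level effects, saturation,
heavy-tailed or correlated noise, class-imbalanced composition drift, or
genuinely overlapping marker distributions.  Passing tests on this
generator therefore demonstrate the pipeline's correctness and its
invariances, not the attainable accuracy on real tumour cohorts, where
reversed-pair counts are orders of magnitude larger and signature sizes are
driven by residual training error.

## Problem sizes and numerical choices

The test-suite study conditions are 500 genes, 50 + 50 training samples,
5 planted pairs, and 100 generator seeds for the recovery experiment;
oracle-equivalence checks run on 50 random instances up to 200 genes × 50
samples.  At these sizes the whole pipeline runs in seconds per dataset;
the blocked pair scan with `block_size = 1024` allocates at most two
1024² integer counter blocks (~8 MB) regardless of gene count.
Degenerate inputs are handled explicitly: matrices need at least two genes
and one sample; non-finite values are rejected unless a flag asks for
gene-wise dropping (ordering counts have no missing-value semantics);
probes mapped to more than one gene are treated as ambiguous and dropped;
probe collapse defaults to keeping the highest-mean probe (`max_mean`),
which preserves within-sample orderings, rather than averaging log-scale
probe rows, which need not.

## Known limitations

- Two classes only; no multi-tissue panels and no probabilistic outputs.
- The artifact consumes already-normalised matrices; array preprocessing
  (e.g. RMA of raw CEL files) and GEO downloading are out of scope — the
  series-matrix reader accepts local files only.
- Gene identifiers are opaque case-sensitive strings; no alias resolution.
- At a stability threshold of 0.95, datasets with fewer than 20 samples
  make "more than 95%" equivalent to "all samples"; this is the intended
  strict reading, but users with tiny cohorts should choose thresholds
  with the sample count in mind.
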