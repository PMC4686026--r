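---
title: "Models and methods behind mthaplostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mthaplostat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthaplostat)
library(dplyr)
```

mthaplostat analyses mitochondrial haplotype data of the kind produced
by population surveys of a single locus: a fixed-width alignment of
maternally inherited sequences, a catalog of known haplotypes defined by
their states at the polymorphic alignment columns, and sample metadata
assigning each individual to a geographic population. This vignette
explains each statistical component, the conventions and tunable
parameters, what the synthetic data generator does and does not emulate,
and the design decisions taken where more than one convention exists in
the field.

## Haplotype catalogs and calling

A haplotype catalog stores only the polymorphic columns, in 1-based
alignment coordinates, one row per named haplotype. This mirrors how such
tables are published — full sequences are deposited in databases, while
papers print the variable sites — and it is sufficient: every statistic
in the package depends only on haplotype identities, their counts, and
their pairwise differences at these columns. The on-disk format follows
the printed convention: the first row is the reference haplotype with
explicit states, later rows use `.` (or the typographic `•`) for
same-as-reference, and `-` is a genuine gap state. `N` is allowed in
sample alignments but never in catalog rows, which are consensus
sequences.

Calling is exact matching: a sample is assigned a catalog haplotype when
its states at all catalog positions equal that profile. `N` matches
nothing — a sample with `N` at a diagnostic position is reported as
unresolvable rather than guessed, because the laboratory remedy
(re-sequencing) is outside the scope of any caller. Unmatched samples
sharing a state vector are minted one new name. The acceptance rule for
novel haplotypes is replication: seen twice or more, a new haplotype is
accepted; seen once, it is flagged `needs_verification`, reflecting the
practice of confirming singletons by re-sequencing before reporting
them. Minted names continue from the highest existing index under the
prefix (default `Z`), in first-seen sample order, so calling is
deterministic.

## Polymorphic sites and substitution classes

A column is polymorphic when at least two distinct non-`N` states occur.
Each polymorphic column gets exactly one class: `indel` if any sequence
carries a gap there; otherwise `transversion` if the observed states
include a purine–pyrimidine pair (A/G vs C/T); otherwise `transition`.
Two conventions exist for multi-column deletions; we count *per column*
(a two-column deletion is two indels), which matches the published
summary tables this package reproduces. For a column with more than two
base states the class is transversion as soon as any cross-class pair
occurs — in the packaged lion catalog no such column exists, so the
choice is unexercised on real profiles.

## Diversity indices

With per-haplotype counts $n_h$, $n = \sum n_h$, $p_h = n_h/n$:

* **Frequency s.d.**: $\sqrt{p_h(1-p_h)/(n-1)}$. The $n-1$ denominator
  (rather than $n$) is locked by a fixture test against published
  frequency tables; the two textbook variants differ in the third
  decimal at these sample sizes, and only $n-1$ reproduces the printed
  cells.
* **Gene diversity**: $\hat h = \frac{n}{n-1}(1 - \sum_h p_h^2)$, the
  unbiased probability that two individuals sampled without replacement
  differ in haplotype, with sampling variance
  $V = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p^3 - (\sum p^2)^2\right]
  + \sum p^2 - (\sum p^2)^2\right\}$.
  Both formulas were confirmed against the published point estimate and
  s.d. before being frozen into tests.
* **Nucleotide diversity**: the within-population mean pairwise
  difference (below) divided by the alignment width.

Pairwise distances between haplotypes come in two modes.
`pairwise_differences` counts columns with unequal states; gap-vs-base
counts one per column and gap-vs-gap zero, consistent with per-column
indel counting. `identity` is the 0/1 indicator of name inequality.
The within-population mean pairwise difference averages the distance over
all unordered sample pairs; under identity distances it equals unbiased
gene diversity exactly (an algebraic identity the test suite asserts to
1e-12 on random count vectors). Between populations,
$\pi_{XY} = \frac{1}{N_X N_Y}\sum_{i \in X}\sum_{j \in Y}\delta_{ij}$,
and Nei's corrected (net) distance is
$d = \pi_{XY} - (\pi_X + \pi_Y)/2$. The exact variant behind the
published distance figure is not stated there; the corrected average
pairwise difference is the standard choice in this analysis suite and is
adopted here. One boundary convention is worth making explicit: when the
two compositions are identical (a population against itself), the cross
term is computed excluding self-pairs, so that $d = 0$ exactly — the
naive formula would give $-\pi_X/N$, a small negative artifact of mixing
ordered cross pairs with unordered within pairs.

## One-level AMOVA

The decomposition uses distance entries directly as squared
inter-individual distances — the convention of the molecular-variance
framework, under which identity distances reproduce classic
haplotype-frequency F-statistics. With $\delta^2_{ij}$ the squared
distance and populations $p = 1..P$ of sizes $N_p$:

$$SSD_{total} = \frac{1}{2N}\sum_{i}\sum_{j}\delta^2_{ij},\qquad
SSD_{within} = \sum_p \frac{1}{2N_p}\sum_{i,j \in p}\delta^2_{ij},$$

$SSD_{among} = SSD_{total} - SSD_{within}$, $V_b = SSD_{within}/(N-P)$,
$n' = (N - \sum_p N_p^2/N)/(P-1)$,
$V_a = (SSD_{among}/(P-1) - V_b)/n'$, and $F_{st} = V_a/(V_a+V_b)$.
Negative $V_a$ (possible when populations are effectively identical) is
reported as computed, with a warning, never clamped — clamping would
break the additivity $SSD_{among} + SSD_{within} = SSD_{total}$ that the
tests assert. Internally everything is computed from
population-by-haplotype count cross-tabs, which is algebraically
identical to the per-individual double sum but makes each evaluation
$O(P H^2)$, so the permutation test is cheap.

The permutation test permutes individuals' population labels (sizes
fixed), the standard null for population differentiation, and reports
$p = (1 + \#\{F_{st}^* \ge F_{st}\})/(R+1)$ — the add-one form that
never returns an exact zero. $R$ defaults to 1000 in the pipeline. A
calibration test checks that under a true null the p-value is roughly
uniform.

Both distance modes are exposed because survey papers commonly use both
without saying so: identity distances for the headline between-region
analysis, nucleotide differences for among-area runs. Populations
contributing a single sample are excluded from among-area AMOVA (with a
warning naming them) since a lone sample carries no within-population
information and would skew the result; the pipeline skips a region
entirely when fewer than two areas have two or more samples.

## Median-joining networks

The network is built over haplotype profiles under Hamming distance with
the gap treated as a fifth character state. Iteratively:

1. Form the $\varepsilon$-relaxed minimum spanning network (MSN): an
   edge is kept iff its weight is within $\varepsilon$ of the *connection
   level* of its endpoints — the smallest distance level at which their
   components merge when levels are processed in ascending order.
   Connection levels are single-linkage cophenetic (minimax-path)
   distances, so $\varepsilon = 0$ yields the classic MSN: the union of
   all minimum spanning trees.
2. For every triplet with at least two of its three pairs linked,
   compute the per-column majority-consensus median (Steiner) vector.
   Triplets with a three-way disagreement at any column are skipped —
   the full quasi-median branching is not needed for two-state columns,
   the only kind this data contains. New vectors whose connection cost
   (sum of distances to the triplet) is within $\varepsilon$ of the
   minimum are added, in lexicographic order of the sorted node-name
   triple, named `mv1`, `mv2`, … in creation order.
3. Unobserved vectors that end up as leaves (degree ≤ 1) are removed.

The loop ends when no vector is added; the construction is fully
deterministic. $\varepsilon$ defaults to 0 and all characters are
weighted equally, since no weighting scheme is specified for the data
this reproduces. Two structural guarantees are tested: no path between
observed haplotypes is shorter than their Hamming distance, and the
network metric restricted to observed nodes carries a spanning tree of
exactly the brute-force MST weight. Note the second property is phrased
through the network metric: median vectors may legitimately replace a
long direct link by an equal-length two-step path, so the observed nodes
need not be connected by direct edges alone.

## The synthetic-data generator

`generate_study()` emulates the *shape* of the study data, not its
biology. One background sequence is drawn per run from the target
nucleotide composition (defaults: C 22.11%, T 22.67%, A 36.64%,
G 18.58%, the composition of the Zambian haplotypes); each sample's
sequence is that background with its haplotype's states written at the
catalog positions; the default design reproduces the published
area × sex × haplotype sample table cell-for-cell (165 samples). Because
all samples share one background, haplotypes differ *only* at catalog
columns. This is deliberate: every implemented statistic except the
nucleotide-diversity denominator depends only on haplotype identities
and counts, so the generator fixes all downstream results exactly at
their design values, which is what makes end-to-end reproduction of the
published numbers a meaningful test of the analysis code rather than of
a simulator.

What it does **not** emulate: mutation along genealogies (no coalescent;
novel haplotypes never arise spontaneously), sequencing error beyond
`N`-masking, length variation (the two-column deletion lives in the
catalog, not in the indel process), and linkage of the background to the
haplotype (real invariant columns are invariant because of shared
ancestry, not construction). Passing tests therefore show the *analysis*
is correct, not that the pipeline is robust to messy real alignments;
the `noise` parameter (per-site `N` probability, default 0) exists for
stress testing and by default never hits diagnostic columns, so exact
results and missingness robustness can be studied separately
(`noise_diagnostic = TRUE` lifts that protection, and such samples are
then correctly rejected by the caller).

## Numerical and design choices

* Human-readable outputs are rounded (4 d.p. for diversity tables, 3
  d.p. for AMOVA displays) to match how such tables are printed; JSON
  outputs and all internal computation keep full double precision.
* Tie-breaks everywhere are lexicographic (median-vector insertion,
  edge-table ordering), making every pipeline output byte-reproducible
  from one seed; the run manifest records md5 checksums per output and
  timestamps appear only in the log.
* Degenerate inputs are errors, not silent defaults: gene diversity
  needs $n \ge 2$, AMOVA needs $P \ge 2$ and $N \ge 3$, a sample with
  `N` at a diagnostic column cannot be called, `Fst` is undefined when
  $V_a + V_b = 0$.
* The pooled regional gene diversities are reported as the larger and
  smaller of the two values rather than by region name: recomputation
  from the published count table yields 0.5057 ± 0.0575 for the western
  pool and 0.5014 ± 0.0336 for the eastern pool, while the source text
  attaches those value pairs to the opposite labels — the values
  themselves are unambiguous, the labels appear transposed.

## Problem sizes used in the test suite

The tests run the full 165-sample, 1882-column design end to end (a few
seconds); brute-force oracles use the full catalog for distances and
networks, a 40-sample subsample for the sequence-level nucleotide
diversity scan, 200 null replicates at $R = 99$ for permutation
calibration, and 100 random splits for the pooled-Fst property. These
sizes were chosen so each stochastic check has comfortable resolution at
its assertion threshold.

## Known limitations

* Single-locus, one-level AMOVA only; no hierarchical (multi-stratum)
  designs and no $\Phi$-statistics beyond the single fixation index.
* The caller requires exact width alignment and exact state matches;
  it does not align, trim or impute.
* Median-joining is exact but exponential in the worst case; the
  implementation guards against runaway median-vector growth and has
  only been exercised at catalog scale (tens of haplotypes), which is
  the intended regime.
* Confidence measures are limited to the variance formulas and the
  permutation test; no bootstrap, rarefaction or richness estimation.
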