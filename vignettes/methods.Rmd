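---
title: "Methods: models, parameter semantics and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameter semantics and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`caprapop` implements the SNP-array analysis battery commonly used to
characterize small livestock populations. This vignette states, in the
package's own terms, the statistical model behind each module, the exact
semantics of every tunable parameter, and the numerical conventions the
package commits to. Nothing here is an empirical claim about real breeds;
every quantitative property mentioned is one the test suite verifies on
simulated or hand-built data.

## Genotype model and quality control

Genotypes are stored as a samples × SNPs integer matrix of alternate-allele
dosages (0/1/2, `NA` for missing) inside a light S3 container carrying a
sorted SNP map (chromosome, bp) and per-sample metadata. PLINK text PED/MAP
files are read with the minor allele as the alternate; at a frequency tie
the lexicographically smaller symbol is the alternate, and a monomorphic
SNP codes every call 0. Writing records the original allele symbols, so a
read → write → read cycle is bit-exact.

`apply_qc()` applies, in this fixed order: autosome restriction, sample
call rate ≥ 0.95, SNP call rate ≥ 0.95, MAF ≥ 0.001. The order matters
(sample filtering changes SNP call rates and allele frequencies) and the
chain is idempotent: running it twice changes nothing.

`exclude_related()` uses an IBS-derived kinship proxy. For each pair,
`s = (IBS2 + 0.5·IBS1) / n_callable` is the probability-scale genotypic
similarity; the pairwise median `s0` serves as the unrelated baseline
(assuming relatives are a minority of pairs), and
`k = (s − s0) / (1 − s0)` rescales so that a duplicate sample scores ~1 and
an unrelated pair ~0. Pairs with `k ≥ 0.25` (second-degree and closer) are
flagged and resolved by greedy vertex cover: repeatedly remove the sample
involved in the most flagged pairs, breaking ties by higher missingness and
then by sample id. This is a proxy, not a pedigree estimator: it is
calibrated by construction at the duplicate and unrelated extremes and
validated on simulated parent–offspring pairs, but its numeric value
between those extremes is population-dependent.

## Diversity

Per breed, expected heterozygosity at a locus is `2p(1−p)` from that
breed's allele frequency, observed heterozygosity the fraction of
heterozygous calls; both are averaged over loci with at least one callable
genotype and combined into Wright's `FIS = (He − Ho)/He` (0 when `He = 0`).
An optional `2n/(2n−1)` small-sample correction is available but off by
default, matching the plain estimator.

## Distances, trees and MDS

Between-breed Reynolds distance uses the ratio-of-sums estimator over
loci: `θ = Σ 2(p−q)² / Σ 2[1 − (pq + (1−p)(1−q))]`, with
`D = −ln(1−θ)` (θ capped just below 1 so D stays finite). Under the
Balding–Nichols model θ estimates the drift divergence directly, which the
tests exploit. Neighbor-joining uses `ape::nj`; a negative branch length
(an artifact of NJ on non-additive matrices) is clamped to zero with its
deficit moved to the sibling edge, preserving path lengths through the
parent. Bootstrap supports resample SNP columns with replacement and count
bipartition recovery via `ape::prop.clades`. Note that high support
requires hierarchical structure: a star-shaped radiation (every breed
independently drifted from one ancestor) has no true internal bipartition
and no resolution can earn support — the simulator (below) produces exactly
such stars, so the package's own support tests build hierarchical allele
frequencies explicitly.

Classical MDS wraps `stats::cmdscale` with eigenvalue reporting. Positive
eigenvalues below `max(eig) × 1e-8` are treated as numerical noise of the
double-centering (a collinear configuration, for instance, yields a second
"positive" eigenvalue around 1e-15) and become zero-padded coordinate
columns with a warning, rather than ~1e-8-scale pseudo-coordinates.

## Runs of homozygosity

`detect_roh()` implements a sliding-window detector governed by ten
parameters (defaults in parentheses). Per individual and chromosome:

1. Windows of `windef` (20) consecutive SNPs are placed at SNP indices
   1, 1+`interval` (5), … up to `nsnp − windef + 1`. A chromosome with
   fewer than `windef` SNPs gets one whole-chromosome window. There is no
   extra end-anchored window: a chromosome tail that no window reaches can
   never be a candidate. Under the defaults this happens when
   `nsnp − windef` is not a multiple of `interval`.
2. A window qualifies iff its heterozygote count ≤ `het_allowed` (0) and
   its missing count ≤ `max_miss` (2).
3. A SNP is a candidate iff the fraction of windows covering it that
   qualify is ≥ `roh_quartile` (0.99). With the default of 0.99 this means
   *all* covering windows must qualify, since a SNP is covered by at most
   `windef`/`interval` = 4 windows.
4. Maximal runs of consecutive candidates are split wherever an
   adjacent-SNP gap exceeds `max_internal_gap_kb` (500), then each piece is
   accepted iff it has ≥ `min_nsnp` (10) SNPs, spans ≥ `min_kb_length`
   (1000) kb, and its kb-per-SNP ratio is ≤ `density_kb_per_snp` (500).
   Segment bounds are the first/last candidate SNP positions.

`max_nsnp` (30) is accepted for interface completeness but inert: no
defensible reading caps a run at 30 SNPs when the minimum length is 1 Mb
on a ~50K chip, and the chosen semantics impose no upper SNP bound.

**Boundary resolution.** Because every window covering a SNP must be fully
homozygous, candidates begin roughly `windef − 1` SNPs inside a true
homozygous tract and end the same distance before it ends. Detected
segments are therefore systematically shorter than the underlying tract by
about `2(windef−1)` inter-SNP spacings: ~130 kb per side on a 150 SNPs/Mb
map, but several hundred kb at chip density. Recovery tests consequently
assert ≥90% reciprocal length overlap on suitably dense maps rather than
breakpoint equality; at sparse density, short tracts are found truncated or
not at all, which is inherent to window-based detection, not a bug.

`compute_froh()` divides each individual's summed ROH length by the
SNP-covered autosome length (per chromosome, last − first SNP bp + 1) and
partitions the total into length classes [1,2), [2,4), [4,8), [8,16),
[16,∞) Mb; the class columns sum exactly to the total. `roh_incidence()`
reports, per SNP, the fraction of a sample set whose accepted ROH cover it.

## Effective population size

Within a breed, `pairwise_r2()` computes squared Pearson correlation of
dosages for SNP pairs on the same chromosome within a distance cutoff.
`ne_trend()` inverts the Sved relation `E[r²] ≈ 1/(1 + 4Nc) + 1/(2n)`:
after subtracting the sample-size term `1/(2n)`, `Ne = (1/(4c))·(1/r²adj − α)`
per distance bin, with `α = 1` by default. Bins are built from a target
list of generations ago via `c = 1/(2t)` with a ±10% multiplicative
window; physical distance maps to Morgans at a constant 1 cM/Mb unless
overridden. Bins whose adjusted r² is non-positive are flagged `NA`, not
inverted. This is the standard unphased-genotype approximation: no
phasing, no recombination map, no confidence intervals.

## Selection signatures

Per-SNP two-group FST is Wright's `(H_T − H_S)/H_T` from the two group
allele frequencies, clamped to [0,1] and `NA` when either group has fewer
than two callable genotypes. A useful derived fact, verified in the tests:
if two breeds each drift from a shared ancestor with Balding–Nichols
parameter F, the estimator's expectation is `F/(2−F)`, not F — from
`E[H_T − H_S] = F·p(1−p)` and `E[H_T] = 2p(1−p)(1 − F/2)` at ancestral
frequency p. Parameter-recovery tests therefore invert the mean statistic
as `F̂ = 2m/(1+m)`.

The delta H-score is the absolute difference of per-SNP ROH incidence
between the two groups, computed on a shared SNP panel.

`select_top()` retains the top `floor(fraction × n_defined)` SNPs by the
statistic, ordering by (descending value, chromosome, bp) so that ties at
the threshold resolve deterministically and independently of input row
order; the reported threshold is the smallest flagged value. Flagged SNPs
are mapped to gene intervals (1-based inclusive; BED input is converted
from 0-based half-open) with an optional symmetric flank, and
`consensus_hits()` intersects the gene lists of the FST and delta-H scans.

## Phenotypes

Body weight is predicted from heart girth as
`BW = 0.0127·HG² − 0.69·HG + 14.7` (kg, cm), a convex quadratic increasing
above ~27 cm. Descriptive statistics use type-7 quantiles by default
(configurable, e.g. type 2 for SAS conventions), a t-based 95% CI for the
mean, and type-2 (sample-adjusted, excess) skewness and kurtosis; moments
are `NA` for constant data and kurtosis additionally requires n ≥ 4.
`tabulate_traits()` cross-tabulates binary traits by sex with integer
percentages computed among known statuses.

## The simulator and its realism limits

`simulate_cohort()` draws, per SNP, an ancestral frequency
`p ~ U(0.05, 0.95)` and per breed a Balding–Nichols frequency
`Beta(p(1−F)/F, (1−p)(1−F)/F)`; genotypes are `Binomial(2, p_breed)`.
Layers are applied in a fixed order: base genotypes → related pairs (one
gamete copied from the "parent") → planted homozygous segments → trait
group reassignment (allele frequencies shifted ±delta/2 inside the locus
windows and genotypes redrawn there) → missingness. The `truth` list
records every planted quantity exactly.

Deliberate simplifications, chosen to keep ground truth exact:

- **SNPs are unlinked** outside planted segments and trait windows. Real
  background LD is absent, so the Ne module's accuracy is tested against
  closed-form r² injection, not simulated chromosomes, and empirical Ne on
  simulated cohorts only checks the no-LD limit.
- **Breed radiation is star-shaped** (each breed drifts independently from
  one ancestor), so simulated trees are stars and tree-support tests build
  hierarchical frequencies directly.
- **Planted ROH are fully homozygous** rather than mutation-peppered, and
  trait loci shift frequencies rather than model dominance or penetrance.

All randomness is seed-driven; helper streams derive sub-seeds
deterministically so each layer is independently reproducible.

## Open design decisions

- The ROH parameter set is named but not algorithmically defined in common
  usage; the window-scoring semantics above (qualifying-fraction threshold
  per SNP, stepped windows, no tail anchor) are fixed as this package's
  definition and enforced by an independent brute-force oracle in the
  tests.
- Problem sizes in tests (SNP counts, trial counts, map densities) are the
  package's own choices, scaled so the full suite runs in minutes while
  keeping each statistical assertion's power ≥ the stated thresholds.
- `run_pipeline()` computes ROH and selection scans before the per-breed
  cap (inbreeding and scan power benefit from every retained animal) and
  diversity/tree/MDS after it (balanced sizes avoid sample-size artifacts
  in between-breed comparisons).
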