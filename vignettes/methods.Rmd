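---
title: "Methods: rhythm detection, differential rhythmicity, and the comparative pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm detection, differential rhythmicity, and the comparative pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavechrono)
```

This vignette explains the statistical machinery of `cavechrono`: what
each stage assumes, which knobs matter, what the synthetic-data
generator does and does not emulate, and the numerical and design
choices that were genuinely open.

## The study design

All defaults describe a one-cycle circadian time course under constant
conditions: 6 circadian times (CT0, 4, …, 20) spaced 4 h over a 24-h
cycle, 6 replicate animals per timepoint, in up to four populations of
which one (the "surface" population) serves as the evolutionary
reference. Animals are reared on a 14:10 light:dark cycle before
release into darkness, so subjective day is taken as CT0–14 and night
as CT14–24 in phase histograms. The period is fixed at 24 h throughout;
period estimation, detrending and multi-cycle designs are out of scope.

## Rhythm detection

For each gene and population the test statistic is Kendall's τ-b
between the 36 counts and a cosine reference waveform
$\cos(2\pi(t-\phi)/24)$ evaluated at each sample's circadian time, for
every candidate peak lag $\phi$ on a grid (default: the 4-h sampling
grid; a 2-h half-interval grid is available). Replicates share a CT, so
the templates are heavily tied; integer counts tie too. τ-b handles
both through its tie terms. The best lag is the phase estimate;
amplitude is half the range of per-timepoint medians (a Hodges–Lehmann
style pairwise-difference option exists behind
`amplitude_method = "hodges_lehmann"`).

Rank statistics are scale-free, so the test runs on raw counts;
library-size normalization is deliberately not required (and is left to
the user as a pre-step if desired).

### Two p-value conventions

The null distribution of the *best* correlation over lags is the open
design question, and the package ships both answers:

- **`maxstat`** (default for `jtk_test()`/`rhythm_scan()`): the exact
  permutation null of the max-over-lags τ, conditioned on the gene's
  own tie pattern. Since full enumeration of 36! orderings is
  impossible, the null is Monte-Carlo (default $10^5$ seeded draws);
  because it depends only on the multiset of tied-group sizes, draws
  are cached per tie signature, and each signature's stream is seeded
  from (seed, signature) so results are independent of gene order.
  This convention is exactly calibrated: on simulated null genes the
  p < 0.05 fraction is ~0.05.
- **`bonferroni`** (default for the pipeline): the classical
  JTK_cycle-style conversion. The best-lag Kendall S is referred to
  the *exact* single-template null — computed by a Harding-style
  dynamic programme: S = 2·JT − M, where the Jonckheere–Terpstra
  statistic's null is the convolution of Mann–Whitney null
  distributions over the template's tied groups — and multiplied by
  the number of lag/sign alternatives (2 × the number of lags),
  capped at 1. Data ties are ignored by this null (as in the
  classical implementation), making it conservative, with a large
  atom of p-values at exactly 1.

The two conventions serve different purposes, and the package is
explicit about the interplay. The conventional classification rules —
*rhythmic* at BH FDR < 0.05, *arrhythmic* at p > 0.5 — were calibrated
by the field against JTK-style conservative p-values: under the
classical convention ~80–90% of truly flat genes exceed p = 0.5,
so "arrhythmic" is a meaningful non-cycling call, and the differential
rhythmicity inclusion rule "p < 1 in either population" actually
excludes genes (p = 1 occurs with positive probability). Under the
exactly calibrated `maxstat` null, flat genes have uniform p, so only
half of them exceed 0.5 and no gene has p = 1: the same thresholds mean
something much weaker. Consequently the pipeline, which applies the
conventional thresholds, defaults to `bonferroni`, while the standalone
test defaults to the calibrated convention. Both are asserted in the
test suite: `maxstat` for calibration and permutation-oracle agreement,
`bonferroni` for the behaviour the classification thresholds
presuppose.

Degenerate (constant) series get p = 1, amplitude 0 and a flag. Exact
single-template tail probabilities are floored at $10^{-16}$ — the
numerical resolution of the convolution — so perfect rhythms do not
underflow to p = 0.

Genes with fewer than 100 reads summed over all samples are removed
before testing (`min_total`, inclusive boundary: a total of exactly 100
is kept).

## Differential rhythmicity (S_DR)

For a population pair, each included gene (p < 1 in either population)
receives

$$S_{DR} = \tfrac12\,(Z_P + Z_R),\qquad
\Delta_P = \log p_1 - \log p_2,\quad
\Delta_R = \log_2(A_2/A_1),$$

where $Z_P, Z_R$ standardize the deltas against the empirical mean and
SD of the included genes *of that pair* (not pooled across pairs).
Positive S_DR therefore means population 2 is the more rhythmic one;
the pipeline passes the cave population first and the surface reference
second, so its headline upper tail is "more rhythmic in surface". Both
deltas are antisymmetric, so swapping the pair negates every score
exactly — a property the tests assert to machine precision.

Two floors keep the scores finite: amplitudes are floored at half the
smallest positive amplitude observed in the pair (JTK amplitudes can be
0 for flat genes), and p-values at half the smallest positive p (an
exact-null tail can underflow). Both floors are recorded on the result.
p-values for S_DR come from a Gaussian fitted to the empirical S_DR
distribution (its mean and SD; at least 10 genes required); the tail is
configurable because the choice is genuinely open — the default reports
the upper tail, matching the signed presentation of
"more rhythmic in the reference" gene sets. With identical populations
the empirical SD is 0; the degenerate rule (all z = 0, p = 1, with a
warning) makes that case explicit rather than erroring.

Loss sets follow the comparative logic: among genes rhythmic in the
reference, those arrhythmic in *every* comparison population
(`lost_in_all`) or in at least one. Set overlaps (e.g. against a
reference species' rhythmic genes) use the upper-tail hypergeometric
test; p-value distribution shifts for a focal gene set (e.g. annotated
clock genes) use the paired Wilcoxon signed-rank test.

## Phase analysis

Peak-time differences live on a circle: the signed minimal distance
wraps $b - a$ into $(-12, 12]$ h, positive meaning a later peak in the
second population. The antipodal tie (|shift| = 12 h) is mapped to +12
from both directions — a deterministic, documented asymmetry (the
alternative, random tie-breaking, would make outputs seed-dependent for
no statistical gain); such records carry an `antipodal` flag. The
population-level shift test includes genes with p < 0.05 in both
populations and applies the signed-rank test with the standard
zero-difference-drop convention. Phase resolution equals the lag grid:
on the default 4-h grid a true +2 h shift is estimated as a mixture of
0 and +4 h, unbiased in the mean but coarse — the 2-h grid resolves it
directly, which is why shift-recovery checks use `lag_step = 2`.

## Promoter and motif analysis

Promoters are the region 1 kb upstream to 200 bp downstream of the
TSS, strand-aware and clipped (with a flag) at contig edges.
Population-specific promoters substitute the population-major allele
(frequency > 0.5) into the window, remapping coordinates across simple
indels; overlapping indels are rejected.

The scanner is FIMO-like: log₂-odds scores against a background
composition, converted to p-values by an exact dynamic programme over
positions and discretized scores. Scores are mapped to a shared integer
grid (default $10^4$ bins across the attainable range) and words are
scored on the *same* grid, so table lookups are exact for the
discretized score; discretization only coarsens resolution, and p is
taken from the bin's lower edge (the conservative side). Windows
containing N are skipped; reverse-strand hits are reported in forward
coordinates. The default hit threshold is p < 10⁻⁴; note a perfect
width-6 consensus has p = 4⁻⁶ ≈ 2.4×10⁻⁴ under a uniform background and
therefore *cannot* clear it — the shipped E-box/RRE/D-box PWMs carry
informative flanks (widths 8–11) for this reason, and production scans
should supply real PWMs in MEME format.

Phase enrichment of motif targets uses circular sliding windows
(default 6 h wide, 2 h step — unstated in the original design and
chosen to cover the clock at half-window overlap) with two-sided Fisher
tests of (has motif) × (peaks in window); cross-population motif loss
is a per-gene presence comparison plus a 2×2 Fisher test.

## Population genetics

Per-site π uses the unbiased $\frac{n}{n-1}2p(1-p)$ with n the called
alleles; per-gene values divide the sum over variant sites by the
coding-interval length. F_ST is the Weir–Cockerham (1984)
two-population estimator; per-gene aggregation is the ratio of averages
Σa/Σ(a+b+c), the standard less-biased aggregate (the per-gene rule was
an open choice). Sites monomorphic across both populations or with
fewer than two called diploids in either are excluded from the sums;
raw (possibly slightly negative) estimates are retained. d_XY is
$p_A(1-p_B)+p_B(1-p_A)$ summed over sites per coding length. Outliers
are genes at or above the 95th empirical percentile of per-gene F_ST
within a comparison (ties all flagged), plus an any-comparison union
flag. High-frequency cave variants use an inclusive ≥ 0.8 threshold
(the frequency cut is quoted both exclusively and inclusively in
different places; the inclusive reading is adopted) and "absent from
the surface" means frequency exactly 0 with at least a minimum number
of called alleles. VCF input is 1-based; all internal intervals are
0-based half-open; the readers are the only place translation happens.

The relaxed-selection enrichment test consumes per-gene boolean flags
(produced upstream by selection-intensity model comparisons, which are
out of scope) and asks whether a focal set — canonically 18 clock
orthologs — contains more flagged genes than random sets of the same
size: default 1,000 permutations, with the add-one (Phipson–Smyth)
estimator $p = (1+\#\{null \ge obs\})/(n_{perm}+1)$, bounded below by
$1/(n_{perm}+1)$ and converging to the hypergeometric upper tail.

## The synthetic-data generator

The generator is the package's test bed and defines the conditions
under which all properties are asserted:

- **Counts**: negative binomial with variance $\mu + d\mu^2$ and
  $\log \mu = b + A\cos(2\pi(t-\phi)/24)$. Defaults: baselines uniform
  on log-mean 4–7, amplitude 1 log-unit for rhythmic genes, dispersion
  0.05 — a clean, moderately deep RNA-seq series. The count-noise
  family of real data is not knowable from summary tables; NB is the
  standard stand-in. Amplitude is exactly 0 for non-rhythmic genes
  (amplitude = 0 iff not rhythmic, by construction).
- **Promoters**: i.i.d. background bases (uniform by default,
  configurable), with a motif's consensus planted at a recorded offset
  for genes whose phase falls in the motif's circular window, with the
  stated probability. No linkage between motifs, no dinucleotide
  structure.
- **Genotypes**: independent sites; per-population frequencies from a
  Balding–Nichols model around a shared ancestral frequency with a
  target F_ST (or explicit frequency matrices); diploid genotypes
  binomial. No linkage disequilibrium — sufficient for testing
  estimators, not for demographic inference.
- **Relaxed flags**: independent Bernoulli flags plus a focal set
  sampled without replacement.

All randomness flows from one master seed through named substreams
(`substream_seed(seed, label)`), so stages are individually
reproducible and insensitive to execution order; identical seeds give
byte-identical outputs. Truth tables are returned separately from the
input files and no analysis stage reads them.

What passing tests on this generator do **not** show: robustness to
library-size variation, batch effects, overdispersion heterogeneity,
non-sinusoidal waveforms, promoter sequence composition bias, or linked
selection. They show that each estimator recovers what it claims from
data matching its own model, at the study's design size.

## Problem sizes and numerical choices

The verification suite runs at deliberately chosen sizes: 2,000 null
genes for calibration; 500 planted rhythms (amplitude 1, dispersion
0.05) for sensitivity and phase recovery; 600 genes with a 5% planted
loss fraction for S_DR ranking; 150 genes with a +2 h planted delay for
shift recovery; 20 generator seeds for enrichment-window recovery;
1,500 identical-frequency and 8×400 Balding–Nichols sites for the F_ST
checks; $10^5$ draws where a Monte-Carlo estimate is compared with an
exact tail. Monte-Carlo nulls default to $10^5$ draws; exact
enumeration oracles are used up to n = 8 (8! orderings). Ties at the
best lag resolve to the first (earliest) lag; argmax over lags is on
the τ scale so lag-specific tie corrections are honoured.

## The pipeline

`run_pipeline()` executes simulate (optional) → filter → rhythm per
population → classification → S_DR per pair → loss sets → phase
analysis → motif analysis → population genetics, writing one TSV per
stage and a JSON summary that embeds the fully resolved configuration
and seed. Stages communicate only through files/values, never by
mutating each other's outputs. In simulation mode the motif stage
scans promoters the generator planted from the reference population's
true phases, while the enrichment step uses *estimated* phases
(q < 2·FDR in the reference) — truth never leaks into an analysis
stage. There is no shell entry point: the exported functions, this
vignette and `scripts/acceptance.R` are the interface, which is how an
analysis package of this kind is normally driven.

## Known limitations

- The Monte-Carlo `maxstat` p has resolution $1/(n_{null}+1)$; for
  genome-scale FDR at very small q, raise `n_null`.
- The Bonferroni convention ignores data ties in its exact null and is
  conservative by design; its factor (2 × lags) is a documented
  convention, not a fitted quantity.
- Amplitude from per-timepoint medians is biased downward for sharp
  waveforms; the pairwise option mitigates but does not remove this.
- The Balding–Nichols target F_ST is matched in expectation by the
  Weir–Cockerham estimate, not site-by-site.
- Indel handling in promoter substitution covers simple, non-overlapping
  indels only.
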