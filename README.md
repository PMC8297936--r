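# cavechrono

Comparative analysis of circadian transcriptomes across populations —
built for the classic evolutionary setting of a surface-dwelling fish
population and its independently derived, perpetually dark cave
populations, but applicable to any multi-population circadian RNA-seq
time course.

## What it does

Given a gene × sample count matrix from a one-cycle circadian time
course (by default 6 timepoints every 4 h, 6 replicates, constant
darkness), the package:

1. **Detects 24-h rhythmic transcripts** per population with a
   from-scratch, JTK_cycle-style nonparametric test: Kendall's τ-b
   between each gene's counts and cosine reference waveforms at every
   candidate peak lag. Two p-value conventions are provided — an exactly
   calibrated permutation null of the max-over-lags statistic
   (conditioned on each gene's tie pattern), and the classical
   conservative Bonferroni-over-lag/sign-alternatives conversion through
   the exact Kendall-S null (computed by a Mann–Whitney convolution
   dynamic programme). Genes are called *rhythmic* at FDR < 0.05
   (Benjamini–Hochberg) and *arrhythmic* at p > 0.5.
2. **Scores differential rhythmicity** between population pairs:
   S_DR = (Z_P + Z_R)/2, where Z_P standardizes the periodicity change
   log p₁ − log p₂ and Z_R the amplitude change log₂(A₂/A₁) across
   included genes (p < 1 in either population); p-values come from a
   Gaussian fit to the empirical S_DR distribution.
3. **Quantifies phase shifts** with circular statistics: minimal signed
   clock distance between peak times, Wilcoxon signed-rank shift tests,
   phase-peak histograms, and comparison against a reference-species
   phase table.
4. **Scans promoters for circadian cis-elements** (E-box, RRE, D-box)
   with a FIMO-like engine: exact PWM score-distribution p-values via
   dynamic programming, a p < 10⁻⁴ hit threshold, sliding-window Fisher
   tests for phase enrichment of motif targets, population-specific
   promoter construction from variants, and cross-population motif
   presence/loss comparison.
5. **Computes per-gene population-genetic summaries**: nucleotide
   diversity π, the Weir–Cockerham (1984) F_ST (ratio of averages
   Σa/Σ(a+b+c) per gene), d_XY, top-5% F_ST outlier flags,
   high-frequency cave-specific variants (frequency ≥ 0.8 in a cave,
   absent from the surface), and a permutation null (1,000 draws of an
   18-gene focal set by default) for relaxed-selection enrichment.

A first-class **synthetic-data generator** emulates the full study
design — negative-binomial counts with cosine log-means, promoters with
phase-linked planted motifs, two-population genotypes of controlled
differentiation, relaxed-selection flags — so that every stage is
testable against known truth without any external data.

## Worked example

```r
library(cavechrono)
library(dplyr)

truth <- simulate_gene_truth(n_genes = 200,
                             populations = c("surface", "cave"),
                             rhythmic_fraction = 0.4, amplitude = 1,
                             loss_fraction = 0.3,
                             phase_delay = c(cave = 2), seed = 42)
sim  <- simulate_expression(truth, seed = 42)
scan <- rhythm_scan(sim$counts, sim$meta, seed = 42)
glance(scan)
#> # A tibble: 2 × 5
#>   population n_genes n_rhythmic n_arrhythmic median_p
#> 1 cave           200         58           65    0.236
#> 2 surface        200         83           61    0.168
```

Fewer genes cycle in the cave population (58 vs 83): the generator
silenced 30% of the surface-rhythmic genes there, and the scan sees it.
Differential rhythmicity ranks exactly those silenced genes on top
(positive S_DR = more rhythmic in the second population, here surface):

```r
res <- tidy(scan)
sdr <- sdr_scores(filter(res, population == "cave"),
                  filter(res, population == "surface")) |> sdr_pvalues()
head(arrange(sdr, desc(S_DR)), 3)
#>   gene  pop1  pop2    delta_period delta_amp   Z_P   Z_R  S_DR        p      q
#> 1 g0049 cave  surface         11.5      4.19  2.94  3.39  3.17 0.000508 0.0679
#> 2 g0036 cave  surface         11.4      3.83  2.93  3.06  3.00 0.000933 0.0679
#> 3 g0005 cave  surface         11.5      3.75  2.94  3.00  2.97 0.00102  0.0679

lengths(loss_sets(res, reference = "surface"))
#> rhythmic_in_reference  lost_in_all  lost_in_at_least_one  rhythmic_in_all
#>                    83           13                    13               58

phase_shift_test(filter(res, population == "surface"),
                 filter(res, population == "cave"))$summary
#>       n mean_shift median_shift           p
#> 1    59       1.97            0 0.000000204
```

The planted +2 h cave delay comes back as a mean signed shift of
+1.97 h over the 59 jointly rhythmic genes (signed-rank p ≈ 2×10⁻⁷);
the median sits at 0 because phases are estimated on the 4-h lag grid,
so a +2 h shift appears as a mixture of 0 and +4 h jumps.

`run_pipeline(pipeline_config(simulation = list(...)), out_dir)`
orchestrates all stages end to end from one config (or from input
files), writing one TSV per stage plus a JSON summary; identical config
and seed give byte-identical outputs. `autoplot(scan)`, `plot_sdr()` and
`plot_enrichment()` draw the standard figures.

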