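---
title: "Mixed-ploidy genome scans: models, estimators and design choices"
author: "PloidyScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-ploidy genome scans: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Diploid and autotetraploid populations of an outcrossing plant repeatedly
colonize two contrasting substrate types — calcareous (high pH, calcium-rich)
and siliceous (low pH, silicate-derived) soils. Comparing the genomic
footprints of this repeated adaptation between the two ploidy levels requires
statistics that behave identically under diploid and polysomic tetraploid
genetics, replicated outlier scans that separate selection from lineage-level
drift, and summaries of sweep shape, fixation and the evolutionary source of
the selected alleles. PloidyScan implements that comparative pipeline,
together with a synthetic study generator that provides ground truth for
every stage.

# Genotype model

`GenotypeMatrix` stores per-site, per-sample *allele dosages*: an integer in
$[0, m]$ for a sample of ploidy $m \in \{2, 4\}$, parsed from VCF genotype
strings of matching arity (`0/1`, `0/0/1/1`). Partially missing calls such as
`./0/0/1` carry ambiguous dosage and are treated as fully missing (the count
is logged). Positions are 1-based as in VCF; analysis windows form a fixed
non-overlapping grid anchored at position 1 of each scaffold, so window
arithmetic is overlap-free.

Site filters follow a fixed order — per-cell depth masking, then site-level
missingness, then MAF — so that the missing fraction already reflects
depth-masked cells. The minor-allele frequency is allele-copy weighted over
all samples of the analysis set. Two structural masks mirror common practice
for polyploid mapping artifacts: genes with at least five *fixed
heterozygous* SNPs (every genotyped sample at dosage $m/2$) in at least two
populations are masked as collapsed paralogs, and sites where at least 20
samples exceed their own depth mean + 2 SD are masked as repetitive. Depth
statistics are per sample, not pooled: per-sample library size variation
would otherwise dominate the pooled SD.

# Diversity estimators

Per-site heterozygosity uses the unbiased pairwise form
$2k(n-k)/\{n(n-1)\}$ for $k$ derived copies among $n$ chromosomes; window
nucleotide diversity $\pi$ divides the sum by the window length in bp, so
monomorphic positions contribute zero. Tajima's D uses the standard constant
set ($a_1 \dots e_2$) with $n$ equal to the *downsampled* chromosome count:
every population is first downsampled to four individuals per site, so that
$\pi$ and D share one sampling scheme and are comparable across populations
of unequal size. Windows with no segregating site have undefined D and are
reported as missing, not zero.

Chromosome-level downsampling (used for standardized fixation counts) draws
without replacement from the population's sampled allele copies — a
hypergeometric draw from the derived-allele count — and is exhaustive (hence
deterministic) when a population holds exactly the requested number of
copies.

# Differentiation: F_ST and Rho

Weir–Cockerham F_ST is computed at the haplotype level from allele counts
(sample sizes are chromosome counts), since the within-individual stratum it
would otherwise include is exactly what differs between ploidies. F_ST is
used only *within* a ploidy, for ranking windows.

Cross-ploidy comparisons use Rho, formulated through gene-identity
probabilities: with $Q_2$ the probability that two allele copies from
*different individuals of the same population* are identical and $Q_3$ the
probability for copies from different populations,
$$\rho = \frac{Q_2 - Q_3}{1 - Q_3}.$$
No two copies are ever compared within an individual, so the statistic is
invariant to everything that lives in the within-individual stratum
(polysomic masking, inbreeding, double reduction) and is directly comparable
between ploidy levels. We deliberately did not use a copy-level nested-ANOVA
ratio of the among-population to among-population-plus-among-individual
variance components: under random mating the among-individual component has
expectation zero at any ploidy, so that ratio degenerates toward 1
regardless of divergence. The identity-probability form is the one whose
behavior matches the statistic's purpose, and the property suite verifies
both ploidy comparability (equal windowed means at equal population
divergence, diploid vs tetraploid) and coincidence with F_ST for
Hardy–Weinberg diploids.

All windowed statistics are *ratio-of-sums* of per-SNP components, not means
of per-SNP ratios; negative per-SNP components are preserved in the sums and
clamped to $[0,1]$ only at reporting, which avoids the upward bias of
clamping before aggregation.

# The replicated outlier scan

Each calcareous/siliceous population pair is scanned in 1-kbp windows
(minimum 10 SNPs), and the top 1% of windows by F_ST are annotated to genes
by ≥ 1 bp overlap. Ties at the quantile cutoff are all included (logged):
dropping an arbitrary subset of tied windows would make the scan
order-dependent. *Parallel candidates* are genes that are outliers in at
least two pairs whose lineages differ — repetition within one lineage is
treated as drift, not parallelism. Top candidates are the parallel F_ST
genes confirmed by at least one of the two orthogonal methods below; genes
found by the other methods alone are not promoted, keeping the list anchored
to the hard-sweep signal the F_ST scan targets.

Two set-level checks guard the candidate list: a one-sided hypergeometric
test of the between-ploidy overlap (the universe defaults to the genes
overlapping at least one analyzable window — the natural reference set, and
configurable because any choice is somewhat arbitrary), and a one-sided
permutation test (10,000 draws) of mean recombination rate, which flags
candidate lists that merely track the recombination landscape.

# Repeated-adaptation order statistics

Per lineage (one contrast per lineage, chosen as the least-diverged pair so
contrasts are as exchangeable as possible), each window receives an
empirical p-value — its rank among all windows, average ranks for ties, so
marginals are uniform by construction. For one window with sorted p-values
$p_{(1)} \le \dots \le p_{(L)}$ over $L$ lineages ($3 \le L \le 12$), the
combined statistic evaluates $q_a = \mathrm{Beta}(p_{(a)}; a, L-a+1)$ for
$a = 2 \dots L$ and takes $1 - (1 - \min_a q_a)^{L-1}$, a Dunn–Šidák
correction over the $L-1$ configurations. The minimum order statistic is
excluded so one extreme lineage cannot drive significance; the $a$ attaining
the minimum is reported as the estimated number of repeatedly adapting
lineages. The statistic is calibrated against a Monte-Carlo null of $L$ iid
uniforms (10,000 repetitions), and `alpha_adapt` (default 0.05) is the
fraction of null windows simulated as already adapted in one random lineage
(that lineage's p-value set to 0). Because the minimum is excluded, this
changes the null only through the order-statistic positions of the remaining
lineages — a small guard against anticonservatism when part of the genome
truly is adapting. Benjamini–Hochberg FDR is applied to the calibrated
p-values; windows at $q < 0.05$ are significant.

# Environmental association

Population allele frequencies are regressed per SNP on the soil PC1 score
with the top-$k$ principal components of the (centered, per-SNP
mean-imputed) frequency matrix as explicit structure covariates. This is a
transparent stand-in for latent factor mixed models: the factors are
estimated once from the frequency matrix rather than jointly with the
effects, and the substitution is asserted only through its calibration
(uniform p-values under permuted soil; FDR hit rate ≤ 2× nominal under
structured null frequencies) and power (a planted soil effect of 0.3 per
PC1 unit at noise SD 0.02 over 40 populations is recovered at $q < 0.1$)
properties, all part of the test suite. Population-level regression matches
the population-frequency formulation of the association; individual-level
mixed models are out of scope. Degenerate principal components (when the
frequency matrix has lower rank than $k$) are dropped with a warning, and
the pipeline caps $k$ so the regression keeps at least two residual degrees
of freedom. Genes need at least three significant SNPs to qualify; a SNP
inside two overlapping genes counts for both, since exclusivity would
require an arbitrary assignment rule.

# Soil gradient

The soil table (pH H2O, pH KCl, bioavailable Ca, total Ca/Mg/K/Na, CEC —
concentrations in mmol/kg) is completed by regressing each incomplete column
on the three always-measured predictors (pH H2O, pH KCl, bioavailable Ca)
over complete rows; observed cells are never altered and imputed cells are
flagged. Observed and imputed values then enter one standardized PCA
together. PC1's sign is anchored so the pH H2O loading is negative:
calcareous populations score negative, siliceous positive, independent of
numerical library conventions. Populations without soil data keep a missing
PC1 and are excluded from the association scan but retained in the F_ST
scan.

# Sweep magnitude and breadth

For each candidate gene and qualifying pair, the per-SNP Rho track within
100 kbp of the gene midpoint is the *curve region*. **Magnitude** is the
highest *raw* per-SNP Rho in the region minus the genome-wide mean —
deliberately smoother-free, so it cannot depend on the span selection.
**Breadth** uses a smoothed curve: local linear regression with the span
chosen from the grid 0.1–0.9 (step 0.05) by the bias-corrected AIC,
$\mathrm{AICC} = \log\hat\sigma^2 + \frac{1 + \mathrm{tr}(L)/n}
{1 - (\mathrm{tr}(L)+2)/n}$, with the smoother trace taken from the loess
fit (approximate for large regions) and ties resolved toward the smaller
span. Grid minimization replaces continuous optimization for exact
reproducibility. The curve is evaluated every 1 kbp; breadth is the width of
the contiguous above-threshold interval *containing the curve maximum*
(linear interpolation at the crossings), with the threshold at twice the
background Rho — the mean per-SNP Rho in the 200 kbp beyond each side of the
curve region, falling back to the genome-wide mean (flagged) when no
flanking SNPs exist. Multi-modal curves therefore report the peak's own
component; 0 (flagged) when the peak never clears the threshold; the region
length (flagged) when the curve never drops below it. Breadths are stored in
bp with a kbp display convention in the summary outputs.

# Fixation, frequency spectra and modes

A fixed difference is strict: frequency exactly 0 in one population and
exactly 1 in the other, on the chromosome set in use — either all genotyped
copies or a standardized 12-chromosome subsample (both modes are provided
since sample-size asymmetry between ploidies otherwise biases the count;
the truly-fixed case survives any subsample, and the spurious-fixation
probability under intermediate frequencies follows the closed-form
hypergeometric expression, both property-tested). Per-gene means include
only pairs in which the gene was an outlier. Allele-frequency summaries by
soil class are oriented (siliceous high) purely for display; statistics are
computed pre-orientation.

Adaptation-mode assignments (neutral / de novo / standing / migration per
gene × quartet, with a selection-strength bin from
$\{10^{-4}, 10^{-3}, 10^{-2}, 0.05, 0.5\}$) are consumed from a TSV
exchange format; fitting the composite-likelihood models that produce them
is out of scope. Quartets are unordered pairs of lineage-distinct contrasts
within a ploidy. Tallies exclude neutral cases; 2×2 ploidy-by-mode
comparisons use the continuity-corrected chi-square
$N(|ad-bc|-N/2)^2 / \{(a{+}b)(c{+}d)(a{+}c)(b{+}d)\}$ (clamped at zero when
$|ad-bc| < N/2$) and Fisher's exact test (two-tailed) where cells are small.

# Protein-interaction degrees

Degrees are counts of distinct partners on the undirected, deduplicated
edge list; the combined-score threshold defaults to 0 (no subsetting).
Candidate genes without a protein mapping are excluded and reported. The
connectivity test compares the mean candidate degree with means of
equally-sized draws without replacement from all node degrees, one-sided,
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n_{\text{perm}} + 1)$ — bounded
below by the permutation floor.

# The synthetic study generator

The generator is first-class, tested code, not a fixture. Allele frequencies
follow a Balding–Nichols hierarchy: ancestral frequency per SNP from a
symmetric Beta(0.8, 0.8); a lineage-level Beta draw with drift `F_lineage`
(default 0.15); a population-level draw with drift `F_pop` (default 0.08).
Tetraploid lineages and populations drift with both parameters scaled by
0.65, reproducing the study conditions the pipeline is meant to discriminate:
lower neutral pairwise differentiation between tetraploid pairs (≈ 0.11 vs
≈ 0.16 genome-wide Rho at the defaults) and higher tetraploid diversity.
The default design has four lineages per ploidy, one calcareous/siliceous
pair per lineage, six individuals per population, a 4 × 500-kbp genome at
0.02 SNPs/bp, 25× mean Poisson depth and 5% missingness — large enough for
~2,000 analyzable 1-kbp windows while a full end-to-end run stays around a
minute on one CPU.

Sweeps are planted inside genes from a deterministic layout (one 3-kbp gene
every 12 kbp). The frequency-elevation kernel is flat across the gene body
and decays linearly to zero at `sweep_half_width` (default 25 kbp) beyond
the gene edges — a flat-topped triangle. The flat top guarantees that
in-gene SNPs reach the full pushed frequency, so fixation outcomes are
governed by the cap, not by where SNPs happen to fall. The pushed target is
$\min\{s/(s + 0.005),\ \text{cap}\}$ — the half-saturation constant places
the two strongest selection bins (0.05, 0.5) near the cap and the two
weakest ($10^{-4}$, $10^{-3}$) below 0.2 — with cap 1 in diploids and
`tetraploid_freq_cap` (default 0.85) in tetraploids. The calcareous member
of each affected pair is depressed toward zero by the same kernel. When the
tetraploid cap is below 1 it is enforced on the *realized sample*: a swept
tetraploid population that would be monomorphic derived has one chromosome
reverted, so "capped ⇒ never fixed" holds exactly rather than with high
probability. This is the dominance-like fixation barrier the cap models, and
it makes the diploid-fixes / tetraploid-does-not contrast a deterministic
property of the generator.

Modes are labels plus frequency-sharing patterns: `standing` applies one
shared elevation across pairs, `denovo` jitters the kernel independently per
pair, `migration` copies the first pair's pushed frequencies to the other
affected pairs. This is sufficient for tally and exchange-format testing and
is *not* a coalescent model.

What the generator does not emulate — and hence what green tests do *not*
establish about real data: linkage disequilibrium outside swept regions,
realistic site-frequency spectra (the Beta ancestral spectrum yields mildly
positive Tajima's D), genotype-calling error structure beyond uniform
missingness and Poisson depth, gene conversion and double reduction, and any
coalescent realism in the mode patterns. Estimator correctness is instead
established against brute-force oracles on enumerable inputs, and scan
behavior against planted truth and analytic nulls.

# Numerical and degenerate-input conventions

Quantile outliers use the ceiling rule (`ceiling(0.01 N)`) with inclusive
ties; fewer than 100 windows or an all-constant statistic is an error, not a
silent answer. Permutation p-values never report below their floor
$1/(n_{\text{perm}}+1)$. Monomorphic SNPs are excluded from association
(zero variance), logged. A population with all samples missing at a site has
a *missing* frequency, never zero. Loess span ties break toward the smaller
span; the AICC denominator going non-positive marks the span unusable. All
randomness flows through named seeds; reruns with the same bundle and seed
are bit-identical, which the suite asserts at the pipeline level.

# Problem sizes used by the tests

The unit suite runs on a reduced bundle (two lineages per ploidy, 2 ×
120 kbp, ~4,800 SNPs); the acceptance-level checks use the full default
study (~40,000 SNPs, 96 samples), 250-window ploidy-comparability
simulations, 20-replicate calibration experiments and 8-replicate power
experiments — sizes chosen so the entire suite completes in a few minutes
while keeping Monte-Carlo standard errors well inside the asserted margins.

# Known limitations

F_ST-based outlier ranking inherits the usual sensitivity to local drift;
the lineage-aware parallelism filter mitigates but does not remove it. The
association stand-in is not a penalized joint estimator and will lose power
when structure and the environmental gradient are strongly confounded. Rho
requires at least two genotyped individuals per population per site. The
mode tallies are only as good as the upstream assignments they consume. The
pipeline assumes one ploidy per population and even ploidy throughout.
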