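---
title: "Methods: windowed divergence statistics and selective-sweep detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed divergence statistics and selective-sweep detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popsweep)
```

## The problem

Two groups of cultivated varieties — here labelled H (hard-seeded) and S
(soft-seeded), after the pomegranate cohorts that motivated the design —
are resequenced against a common reference, yielding a biallelic SNP
genotype matrix. Divergent selection leaves a characteristic footprint:
locally reduced nucleotide diversity in the selected population together
with elevated allele-frequency differentiation between the populations.
`popsweep` scans for that footprint, and surrounds the scan with the
standard companion analyses (heterozygosity, LD decay, distance-based
trees, PCA, membership assignment, pathway enrichment) so a cohort can be
characterised end to end from a VCF, a popmap and a GFF3.

## Site filters

Input sites are filtered by three rules before any statistic is computed:

* **MAF**: minor allele frequency strictly greater than 0.05, computed on
  non-missing alleles only.
* **Integrity**: at least 50% of samples genotyped (the "loci integrity"
  convention for cohort panels).
* **Cluster**: no more than 2 SNPs in any 5-bp window. When a window
  exceeds the bound, *every* SNP in the offending span is removed, not
  just the excess: the result is then independent of scan order and the
  filter is idempotent (verified by property test).

The comparison operators (strict `>` for MAF, `>=` for integrity) follow
the printed conventions of resequencing studies; both thresholds and the
cluster geometry are configurable through `site_filter_config()`.

## Windowed statistics

Statistics are computed in sliding windows (default 100 kb advanced by
10 kb, the standard resolution for cohort sweep scans) emitted only when
fully contained in a chromosome.

**Nucleotide diversity.** Per site, the unbiased expected heterozygosity
$\frac{n_i}{n_i-1} 2 p_i (1-p_i)$ with $p_i$, $n_i$ the non-missing
alternate-allele frequency and allele-copy count; summed over the window
and divided by the window length. This equals the mean pairwise
difference per site, which the test suite verifies against a brute-force
enumeration of all allele pairs (exact to 1e-12 on 100 random cohorts).
Because the "per kb" unit of published $\pi$ values is sometimes
ambiguous, the statistics table reports both the per-site value and its
per-kb scaling.

**Tajima's D.** The classical normalised difference between the pairwise
and segregating-site estimators of $\theta$, with the standard
$a_1 \dots e_2$ constants. With missing data the allele-copy count varies
across sites; the constants are evaluated at the mean non-missing copy
count over segregating sites (linear interpolation of the harmonic sums
between adjacent integers). With complete data this reduces exactly to
the textbook formula, which is what the oracle tests assert.

**FST.** A multi-site ratio-of-sums estimator. The default is Hudson's
estimator, chosen because it is the least sensitive to unequal sample
sizes — relevant for an 8-versus-12 design; Weir–Cockerham (1984, with
observed heterozygote proportions) is selectable. Negative estimates are
reported as computed and only clamped in plots. Because published
"average FST" values may be window-averaged or genome-pooled, both are
available (`window_stats()` vs `genome_fst()`).

**Diversity ratio.** $\pi$ of one population over the other; orientation
is always recorded. A zero denominator with a positive numerator is
capped (default 100) and flagged; 0/0 is undefined.

Windows with fewer than 10 segregating sites (configurable) are masked
from sweep scans — a variance-control choice: ratio and FST estimates on
a handful of SNPs are dominated by sampling noise.

## Sweep calling

1. **Permutation cut-off.** Published scans often state only that a
   ratio cut-off was "determined by permutation"; the scheme here is
   explicit: population labels are permuted across the labelled samples,
   the windowed ratio is recomputed genome-wide per permutation, all
   permuted values are pooled, and the cut-off is the $(1-\alpha)$
   quantile of the pool. This is correct under the exchangeable null and
   fully reproducible given a seed. The empirical type-I rate is
   validated on no-differentiation cohorts (non-overlapping windows, so
   the binomial tolerance is honest; overlapping windows share sites and
   would inflate the variance of the empirical rate without changing its
   expectation).
2. **FST rule.** Either membership of the genome-wide top 5% (the "top
   fraction" convention; threshold at the ceiling-rank value with all
   ties included, so selection is deterministic and order-independent),
   or an explicit threshold such as FST > 0.55 for highly differentiated
   subregions.
3. **Combination.** A window is a candidate for population X when the
   ratio (other/X) reaches the cut-off *and* the FST rule passes.
   "Combining" two evidence tracks admits either operator; conjunction
   is the default because it can only reduce false calls, and the
   operator is configuration-exposed.
4. **Merging.** Candidate windows overlapping or separated by at most
   the step size (default 10 kb) are merged, so adjacent sliding windows
   integrate into one region; region lengths are reported in Mb with
   half-up rounding at two decimals.
5. **Annotation and enrichment.** A gene belongs to a region on >= 1 bp
   overlap. Enrichment uses the upper-tail hypergeometric test per
   pathway against a user-supplied gene-to-pathway map, with
   Benjamini–Hochberg correction by default (the correction used when a
   study says only "corrected P"; configurable) and a 0.05 flag level.

## LD decay

r² is the squared Pearson correlation of genotype codes over samples
non-missing at both sites — the composite (Burrows-style) measure. This
deviates from haplotype-based r²: the data is unphased, and the composite
measure is deterministic, whereas EM haplotype estimates depend on
initialisation. Pairs are restricted to 1000 kb within chromosomes and
binned in 10-kb bins by default. The between-population decay comparison
permutes sample labels and uses the difference in area under the binned
curves as the statistic — distribution-free, and it reuses the module's
own machinery; the population with the smaller area decays faster.

## Trees, PCA, membership

SNP columns are bridged to nucleotide space as pseudo-sequences; since
the source studies rarely state how heterozygotes were fed to distance
software, the default policy draws a random allele under a recorded seed,
with an IUPAC-ambiguity policy (excluded pairwise from distances) as the
alternative. K2P distances use the closed form
$d = -\tfrac12\ln[(1-2P-Q)\sqrt{1-2Q}]$ with pairwise deletion;
saturated pairs are flagged undefined rather than clamped. Trees are
unrooted neighbour-joining (exact on additive matrices, verified for all
random 4–8-taxon cases), with bootstrap support from resampling SNP
columns with replacement. PCA standardises genotype codes by
$\sqrt{p(1-p)}$ (the Patterson convention), drops monomorphic sites
rather than zero-weighting them, and mean-imputes missing calls.
Admixture proportions are consumed, not estimated (MCMC structure
inference is out of scope); the membership rule assigns a sample to its
argmax cluster only when the proportion strictly exceeds 0.7.

## The synthetic cohort generator

`simulate_cohort()` draws from the Balding–Nichols model: ancestral
frequencies Uniform(0.05, 0.95), population frequencies
Beta-distributed with differentiation parameter F, genotypes
Binomial(2, freq), missing calls Bernoulli per call. The defaults *are*
the study conditions the package targets: 8 H + 12 S + 6 unassigned
samples, 8 chromosomes (chromosome 1 longest at 45 Mb, the rest 40 Mb),
1 SNP/kb, F = 0.26, and one large injected sweep on chromosome 1
(16.33–42.53 Mb, 10-fold diversity reduction in H). The missingness rate
defaults to 2%, a typical call-rate loss for mid-coverage short-read
cohorts (neither a published value nor critical: the integrity filter
and per-site allele counts absorb it). Sweeps are modelled
phenomenologically — frequencies pushed toward the nearest boundary so
expected heterozygosity drops by the configured factor — because the
scan detects sweeps through diversity contrast, not through trajectory
dynamics. Unassigned samples draw from the ancestral frequencies and
exercise the popmap-subset logic.

Balding–Nichols sites are unlinked, so the generator cannot exercise LD
decay by default; an optional first-order genotype autocorrelation
(`ld_rho`) provides monotonically decaying LD for those tests. What
passing tests show, therefore, is that the estimators and the scan are
correct under the model's assumptions (independent sites, no sequencing
error, clean biallelic calls); they do not certify behaviour under
genotyping error, allele dropout, reference bias or real recombination
landscapes.

## Numerical choices and degenerate inputs

* Reported densities and percentages round half away from zero at the
  stated decimals.
* Ratio 0/0 is undefined and excluded from ranking; positive/0 is capped
  and flagged.
* Tajima's D is undefined when S = 0 or fewer than 3 allele copies are
  available; FST when no site has two genotyped samples per population;
  such windows are excluded from summaries rather than zero-filled.
* Multi-allelic and non-SNP VCF records are dropped (with a logged
  count), not split: downstream statistics assume biallelic sites.
* All coordinates are 1-based inclusive internally; BED export converts
  to 0-based half-open.
* Every stochastic step (permutations, bootstrap, het resolution,
  simulation) takes an explicit seed, and the pipeline manifest records
  them; re-running a pipeline configuration is byte-identical.

## Validation problem sizes

The test-suite experiments use desk-scale versions of the default
conditions, chosen so the whole suite runs in a couple of minutes while
keeping Monte-Carlo error well below the asserted tolerances: FST
recovery on 5000-site single-chromosome cohorts over 20 seeds
(tolerance ±0.05); sweep recovery on a 40-Mb chromosome with a 2-Mb,
10-fold sweep over 20 seeds (mean sensitivity ≥ 0.8, mean base-level
FDR ≤ 0.2); the permutation type-I experiment on two 40-Mb
no-differentiation cohorts with 400 non-overlapping windows.

## Known limitations

* Composite r² differs from haplotype r² when departures from
  Hardy–Weinberg are strong.
* The Tajima's D constants at non-integer mean copy counts are an
  interpolation; windows mixing very different call rates across sites
  are better interpreted through the per-population SNP counts also
  reported.
* The sweep caller's sensitivity degrades when the sweep is much
  narrower than the window size, and region boundaries inherit window
  granularity (±1 window step).
* The generator's sweeps sharpen allele frequencies instantaneously and
  uniformly over the interval; real sweeps have soft shoulders, so
  boundary-error estimates from simulation are optimistic.
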