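---
title: "Models and methods: sex-linked marker discovery and hybrid-zone clines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: sex-linked marker discovery and hybrid-zone clines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radzone)
library(dplyr)
```

radzone bundles two analysis tracks that share data structures but answer
different questions about the same kind of organism — amphibians and other
taxa with labile, poorly differentiated sex chromosomes that meet a close
relative in a hybrid zone:

1. **Which sex is heterogametic?** Sex-linkage scans over RADseq genotypes
   and tag presence/absence, with permutation significance.
2. **How do the two genomes meet in space?** Species-diagnostic SNPs,
   per-individual hybrid indices, per-population admixture statistics, and
   maximum-likelihood geographic clines with exponential introgression
   tails.

Everything is testable offline because the package ships a synthetic-data
module that generates datasets with exactly the statistical structure the
analyses assume.

## Sex-linkage scans

With male heterogamety (XY), a marker carrying a fixed X/Y difference shows
a characteristic signature: every male is heterozygous (one X allele, one
Y-limited allele), every female is homozygous. The Y-limited allele
therefore sits at frequency 0.5 in males and 0 in females. Female
heterogamety (ZW) is the mirror image. Three scans target this signature
from different angles:

* **Method I (allele frequencies)** flags a locus when either allele has
  frequency within `[0.5 - het_freq_tol, 0.5]` in the heterogametic sex and
  at most `hom_freq_max` in the other sex. The predicate is evaluated for
  both alleles so that the ideal pattern is flagged regardless of which
  allele happens to be the REF call.
* **Method II (heterozygosity)** flags a locus when the heterozygote
  fraction is at least `het_het_min` in the heterogametic sex and at most
  `hom_het_max` in the other.
* **Method III (tag dropout)** works on tag presence/absence rather than
  genotypes: a Y- (or W-) borne restriction-site tag has no homolog in the
  homogametic sex, so it is present in most heterogametic-sex individuals
  and in none of the others. The zero is strict; a single presence in the
  wrong sex disqualifies a tag. Presence itself is depth thresholded
  (`tag_presence()`, default 5 reads).

Thresholds are deliberately exposed: real data have genotyping error,
missing calls, and population polymorphism on the sex chromosomes (a
polymorphic Z can mimic XY segregation, which is why `scan_method_II()`
flips between systems as thresholds relax — a behaviour covered in the
tests). Because threshold choice changes the candidate count, significance
and threshold selection are permutation-based (`permutation_test()`,
`optimize_params()`): sex labels are shuffled across the whole sample set
(preserving the observed male/female totals), the scan is re-run per
shuffle (default 100), and the observed count is compared with the null's
95th percentile. The reported p-value uses the add-one estimator
`(1 + #{null >= observed}) / (1 + n_permutations)` so it is never zero. The
per-setting *optimality score* is the mean null count divided by
`max(observed, 1)`; grid search picks the setting minimising it — i.e. the
fewest expected false positives per observed candidate — breaking ties by
larger observed count, then grid order. The default grids span three
heterogametic and two homogametic thresholds for each of methods I and II
and six specificity values for method III.

The RadSex-style track (`radsex_distribution()`, `radsex_test()`)
summarises every tag over the (males present, females present) grid and
tests each tag's 2x2 presence-by-sex table with a Yates-corrected
chi-squared (1 df), Bonferroni-corrected across the testable tags (those
present in at least one and at most all-but-one sexed sample); degenerate
tags are reported with chi-squared 0 and p 1 and excluded from the
denominator.

## Diagnostic SNPs and admixture statistics

Species-diagnostic SNPs are called from reference populations at the two
ends of the transect: a locus qualifies when all non-missing genotypes are
homozygous for one allele across edge group A and for the other allele
across edge group B (`call_diagnostic_snps()`). Fixation tolerates missing
data (default at most 10% per edge group) but never polymorphism, and only
one SNP per RAD tag is kept (the lowest SNP index) so that tightly linked
sites do not pseudo-replicate. The polarity map records which allele is the
southern-species ("B") allele.

For an individual genotyped at `L` panel loci carrying `k` B alleles, the
hybrid index is `q = k / 2L` — the maximum-likelihood ancestry estimate
under binomial sampling of diagnostic alleles, verified in the tests
against a grid-search likelihood maximisation. Interspecific heterozygosity
is the fraction of panel loci that are heterozygous: 1 for an F1, and at
most `2 min(q, 1 - q)` (plus discreteness slack) in general, which gives
the classic triangle plot (`plot_triangle()`). Using allele fractions
rather than a Bayesian clustering posterior is deliberate: for loci fixed
between the parental reference groups the admixture-model posterior mean
coincides with the allele fraction up to sampling noise, and the estimator
is deterministic and fast.

Per population, `population_summaries()` reports the mean hybrid index,
observed heterozygosity `Ho` (heterozygote fraction averaged over panel
loci), composite linkage disequilibrium `ld_r2` (squared Pearson
correlation between dosage vectors, averaged over locus pairs with non-zero
variance — genotypic LD, since phase is unknown), and admixture linkage
disequilibrium `D'`, computed as the variance of the individual hybrid
index within the population. The variance uses the `n` denominator (the
population variance; the convention is not universal, so it is stated
here), which bounds `D'` by 0.25, attained by an even mixture of pure
parentals. Both `Ho` and `D'` peak where parental genomes actually mix,
i.e. at the cline center.

## Geographic clines

The cline core is the tension-zone sigmoid

$$y(x) = \frac{1}{1 + e^{-4 (x - c) / w}},$$

so the width `w` is the inverse of the maximum slope and `y(c) = 0.5`.
Beyond a distance `delta` from the center the sigmoid may hand over to an
exponential introgression tail; on the left side, for `x < c - delta_L`,

$$y(x) = y_L \exp\!\left(\frac{4\,\tau_L\,(x - c + \delta_L)}{w\,(1 + e^{-4\delta_L/w})}\right),
\qquad y_L = \frac{1}{1 + e^{4\delta_L/w}},$$

with the right tail mirrored. The tail meets the sigmoid continuously at
the join by construction, and `tau` in `[0, 1]` sets the tail's decay rate
relative to the sigmoid slope there (tangent-continuous at `tau = 1`).
Configurations `none`, `left`, `right`, `mirror` (one shared tail pair) and
`both` have 2, 4, 4, 4 and 6 free parameters. Frequency asymptotes
`p_min`/`p_max` are fixed at 0/1 by default, appropriate for markers fixed
between the edge reference groups; they can be loosened for partially
diagnostic markers.

Fitting maximises the binomial likelihood of per-population allele counts,
with fitted frequencies clamped to `[1e-9, 1 - 1e-9]` so saturated
populations contribute finite terms. Estimation is multi-start bounded
L-BFGS-B (default 20 starts): the first start uses moment-based initials
(the interpolated 0.5 crossing for the center, the distance between the 0.2
and 0.8 crossings for the width), the rest jitter around them. Default
boxes: center within the sampled range plus/minus 50 km, width in
`[0.1, 2 x span]`, tail lengths in `[0, span]`, tail slopes in `[0, 1]`.
Confidence intervals are profile-likelihood (drop of 1.92 log-likelihood
units), computed for the center and width by default. This is a
deliberately deterministic alternative to the MCMC machinery common in
cline software: given the seed, every fit is exactly reproducible, which is
what the test suite and the pipeline's manifest contract require.

Three honesty guards are built in. Estimates at an optimisation bound are
flagged (`hit_bounds`). A fit with no residual degrees of freedom
(populations <= parameters) is never reported as converged. And a
likelihood that is flat in the width (as with two saturated populations) is
detected by probing the width at half and double the estimate and also
reported as not converged, rather than returning a silent arbitrary
estimate.

`model_select()` compares tail configurations by AIC (`2k - 2 logL`), ties
going to fewer parameters. `fit_all_loci()` fits every locus independently
— with the six-parameter both-tail model by default, for comparability —
and summarises each parameter's distribution by its median and central 95%
range. `tail_asymmetry_test()` then compares left and right tail lengths
and slopes across loci with two-sided paired Wilcoxon signed-rank tests;
loci that did not converge or whose two tail lengths both sit on a bound
are dropped and counted, and at least six usable loci are required.
Identifiability deserves a caveat: when a tail joins the sigmoid deep in
its saturated range (`4 delta / w` large) the likelihood is nearly flat in
that tail's parameters, so single-locus tail estimates are noisy and should
be read distributionally — which is exactly how the asymmetry test uses
them.

## The synthetic-data module

`simulate_sexlinked()` generates the three marker classes the scans
separate: fully sex-linked SNPs (heterogametic sex heterozygous, the other
sex homozygous, before noise), autosomal SNPs in Hardy-Weinberg proportions
at a minor-allele frequency drawn uniformly from `autosomal_maf_range`
identically in both sexes, and sex-specific tags with Poisson read depth
(mean `mean_depth`) in the heterogametic sex only, plus optional background
tags present in both sexes. Genotyping error is a symmetric dosage flip
(`0 -> 1`, `2 -> 1`, `1 -> 0` or `2` with equal odds) — a simple,
documented abstraction of miscalls; missingness and per-sample tag dropout
are independent Bernoulli events.

`simulate_zone()` models populations along a 1-D transect (kilometres from
the northern end). The mean ancestry at position `x` follows the true
cline; each individual draws a hybrid index `h` from a Beta distribution
with that mean and concentration `nu` (shapes `m nu`, `(1 - m) nu`), and
each diagnostic locus is a `Binomial(2, h)` draw of the southern allele.
The Beta draw, rather than explicit pedigree classes, is what generates
admixture structure: the within-population variance of `h` is the Beta
variance `m (1 - m) / (nu + 1)`, so admixture LD and the heterozygosity
deficit both peak at the center and are tunable through one parameter.
Per-locus cline jitter (center shift, log-width scaling) perturbs the
per-locus success probability around the shared cline, and mitotypes are
Bernoulli draws from a separate mitochondrial cline. What this generator
deliberately does *not* emulate: linkage between diagnostic loci beyond
ancestry correlation, drift along the transect, selection against hybrids
as a mechanism (tails are imposed, not evolved), or coalescent noise — so
passing tests demonstrate correctness of the estimators under the stated
sampling model, not robustness to every feature of real RADseq data.
Sequencing-depth artefacts are likewise reduced to the Poisson/dropout tag
model, and full-scale de novo locus assembly is out of scope (the
depth-based genotype filter in `apply_locus_filters()` applies only when
per-genotype depth is available, e.g. from a VCF `DP` field, and is
otherwise skipped with a notice).

## Study conditions used by the tests and the acceptance script

Simulation sizes were chosen once, as realistic desk-scale analogues of a
RADseq hybrid-zone study, and are shared between the test suite and
`scripts/acceptance.R`:

* Sex-linkage recovery: 20 males/20 females, 5,000 autosomal + 20
  sex-linked SNPs, 1% genotyping error, 5% missingness; threshold grids
  optimised with 100 permutations.
* Permutation calibration: 200 replicate datasets of 1,000 autosomal loci
  (10 males/10 females), 100 shuffles each.
* Tag association: 10,000 tags (30 W-specific, 10% dropout, mean depth 20)
  in 21 males/20 females.
* Cline recovery: a 30-population transect spanning 140-230 km with
  two-thirds of populations between 169 and 201 km — hybrid-zone surveys
  concentrate sampling where the gradient is — 40 alleles per population,
  truth `c = 185.9`, `w = 8.6`; per-locus fits use 200 loci jittered
  around `c = 184`, `w = 12` (sd 2 km, log-sd 0.15) on a slightly wider
  layout.
* Tail asymmetry: both-tail fits on 25 symmetric populations (64-304 km),
  width 20 km; calibration uses mirrored tails (`delta = 10`,
  `tau = 0.4`), power uses `delta_R = 3 delta_L` (15 vs 5 km). Tail
  parameters were set so the joins sit in the observable range of the
  sigmoid (see the identifiability caveat above).
* Zone geometry: 23 populations every 4 km across 140-228 km, 40
  individuals each, 40 diagnostic loci, ancestry concentration 5.

## Numerical and design choices, in brief

* Genotypes are alternate-allele dosage `{0, 1, 2}`; phase is ignored
  (every statistic here is phase-free). TSV is the canonical interchange
  dialect; VCF is read-only.
* Missing data: frequencies, heterozygote fractions and hybrid indices are
  computed over non-missing calls only; `q` and heterozygosity for an
  individual always use the same locus set.
* Ties: method I evaluates both alleles, so an exact 0.5/0.5 locus is
  flagged if either allele satisfies the homogametic ceiling; grid
  optimisation ties break toward more observed candidates, then earlier
  grid rows; AIC ties break toward fewer parameters.
* Degenerate inputs error early and informatively: empty sex groups,
  frequency counts out of bounds, all-fixed frequency tables, too few
  populations for the parameter count.
* Determinism: every stochastic function takes an explicit integer seed;
  `run_pipeline()` stamps the seed, package version and per-file MD5 hashes
  into its manifest, and identical configurations reproduce byte-identical
  outputs.
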