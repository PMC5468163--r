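---
title: "Contrasting divergence and introgression in a hybrid zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrasting divergence and introgression in a hybrid zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two historically isolated lineages meet again in secondary contact,
two questions can be asked of the same SNP panel. First, which loci became
unusually differentiated *between* the parental lineages while they were
apart — candidates for divergent selection? Second, which loci resist (or
exaggerate) gene flow *within* the admixed zone — candidates for selection
against or for introgressed alleles? `hybridclines` implements both
analyses and the comparative layer that connects them, for biallelic SNP
panels of the RADseq kind (one SNP per locus, two parental populations
labelled `west` and `east`, plus an `admixed` population).

All statistics operate on allele counts at single sites, so missing
genotypes simply drop out of the counts; no imputation is performed and no
missingness threshold is applied (a per-locus `missing_fraction` column is
reported instead).

## Divergence side

`compute_locus_stats()` produces, per SNP, from non-missing parental
alleles only:

* **pi** (within-population diversity): the unbiased per-site
  heterozygosity `2p(1-p) n/(n-1)`, the mean pairwise difference over
  sampled alleles. `delta_pi = pi_east - pi_west` is signed: positive at
  loci more diverse in the east.
* **FST**: Weir–Cockerham's variance-components estimator in its
  haploid-sample (allele-count) form, negative estimates clamped to zero.
  The allele-count form treats each sampled allele as the sampling unit,
  the natural contract for RAD data with missingness; genotype-aware
  implementations may differ in the third decimal.
* **dxy**: the probability that two alleles, one from each population,
  differ: `p_w(1-p_e) + p_e(1-p_w)`. Reciprocally fixed sites give exactly
  1, which forces the per-SNP (not per-locus-average) reading of dxy.

`mahalanobis_distances()` scores each locus's `(fst, dxy, delta_pi)`
vector by its covariance-scaled distance from the genomic centroid;
`delta_pi` enters *signed* so that loci extreme in either direction score
high. `classify_divergence_outliers()` flags loci above the empirical 95th
(outlier) and 99th (strong) distance quantiles — type-7 quantiles, strict
`>` — and the `retained` set additionally requires `fst > 0.2`, removing
high-distance loci whose signal is low differentiation (putative balancing
selection) rather than elevated divergence.

## The neutral reference: posterior-predictive coalescent simulation

High FST alone does not imply selection: drift under a given demography
produces its own tail. `build_null_distribution()` simulates that tail
under a strict two-population isolation model. For each posterior draw of
`(theta_west, theta_east, theta_anc, tau)` — e.g. from a species-tree
analysis of the parental populations, or `make_pseudo_posterior()` for a
stand-in — it simulates independent loci (default 100 per draw, 190 sites
each): a coalescent genealogy in mutational units (pairwise coalescence at
rate `2/theta` within each population, lineages pooled into the ancestral
population at time `tau`), JC69 mutations at rate one per site per unit
branch length, one polymorphic biallelic site sampled per locus, and FST
and dxy computed on it with the same operators as the empirical panel.
Monomorphic loci are skipped and counted, making the ascertainment of a
SNP panel explicit. Sample sizes per locus are drawn from configurable
coverage distributions, mirroring uneven sampling across RAD loci.

`compare_binned()` then contrasts empirical and simulated distributions in
width-0.1 bins by two-sided Fisher exact tests (reported raw, no
multiple-testing correction across bins), and
`estimate_false_positive_rate()` reports the capped ratio of simulated to
empirical mass in a chosen range — the expected fraction of neutral loci
per observed locus there.

Two unit conventions are made explicit because they are easy to get wrong:
`theta` and `tau` are per-site mutational quantities (`theta = 4N mu`,
branch lengths in expected substitutions per site), so the pairwise
coalescence rate is `2/theta`; and the expected between-population raw
divergence is `2 tau + theta_anc`, while within-population diversity
equals `theta` only in the long-isolation limit — at short `tau` the exact
truncated-coalescent expectation applies (both are tested against frozen
estimates from an independent coalescent simulator).

## Introgression side: Bayesian genomic clines

`fit_genomic_clines()` estimates, by MCMC, each admixed individual's
hybrid index `h` (eastern genome fraction) and per-locus cline parameters
`alpha` (center) and `beta` (rate) of

```
Phi = h + 2 h (1 - h) (alpha + beta (2 h - 1)),   truncated to [0, 1]
```

where `Phi` is the probability that a gene copy derives from the eastern
parent; with `alpha = beta = 0`, `Phi = h`. Admixed genotypes are
`Binomial(2, Phi p_e + (1 - Phi) p_w)`; parental allele counts enter as
binomial likelihoods, anchoring the orientation (positive `alpha` = excess
eastern ancestry) and propagating parental-frequency uncertainty.

Two implementation choices matter and were forced by experiment rather
than taste:

* **Hierarchical locus-effect scales.** `alpha_i ~ N(0, sigma_a^2)` and
  `beta_i ~ N(0, sigma_b^2)` with inverse-gamma hyperpriors, Gibbs-updated.
  With a *fixed* wide `alpha` prior the marginal posterior of the
  genomewide `h` level is degenerate: at off-center `h` the factor
  `2h(1-h)` shrinks, each `alpha_i` becomes less data-constrained, and the
  posterior volume gained across hundreds of loci outweighs the prior cost
  of the compensating shift — the fitted `h` drifts far from truth (we
  reproduced the drift with a second, independently written sampler, so it
  is geometry, not a bug). Estimating the scales removes the degeneracy.
  `hierarchical = FALSE` restores fixed scales for comparison.
* **A ridge proposal.** The `h` level and the mean of `alpha` trade off
  along a near-flat direction (`dPhi = dh + 0.5 dalpha` at `h = 0.5`).
  Single-parameter updates mix across it extremely slowly, so each sweep
  adds a few joint random-walk proposals along the fixed direction
  `(dh, dalpha) = delta(1, -2)`, which is symmetric and needs no Jacobian.

Proposals are reflected at bounds and adapt toward 20–50% acceptance
during burn-in only (defaults: 25,000 iterations, 2,500 burn-in, thin 5).
Effective sample sizes are reported; the warning threshold ignores `beta`,
which the hierarchical scale typically shrinks to near zero where its slow
chain is harmless. The returned `cline_fit` object has `print`, `summary`,
`coef`, `predict` (which reconstructs `Phi`) and `plot` methods.

`classify_excess_ancestry()` calls a locus `east` when its 95% equal-tail
`alpha` interval excludes 0, the median is positive, *and* the median lies
above the 97.5th percentile of the genomewide median-`alpha` distribution
(`west` symmetric). "Tails of the 95th quantile" is read as outside the
central 95%; the strong-outlier gamma-quantile rule is read as `q < n/2`
or `q > 1 - n/2` with `n = 0.1` (the interval as conventionally printed,
`1 - n/2 < q < n/2`, is internally inconsistent). Gamma-quantiles use a
normal fitted to the median-`alpha` distribution (an empirical-rank mode
exists in `gamma_quantiles()` internally).

## Comparative layer

`correlate_divergence_introgression()` reports Pearson correlations of
`|alpha|` with `fst`, `dxy`, `|delta_pi|` and the Mahalanobis distance
(magnitudes for the signed quantities, since the hypothesis concerns
strength, not direction). `overlap_resampling_test()` draws 1,000
equal-sized random gene sets from the background (all genes linked to any
analysed locus, counted once) and uses the `+1`-corrected tail
probability, plus the 95th-null-quantile significance rule.
`candidate_enrichment_test()` is the exact hypergeometric test, one-sided
(enrichment) by default because every use is an enrichment claim, with a
0.5 continuity correction on the odds ratio when a cell is empty.
`ancestry_symmetry_test()` is the exact two-sided binomial test of
east-vs-west outlier counts against 0.5.

## The synthetic world

The generators state one world and keep it:

* `simulate_divergent_parentals()`: 24 + 24 diploids by default, loci drawn
  from the isolation coalescent at `theta_west = 0.0592`,
  `theta_east = 0.217`, `theta_anc = 0.0615`, `tau = 0.00578` (posterior
  means typical of a deeply structured snake system); truth frequencies are
  the site frequencies of a 50+50-allele pseudo-sample conditioned on
  polymorphism. A planted fraction (default 5%) of "divergent" loci has
  frequencies shifted apart by `p ± boost · min(p, 1-p)` (monotone in the
  boost, but deliberately gentle on rare alleles — most coalescent variants
  are rare, so planted-locus recovery by outlier scans is partial by
  construction, and tests assert enrichment rather than full recovery).
* `simulate_admixed()`: the generative inverse of the cline model; default
  hybrid indices on a uniform grid over [0.2, 0.8], mimicking a broadly
  admixed zone (empirical analogues center near 0.46).
* `simulate_null_admixed()`: 21 individuals, 5 replicates by default; each
  allele drawn by picking a parental population uniformly (50/50) and then
  an observed allele at that locus — the neutral benchmark for the
  excess-ancestry classifier.
* `generate_gene_annotations()`: two genes (up/down) per locus;
  candidate sets over-represent divergent-linked genes by a configurable
  factor, with uniform sets as negative controls.

What the generators do *not* emulate: linkage within loci, migration
during divergence, spatial structure, genotyping error, and allele-drop
artefacts of real RAD data. A green test therefore establishes correctness
of the estimators and classifiers under the stated model, not robustness
to those real-data pathologies.

Recovery tests are designed where their estimand is identifiable: planted
`alpha` loci are placed among ancestry-informative loci (parental
frequency difference > 0.3), because a cline center is meaningless where
the parents do not differ; and the hybrid-index recovery check (±0.1) uses
a deeply diverged pair (`tau = 1`), since at the default `tau` the Fisher
information bound alone puts the per-individual posterior sd near 0.13.
The null-admixture benchmark runs exactly at the default (paper-scale)
parameters.

## Numerical choices and degenerate inputs

* Quantiles are type-7 with strict `>` for outlier flags; ties therefore
  never inflate the outlier count.
* Near-singular covariances in the Mahalanobis step are ridged by
  `1e-8 · trace(S)/dim` with a warning; exact singularity after ridging is
  an error.
* `wc_fst` returns 0 for sites monomorphic across both samples (no
  information), 1 exactly at reciprocal fixation, and `NA` when either
  population has fewer than two alleles.
* Genotype probabilities in the MCMC are clamped to `[1e-9, 1 - 1e-9]`;
  parental frequencies are reflected inside `(0, 1)`.
* Half-missing VCF genotypes (`./1`) are treated as fully missing.
* Resampling p-values use the `+1` correction and cannot be zero.
* All generators and the sampler run under a locally seeded RNG and
  restore the caller's RNG state; identical seeds give byte-identical
  output.

## Scaling of the shipped checks

Chain lengths and replicate counts in the test suite are scaled to a
single-CPU budget (e.g. 10,000 iterations instead of 25,000; 2 null
replicates instead of 5; hundreds rather than thousands of simulated
loci). The quantities asserted are unchanged; only their Monte-Carlo
resolution is reduced.

## Known limitations

* The cline model's `beta` is weakly identified at moderate panel sizes;
  its posterior is dominated by the hierarchical shrinkage scale, matching
  the empirical observation that rate estimates rarely exclude zero.
* FST/dxy at a single site are coarse; the package deliberately has no
  sliding-window or haplotype statistics.
* The isolation null has no migration; for systems where post-contact
  gene flow is strong, the posterior-predictive null is conservative in
  the low-FST bins.
* The BLAST orthology search that produces the locus-to-gene table is out
  of scope; the table is consumed pre-computed (or simulated).
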