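---
title: "Window-variance GWAS for feed-efficiency traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window-variance GWAS for feed-efficiency traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

feedqtl maps QTL for feedlot feed-efficiency traits by partitioning the
additive genetic variance captured by a Bayesian whole-genome regression
into non-overlapping 1-Mb genome windows, and calling windows whose
variance share is improbable under a permutation-derived null. This
vignette is the package's account of the underlying models, the
parameters that matter, the numerical choices, and what the simulator
does and does not emulate.

## Traits

Feeding trials record serial body weights and daily feed intakes per
animal. From these the package derives, per animal:

* **ADG** (kg/d): the ordinary least-squares slope of weight on day on
  feed. All available weights enter; two weights on adjacent days at the
  start and end of the test (a common commercial design) are just four
  observations to the same regression.
* **Mid-test weight** (kg): the fitted value of that regression at the
  midpoint of the first and last weigh day. "Mid-test" is not defined
  more precisely by convention; the midpoint of the weigh-day range is
  symmetric and reproducible, and with an (approximately) regular
  weighing schedule coincides with the mean weigh day.
* **MBW** (kg^0.75): mid-test weight raised to the power 0.75, the
  classical metabolic scaling of maintenance requirements.
* **DMI** (kg/d): the mean daily as-fed intake over the test multiplied
  by the ration's dry-matter fraction. Days with missing intake records
  are simply absent from the mean.
* **RFI** (kg/d): feed intake adjusted for growth and body size. RFI is
  *not* pre-computed as a phenotypic residual; instead the DMI analysis
  is re-run with ADG and MBW added as linear covariates
  (`build_design(trait = "RFI")`), so the marker effects estimated in
  that model pertain to intake variation independent of growth and size.
  A classical residual (`classical_rfi()`) exists only as a convenience
  for simulator checks.

Contemporary groups (trial x farm x year x season x sex cohorts) are
taken as given labels and fitted as fixed effects; the package never
infers them. Breed composition and expected heterosis
(`expected_heterosis()`: one minus the probability that both alleles
derive from the same breed, computed from parental breed fractions) can
be added as covariates for admixed designs.

## Genotype QC

Filters run animals first, then markers, each with a fixed rule order so
every exclusion carries one deterministic primary reason:

* animals: call rate < 0.90; autosomal heterozygosity > 0.45; predicted
  Klinefelter (XXY).
* markers: call rate < 0.85; MAF < 0.001; Hardy–Weinberg P < 3x10^-9
  (autosomes); heterozygosity > 0.03 in males for non-pseudo-autosomal X
  and Y markers; heterozygosity > 0.03 for mitochondrial markers.

Sex is assigned from non-pseudo-autosomal X heterozygosity and, on the
high-density assay, the Y-marker call rate (males are hemizygous X, so
apparent X heterozygosity above a genotyping-error allowance of 0.03
indicates two X chromosomes; Y call rate ≥ 0.5 indicates a Y). The one
combination the rules leave open — low X heterozygosity with a low Y
call rate on the HD assay — is assigned male with a warning, since low X
heterozygosity is the primary male criterion. The pseudo-autosomal
region is a separate chromosome label (`paX`) supplied by the marker
map; no coordinate-based inference of the boundary is attempted.

The Hardy–Weinberg test defaults to the 1-df chi-square goodness-of-fit
test standard for array QC; an exact test is available
(`hwe_pvalue(method = "exact")`). At the deep-tail threshold of 3x10^-9
the two agree on the decision for any marker with non-trivial counts.
Monomorphic markers return P = 1 and are removed by the MAF rule
instead, avoiding 0/0 in the chi-square. QC order (animals before
markers) matters only marginally; both stages are idempotent.

Missing genotypes that survive QC are mean-imputed per marker and every
marker column is centered (`impute_and_center()`). Mean imputation keeps
the package self-contained; on real multi-platform data one would
LD-impute externally first, and the imputation step here simply accepts
whatever codes arrive.

## The BayesB model

For n animals and M markers,

y = X b + Z a + e,

with X the fixed-effects design (intercept, contemporary-group
indicators in drop-first coding, covariates), Z the centered genotype
codes, and a mixture prior on marker effects: a_j = 0 with probability
pi; otherwise a_j ~ N(0, sigma2_j) with locus-specific variance
sigma2_j ~ scaled-inv-chi-square(nu_alpha, S2_alpha). The residual
variance has a scaled-inv-chi-square(nu_e, S2_e) prior and b a flat
prior.

**Sampler.** A single-site Gibbs sampler (C++): each fixed effect from
its normal conditional; each marker's inclusion indicator from the
conditional odds with the effect integrated out given the current locus
variance, its effect (when included) from the normal conditional, and
its locus variance from the exact scaled-inverse-chi-square conditional
when included and from the prior when excluded; the residual variance
from its conditional. We use the exact locus-variance conditional rather
than a Metropolis update because it is available in closed form, needs
no tuning, and mixes at least as well. Residuals, genomic values
g = Z a and per-window genomic values are maintained incrementally, so
one iteration costs O(nM). Chains are bit-for-bit reproducible given
the spec seed.

**Key parameters.**

* `pi` — prior proportion of null markers. The guiding calibration is
  the expected number of markers fitted per iteration, (1-pi)·M: around
  500 for a 50K panel (pi = 0.99) and around 400 for a 770K panel
  (pi = 0.9995). For the package's simulated 2,000-marker panels we use
  pi = 0.9 (about 200 fitted) by the same logic; very sparse settings
  underestimate h2 there because too few markers are available to tag a
  polygenic background through modest LD.
* `n_iter`, `burn_in` — default 41,040 and 1,000. Test-scale analyses in
  this package use 4,000/1,000, which is posterior-stable for the sizes
  involved (repeating with different chain seeds moves window shares by
  far less than their across-dataset spread).
* `nu_alpha = 4.2`, `nu_e = 10` — conventional whole-genome-regression
  defaults. The locus-variance scale derives from a user-suppliable
  assumed genetic variance (default: half the response variance) divided
  by (1-pi)·M times the mean marker variance; the residual scale from an
  assumed residual variance (default: the other half). These priors are
  weakly informative at the default chain lengths.

**Outputs.** V_A per saved iteration is the empirical variance across
animals of g (not sum 2 p_j q_j a_j^2), which makes the window shares
internally consistent with the total; V_E is the residual-variance
sample; h2 is reported both as the posterior mean of per-iteration
ratios (default) and as the ratio of posterior means — they differ
negligibly in practice and both are serialized. The per-marker sPPI is
the fraction of post-burn-in samples in which the marker is in the
model.

## Window variance partitioning and significance

Windows are half-open 1-based megabase bins: positions 1..10^6 on
chromosome 7 are window `7_0`, a site at 23,456,789 bp is in `7_23`.
Per saved iteration a window's share is
100 · var(sum of its markers' genomic values) / var(g), zero when
var(g) is zero; the reported %V_A is the posterior mean. Shares sum to
exactly 100 only when cross-window genotype covariance vanishes;
relatedness and long-range LD make individual window variances overlap,
so sums around 85–110 are normal.

The null distribution comes from permutation: genotype rows are randomly
reassigned against (response, fixed-effects) rows — preserving the trait
distribution and its relation to the systematic effects while destroying
genotype–phenotype association — and the identical model is re-run; all
windows' posterior-mean shares from all replicates pool into one null
sample. One replicate (a null the size of the window count) is the
minimal paper-faithful layout; ten or more replicates give a visibly more
stable tail and are the recommended default for real analyses. Whether
to permute within contemporary groups is a judgment call; the default
permutes whole phenotype rows, which also randomises group assignment
and is slightly conservative.

A Johnson Su distribution — z = gamma + delta·asinh((x-theta)/sigma)
standard normal; gamma, delta shapes, theta location, sigma scale, all
on the percent scale — is fitted to the pooled null by maximum
likelihood, with quantile-matching (Slifker–Shapiro-style spread ratios)
plus fixed fallback starts, delta and sigma kept positive on the log
scale, BFGS, best of multi-start by likelihood; -2·logLik is serialized
with the parameters. The unbounded Johnson family is a natural
parametric model here: null shares are strictly positive-ish,
right-skewed, and near-lognormal in the body but with a heavier upper
tail. Nominal P-values are the fitted upper tail at the observed share;
the Bonferroni correction multiplies by the number of windows actually
tested in that population (platforms differ in window counts), and
corrected P < 0.05 calls a QTL. A per-trait parameter map supports
reusing one trait's null for another when a trait's own null fit is
ill-behaved. Lead-SNPs are the window's top-sPPI marker, ties broken by
smaller bp then id.

Two numerical notes: the Johnson Su quantile/cdf round-trip degrades in
double precision beyond |z| ~ 8 (upper-tail probabilities below ~1e-15),
which is far past any decision threshold; and published-table
reproduction of deep-tail P-values from 3-decimal-rounded parameters is
order-of-magnitude only — with the published DMI null parameters the
largest DMI window's share of 10.39% gives an upper tail of 4.2x10^-10
against a printed 3.0x10^-10.

## The simulator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, at a default scale modelled on a single-herd progeny test: 40
sires with Poisson family sizes averaging 21.2, unobserved unrelated
dams, 10 contemporary groups, and default h2/V_A values in the ranges
reported for these traits (ADG 0.27/0.02, MBW 0.50/24, intake deviation
0.45/0.32).

* **LD** comes from blockwise copying out of a small haplotype pool:
  every gamete copies each 1-Mb block intact from one pool haplotype, so
  within-window LD is strong and cross-window LD is negligible by
  construction. `pool_size` controls haplotype diversity (smaller =
  stronger LD).
* **Breeding values** are planted window-QTL effects (a few causal SNPs
  per window, scaled so each window explains exactly its configured
  fraction of the trait's additive variance) plus a polygenic background
  balanced across windows: each window's background component is scaled
  to an equal share of the background variance and orthogonalised
  against any QTL component in the same window. The realized variance
  decomposition therefore matches the nominal architecture essentially
  exactly, which is what makes recovery tests interpretable. Cross-trait
  correlation enters through shared background effects (default: ADG–MBW
  0.6, intake deviation independent).
* **Phenotypes** add contemporary-group effects and normal residuals
  sized for the target h2. DMI is composed as partial regressions on the
  ADG and MBW phenotypes (defaults 1.5 kg DM per kg/d gain, 0.09 kg DM
  per kg^0.75) plus its own deviation, so the deviation carries the true
  RFI signal.
* **Records**: weights follow the linear growth line implied by ADG and
  mid-test weight plus weighing error (3 kg default); intakes are
  constant at DMI / dry-matter fraction plus day-to-day noise (1 kg
  default). With zero noise the derivation stage recovers the latent
  traits exactly.

What the simulator does **not** emulate: recombination within blocks,
mutation, selection, platform ascertainment, multi-generation pedigrees,
genotype–environment interaction, non-normal residuals, intake-recording
artefacts. Passing tests therefore demonstrate correctness of the
machinery under the assumed statistical structure, not robustness to
real-data pathologies.

## Power at test scale, and the choices behind the fixtures

The bundled recovery fixture (`recovery_config()`: n ≈ 500, M = 2,000 in
20 windows, two windows planted at 5% of V_A on 2 causal SNPs each,
h2 = 0.40, haplotype pool of 8) deliberately sits at the edge of what
this design can resolve. A 5%-of-V_A window is about 2 percentage points
of phenotypic variance; at n ≈ 500 the posterior window share has a
standard error of the same order, driven by chance association between
window haplotypes and the non-genetic variation. In repeated simulation
the true variance decomposition always ranks the planted windows first
and second, the analysis ranks *at least one* of them in the top 3 in
about 95% of datasets and *both* in about 45% — and h2 lands within
±0.10 of truth essentially always. This mirrors field experience: studies
at n below ~1,000 reliably detect only windows explaining well above 5%
of additive variance. The test suite asserts the h2 property strictly;
the joint rank property is asserted at its face value and its failures
should be read against this power analysis.

The null fixture (`null_config()`: n ≈ 300, M = 1,000, no QTL) is used
for family-wise error control: across 20 datasets, each analysed against
its own 5-replicate permutation null, at most one dataset should yield
any Bonferroni-significant window, and pooled null shares evaluated
against their own fitted Johnson Su law have near-uniform P-values
(Kolmogorov–Smirnov statistic < 0.05 at N = 2,000).

Problem sizes in the test suite (chains of a few hundred to 12,000
iterations, panels of 20–2,000 markers) were chosen as the smallest at
which the checked property is stable; the defaults users see
(`bayesb_spec()`) remain the full-scale settings.

## Interfaces

All tabular inputs and outputs are TSV with documented headers
(coded genotype matrix, marker map, weights, intakes, QC reports, QTL
tables mirroring the published column set, null-parameter tables,
Manhattan data); VCF input is supported through vcfR. Fitted objects are
plain lists of tibbles with `tidy()`/`glance()`/`autoplot()` methods, so
results compose with dplyr/ggplot2 workflows.
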