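---
title: "Methods: pooled-GBS germplasm characterization with poolscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-GBS germplasm characterization with poolscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`poolscape` analyses germplasm collections genotyped as population bulks.
Because the unit of observation is a population allele frequency rather
than an individual genotype, every statistic in the pipeline is defined on
frequencies. This vignette records the models, the assumptions behind
them, the numerical choices, and what the synthetic-data generator does and
does not establish.

## 1. Allele frequencies from pooled counts

The estimator is the read-count ratio `AAF = Alt / (Alt + Ref)` after
summing counts over technical replicates. Summing is deliberate: the merged
frequency is the depth-weighted mean of replicate frequencies, which is the
maximum-likelihood estimate under binomial read sampling, whereas an
unweighted mean of replicate AAFs would up-weight shallow replicates.

Conventions that matter downstream:

* **Zero depth is missing, not zero.** A cell with no reads carries no
  information; the coverage filter needs to distinguish "absent" from
  "fixed for the reference allele".
* **Filters use open intervals and a strict coverage fraction.** "Greater
  than 95% of samples" is a strict `>`; a locus observed in exactly 95% of
  populations fails. Frequency bounds (0.05, 0.95) are open, so a locus
  fixed at exactly 0.05 is excluded. Both are configurable
  (`filter_spec()`), since the prose definitions are ambiguous at the
  boundary.
* **Imputation** replaces missing cells by the per-locus mean over observed
  populations. It preserves per-locus means exactly and never touches
  observed cells; it shrinks imputed populations toward the collection
  mean, which slightly understates their distinctiveness.
* **VCF ingestion** reads per-sample `AD` (ref, alt) and skips
  multi-allelic records with a warning; the pipeline is defined for
  biallelic SNPs.

## 2. Distances, diversity, differentiation, AMOVA

*Modified Rogers Distance* on biallelic frequencies reduces to
`sqrt(mean_l (p_xl - p_yl)^2)`, bounded in [0, 1], invariant to ref/alt
relabeling and locus order.

*Expected heterozygosity* is `mean_l 2p(1-p)` per population (≤ 0.5 for
biallelic loci). Whether He should be computed on raw or imputed
frequencies is not decidable from first principles; the pipeline computes
it on imputed frequencies (a flag away from raw), since imputation
preserves locus means.

*Pairwise cluster FST* is a Nei-type ratio of sums,
`FST = Σ(HT - HS) / Σ HT`, over the member populations of each cluster
pair: only frequencies are observable for pools, so genotype-based
estimators (Weir–Cockerham) are not applicable. This estimator measures
total among-population differentiation within the pair of clusters, which
is larger than the between-cluster-mean contrast when populations vary
within clusters. Published FST values are therefore not reproduction
targets; the algebraic transform to gene flow, `Nm = (1-FST)/(4·FST)`, is,
and reproduces the published gene-flow table at printed precision.
Classification bins are lower-inclusive and half-open: differentiation
little [0, 0.05), moderate [0.05, 0.15), great [0.15, 0.25), with values
above 0.25 labelled "very great" (an extension beyond the published bins);
gene flow low [0, 0.25), medium [0.25, 1), high ≥ 1.

*AMOVA* partitions squared Modified Rogers Distances across nested strata
(clusters ⊃ countries ⊃ populations), with populations as the units. Sums
of squares follow the standard identity `SS(group) = Σ_{i<j} d²_ij / n`;
variance components use the unbalanced nested-design coefficients; country
groups are formed as (cluster, country) combinations so nesting holds even
when a country spans clusters — the published table's inconsistent country
degrees of freedom (21 for 15 named countries) suggests the original
grouping did something similar, but it is not recoverable, so the module
computes df from the actual label sets. Significance uses 999 seeded
permutations: populations among clusters for the top stratum, populations
among countries within their cluster for the middle one.

## 3. Population structure (DAPC)

The pipeline is PCA → k-means over K = 1..Kmax → linear discriminant
analysis, with membership probabilities from Mahalanobis distances under
the pooled within-class covariance and equal priors (ties break to the
lowest cluster index).

Numerical/design choices:

* **BIC convention** is the Gaussian-profile k-means form
  `BIC(K) = n ln(WSS_K/n) + K ln(n)`; K = 1 uses the total centred WSS.
* **The K search runs on all PCs; the discriminant step on few.** With only
  a handful of axes, k-means can split true clusters and keep lowering the
  BIC (small clusters overfit in low dimensions); with the full score
  space, a spurious split frees a negligible WSS fraction and the penalty
  dominates, so the BIC minimum sits at the true K. The discriminant step
  then uses the a-score-selected count (default 7) to avoid overfitting
  class boundaries. This split mirrors standard DAPC practice.
* **a-score** = observed correct-reassignment proportion minus its mean
  over label permutations (default 10), seeded.
* **chosen_k can be overridden** in the pipeline configuration: selecting
  the cluster number is ultimately a judgment call against external
  (geographic) information, and the BIC profile is always reported.
* Frequencies are centred but not unit-scaled before PCA by default
  (scaling is a flag); loci with higher diversity legitimately carry more
  structure signal on the frequency scale.
* Single-member clusters make the within-class scatter singular; a ridge
  of `1e-6 * mean(diag(W))` is added when the reciprocal condition number
  falls below 1e-10.

## 4. Relationship matrices

The genomic relationship matrix treats the pooled frequency as the
population's mean dosage: `M = 2·AAF` in [0, 2], recoded to `Z = M - 1`,
centred by locus means, `G = Z_c Z_cᵀ / (2 Σ p̄(1-p̄))` with `p̄` the mean
observed frequency (VanRaden method 1 adapted to population-level
dosages; a "reference 0.5" denominator is available since the original
choice is not recoverable). Monomorphic loci are dropped with a warning; a
1e-8 diagonal ridge guarantees invertibility in the mixed model. On
population frequencies the diagonal is well below 1 — entries are
variances of population *mean* dosages, not individual dosages; the usual
`mean(diag(G)) → 1` behaviour is recovered when individual Hardy–Weinberg
genotypes are supplied, and the tests check exactly that.

The pedigree numerator matrix uses the tabular recursion
(`A(i,i) = 1 + 0.5 A(sire, dam)`, `A(i,j) = 0.5[A(j, sire) + A(j, dam)]`)
after a topological sort; parents without pedigree rows become implicit
founders (logged), cycles are an error, and `F = diag(A) - 1`. An
all-founder collection yields the identity — the situation the package is
designed around, where pedigree information is uninformative and the
G-matrix must carry the covariance structure.

## 5. REML variance components and heritability

The trial model is a Gaussian mixed model with fixed year/location/season
effects and random population (covariance `G σ²_p`), population ×
season/year/location interactions, design terms and residual. Estimation
is REML through the mixed-model equations: average-information updates
with EM steps as fallback (first two iterations, and whenever an AI step
leaves the parameter space after 10 halvings), convergence at
`|Δ logREML| < 1e-6`, components constrained non-negative with boundary
fixing at zero (a component pinned at the floor of `1e-8 · var(y)` on
consecutive iterations is frozen and reported as 0). The restricted
likelihood is evaluated exactly (`-2ℓ = log|R| + log|G| + log|C| + y'Py`)
and the tests verify both the value and a numerical gradient against a
direct dense-V implementation; standard errors come from the inverse AI
matrix. Terms confounded with the residual (one level per observation,
identity covariance) are dropped with a warning; aliased fixed-effect
columns are removed by pivoted QR; fixed factors with a single observed
level (e.g. location in a single-site analysis) are dropped silently, which
is what "altered depending on the analysis" requires operationally.

Interaction significance uses `2Δ logREML` against the boundary mixture
`0.5 χ²₀ + 0.5 χ²₁` (a variance component sits on the boundary of its
parameter space under the null), with stars at 0.05 / 0.01 / 0.001.

Heritability on the population-mean basis is
`h² = σ²_p / (σ²_p + σ²_pb/n_r + σ²_ps/n_s + σ²_py/n_y + σ²_pl/n_l +
σ²_e/(n_r n_s n_y n_l))`. The residual divisor is interpreted as the
product of the effective replicate/season/year/location counts *of the
analysis at hand* and generalized accordingly; the published fixed product
("2·4·3·2") is inconsistent with the three assessed seasons and the
replicate-interaction component is never tabulated, so printed h² values
are treated as magnitude checks (the single-site across-years biomass
inputs give 0.82 against a printed 0.81), not exact targets.

GBLUPs are the BLUPs of the population term; for the trait biplot they are
z-scored per trait before PCA (the original scaling is unstated; per-trait
standardization makes traits with different units commensurable).

## 6. Landscape genomics

Predictor pruning removes, while any pair of variables correlates at
|r| ≥ 0.8, the member of the worst pair with the larger mean absolute
correlation to the remaining variables (ties to the higher Bio index);
zero-variance variables are dropped first. The rule is deterministic and
the tests check it against an independent re-implementation.

RDA standardizes predictors, centres the response (z-scores it for trait
responses), and decomposes the multivariate least-squares fitted values by
SVD; eigenvalue fractions are taken over the total response inertia, so
"constrained proportion" is the multivariate R². The implementation is
checked to 1e-8 against both a naive regression+eigendecomposition oracle
and `vegan::rda`.

Candidate SNPs are loci whose loading on any of the first 3 axes (the
number of axes displayed in such studies; config-exposed) lies more than 3
SD from that axis's mean loading; loadings are the unit-norm right
singular vectors, and since the 3-SD rule is applied per axis, any
per-axis rescaling convention gives identical candidates. Each candidate
is assigned the bioclim variable with the largest |Pearson r| (ties to the
lower Bio index), with two-sided correlation-test p-values and
Benjamini–Hochberg q-values computed *across the candidate set* (the
published correction is scoped to candidates, not all loci). The cluster
association test builds cluster × allele tables from rounded pooled allele
counts (`2 · pool_size · AAF`) and uses the uncorrected chi-square
statistic, BH-adjusted; tables with > 20% of expected cells below 1 are
flagged low-reliability. Nearest-gene annotation assigns "within" when the
SNP lies inside the gene span, otherwise the nearest gene whose boundary
is within 3,000 bp (so 2,999 bp qualifies and 3,001 bp does not), with
upstream/downstream defined relative to gene strand (5′ flank = upstream;
a strand-naive flag is available since the original convention is
unstated).

## 7. What the synthetic world is — and is not

The generator states one world and the tests interrogate it:

* **Drift structure.** Ancestral frequencies are Uniform(0.05, 0.95);
  cluster frequencies follow the Balding–Nichols beta model at F = 0.06,
  which has a known FST expectation (the calibration test checks Hudson
  FST between cluster frequency vectors to ±0.015); populations add
  Gaussian perturbation on the frequency scale.
* **Within-cluster SD = 0.12.** The magnitude of among-population
  differentiation within clusters is genuinely unstated in the motivating
  study; 0.12 was chosen so the simulated collection reproduces the
  study's qualitative AMOVA partition (the clear majority of molecular
  variance among populations, not among clusters), keeps the seven
  clusters recoverable from both true and pooled-measured frequencies, and
  gives the G-matrix enough within-cluster rank that the population
  variance component has realistic precision (with a near-rank-7 G the
  component has ~6 effective degrees of freedom and its Wald intervals are
  meaningless).
* **Pooling and sequencing.** A bulk draws `2 · 30` alleles binomially
  (the dominant noise source at typical depths), then each of 4 technical
  replicates draws a Poisson(20) depth and binomial reads; 2% of
  (population, locus) cells drop out entirely to exercise the coverage
  filter.
* **Climate.** Seven core gradients with cluster-level means, the first
  three markedly dominant (the constrained climate spectrum of such
  collections concentrates in the leading axes; in the motivating study
  the first two constrained axes carry two thirds of the climate-aligned
  variation), plus collinear copies (|r| ≈ 0.97) to exercise pruning.
  Adaptive loci add `slope · z(driver)` on the logit scale on top of their
  drift background — slope 0 leaves them exactly as generated — with
  drivers drawn from the three dominant cores at the 69:9:44 proportions
  of the study's candidate split.
* **Phenotypes** come from the same mixed model the estimator fits, with
  default magnitudes taken from the study's printed single-site biomass
  components, in a balanced row-column layout with i.i.d. row/column
  effects (no spatial autocorrelation).

What a green test therefore establishes: estimator correctness against
independent oracles, recovery of planted structure under the stated world,
and calibrated error rates under exchangeable nulls. What it does not
establish: reproduction of the study's data-dependent numbers (4,509
retained SNPs, He of 0.08–0.17, the exact AMOVA percentages, specific PC
and RDA percentages, per-trait h² values). Those depend on the undeposited
raw data. Notably, with a Uniform ancestral spectrum the expected
heterozygosity is ≈ 0.35, far above the published 0.08–0.17 band — the
band would require a strongly MAF-skewed spectrum that the stated world
does not include; the tests assert the biallelic bound and exactness on
fixtures instead.

## 8. Known limitations

* The pool FST estimator ignores the finite pool size and read depth as
  error terms; no genotype-likelihood model for pools is included.
* Single-trait REML only; no spatial (AR1×AR1) residual models.
* The GEA scan is a plain RDA without latent-factor correction for
  population structure, so in strongly structured collections the
  candidate set is enriched for, but not free of, structure-confounded
  loci; the cluster chi-square column exists precisely to flag that.
* GO annotation/enrichment and map rendering are out of scope.
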