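---
title: "Signed pathway scores and permutation inference in pathburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed pathway scores and permutation inference in pathburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathburden)
```

# The problem

Candidate-gene resequencing of a metabolic pathway in a case-control
cohort yields a matrix of minor-allele dosages that is wide, sparse and
dominated by rare variation: most variants are seen a handful of times
and many exactly once. Single-variant tests are underpowered and a plain
pathway-wide mutation count can be self-cancelling when the pathway
contains enzymes that compete for substrates: a damaging allele in one
gene can push a metabolic output in the *opposite* direction to a
damaging allele in its neighbour. `pathburden` therefore scores
individuals two ways:

* the **burden sum** `B_i = Σ_j g_ij`, an unweighted minor-allele tally
  over a variant subset, and
* the **Metabolic Index Score** `MIS_i = Σ_j s_gene(j) · g_ij`, where
  each gene carries a pre-declared sign per metabolic output: +1 if its
  activity is inferred beneficial to that output, −1 if it competes with
  or is detrimental to it.

Both give every variant and every gene identical weight. The only
biological input is the sign table, which must be fixed *before* looking
at case-control contrasts — the package treats it as a configuration
object (`pathway_model()`), not something to be fitted.

# The default pathway model

`default_pathway_model()` covers three outputs of folate/one-carbon
metabolism. The reasoning, gene by gene:

* **Purine synthesis.** Cytoplasmic 10-formyl-THF, the one-carbon donor
  for two steps of de novo purine synthesis, is mostly fed by
  mitochondrial formate. Genes generating that formate flux (MTHFD2,
  SHMT2, AMT, SARDH, DMGDH) and genes incorporating it into purines
  (MTHFD1, ATIC, GART) are signed `+`. Genes competing for formate or for
  10-formyl-THF or for the cytoplasmic THF pool (MTFMT, ALDH1L2,
  ALDH1L1, SHMT1) are signed `−`. Compartment tags (cytoplasmic:
  MTHFD1, ATIC, GART, ALDH1L1, SHMT1; mitochondrial: the rest) let the
  score be restricted with `compartment = "cytoplasmic"` etc.
* **Homocysteine level.** Reduced one-carbon flux lowers purine output
  but *raises* homocysteine, so every purine-set gene enters with the
  opposite sign. The methionine-cycle genes BHMT, BHMT2, MTHFR, MTR,
  MTRR and the trans-sulfuration genes CBS, CTH consume homocysteine and
  are signed `−`. MAT1A/MAT2A are excluded: AdoMet synthesis does not
  directly move homocysteine levels.
* **Thymidylate synthesis.** The nuclear dTMP module SHMT1–TYMS–DHFR is
  signed `+`; MTHFR is signed `−` (competes with TYMS for
  methylene-THF); MTR, MTRR, MAT1A, MAT2A are signed `+` through the
  AdoMet-mediated inhibition of MTHFR.

The shipped table restricts itself to genes with clear literature-based
designations (the homocysteine set, in particular, covers the 12
cytoplasmic genes that can be signed on this reasoning); groups working
from richer curation supply their own table as TSV or YAML via
`read_pathway_model()`.

# Analysis grid and conventions

* **Minor-allele orientation** is computed per analysis stratum on cases
  and controls pooled, because the identity of the minor allele is
  population-dependent (a well-known folate example: an allele that is
  minor in Europeans is the major allele in Mexican-American
  populations). Alt frequency > 0.5 flips `g → 2 − g`; exactly 0.5 keeps
  the alt allele as minor; an all-missing variant is flagged and left
  alone. Orientation on the whole cohort (`stratum = "all"`) is also
  supported; per-stratum is the default in the pipeline.
* **Common vs rare** is MAF ≥ 2.5% vs < 2.5% *within the analysis
  stratum*, boundary inclusive as common. The threshold is a config
  value (`analysis_config(maf_threshold = …)`).
* **Missingness QC** drops individuals, then variants (recomputed on the
  retained individuals), whose missing fraction strictly exceeds 25%.
  The order is configurable; sample-first is the default.
* **Imputation** draws each missing cell from the empirical genotype
  distribution of its variant within the individual's stratum (cohort
  fallback when a stratum has no observed genotype). This is a single
  seeded stochastic draw, deliberately simple and self-contained; it
  preserves stratum genotype frequencies in expectation but, unlike
  haplotype-model imputation, ignores LD information, so imputed cells
  carry no linkage signal. With ~6% missingness this mainly adds a small
  amount of noise to scores.
* **LD pruning** groups variants greedily in coordinate order: each
  unassigned variant seeds a group and absorbs later unassigned variants
  with squared dosage correlation (composite LD — phase is unknown)
  strictly above 0.8; the seed is the retained representative. The rule
  is deterministic given variant order; pruning is done cohort-wide
  before subsetting, both choices exposed as options.

# Permutation inference

Case/control labels are the only random element under the null, so all
p-values come from label permutation with group sizes fixed:

* Statistics: Welch t (unequal variances — the safer reading of a
  "t-test" between unbalanced groups), Mann-Whitney U for the skewed
  rare-variant sums, KS sup-distance as a distribution-shape
  alternative. Two-sided by default, on the centered statistic (U is
  centered at `n1·n0/2`).
* Monte-Carlo p-values use the add-one estimator `(b + 1)/(B + 1)`,
  which cannot be zero and is valid for any `B`. When the number of
  distinct label arrangements is at most `1e6` (and no stratification is
  requested) the package switches to exhaustive enumeration and reports
  the exact proportion `b/C` (the observed arrangement is one of the
  `C`, so `b ≥ 1`).
* Degenerate scores (all individuals equal) return `p = 1`.
* **Stratified permutation**: pooled ("all") analyses of a stratified
  cohort shuffle labels within each race-ethnicity stratum, preserving
  per-stratum case/control ratios, so stratum-frequency differences
  cannot masquerade as signal.
* **max(T)**: the family-wise adjustment records, for every permutation,
  the maximum absolute statistic over all hypotheses; the adjusted p of
  a hypothesis is the exceedance rate of that maximum over its observed
  statistic. Single-step max(T) was chosen as the minimal standard
  reading; it is conservative relative to the step-down variant but
  shares its validity. The pipeline adjusts over the *full*
  metabolite × subset × stratum grid using one shared stratified
  permutation stream: a stratum-restricted hypothesis computes its
  statistic on its subpopulation's rows of each permuted label vector.
  Sharing the stream is what makes adjusted p-values comparable across
  cells, including cells from different strata.

Single-variant association uses maximum-likelihood logistic regression
on dosage (log-additive), optionally with stratum indicator covariates;
detected separation (routine for singletons) switches to a Firth
penalized fit, implemented in the package with the standard
hat-diagonal-corrected score, and flags the result. Dichotomized odds
ratios use `ad/bc` with a Woolf log CI; a zero cell triggers the
Haldane-Anscombe 0.5 correction (flagged). Ties at a cut go to the
"below" arm for the control-median rule, and are excluded for a fixed
cut (comparing "below 0 to above 0" leaves the zeros out).

# The cohort simulator

`simulate_cohort()` emulates the structure the analysis is designed for,
with defaults fixed to the published structure of a 480-member spina
bifida case-control resequencing cohort:
480 individuals (239 cases / 241 controls), strata 65% Hispanic /
21% non-Hispanic white / 14% other (largest-remainder rounding so every
stratum is realized), 31 folate-pathway genes carrying 1,441 variants in
the class mix 1050 non-coding : 211 nonsynonymous : 171 synonymous :
4 truncation : 5 frameshift, a frequency spectrum with 614/1441 singleton
mass and 1096/1441 total rare mass, and 6% missing genotypes. Values the
study did not publish were fixed once at what we consider realistic for
this kind of cohort: logit-scale SD 0.3 for between-stratum MAF
differences, LD blocks of 5 consecutive within-gene variants with latent
copula correlation 0.3 (modest background LD; `ld_rho` near 1 produces
R² > 0.8 groups for pruning exercises), and rare non-singleton MAFs
uniform between one allele copy and the 2.5% boundary, common MAFs
uniform on [0.025, 0.5].

Mechanics worth knowing:

* Genotypes are Hardy-Weinberg binomial draws at the individual's
  stratum MAF, coupled within an LD block through a shared latent
  Gaussian factor (a Gaussian copula). The copula induces within-block
  dosage correlation while leaving every variant's marginal stratum MAF
  exactly on target — an allele-copying scheme we considered instead
  drags member frequencies toward the block anchor's.
* Singletons are *placed* (one heterozygous carrier, uniformly chosen),
  not frequency-sampled, and take no part in LD.
* Missingness is completely at random; the study gives no missingness
  mechanism.
* `plant_effect()` redraws case status from
  `Pr(case) = plogis(α + β·MIS)`, with α calibrated by root-finding to
  hit a target marginal prevalence; `β = 0` is exactly the null. The
  returned sample sheet records the generating score (`true_score`) for
  parameter-recovery checks.

What the simulator does **not** emulate: real haplotype structure
(coalescent LD decay, recombination), population admixture within
strata, non-random missingness (e.g. failed exons clustering in
specific genes), genotyping error, and any dependence of the effect on
covariates. Passing tests on simulated cohorts therefore demonstrate the
*statistical machinery* — calibration, family-wise error control,
power ordering, parameter recovery — not that the biological findings of
any particular study would replicate.

# Numerical choices and degenerate inputs

* Exceedance comparisons use a relative tolerance of `1e-8` so that
  permutations reproducing the observed statistic up to floating-point
  noise count as ties (two identical hypotheses must get identical
  adjusted p).
* A constant score row in a max(T) family carries statistic 0 throughout
  rather than erroring, so a degenerate grid cell cannot poison the
  family.
* `t` on zero-pooled-variance scores is an error directing the caller to
  Mann-Whitney or a permutation of means; inside the permutation engine
  a zero standard error with a zero mean difference scores 0 and with a
  non-zero difference scores ±Inf (the most extreme rank, which is the
  correct limiting behaviour).
* Empty variant subsets are legal and flagged; downstream tables carry
  `NA` p-values for them.
* The Firth Newton-Raphson step is damped (max step 5 on the logit
  scale) and gives up, flagged, if the information matrix is singular.

# Test problem sizes

The shipped test-suite exercises the machinery at sizes chosen to make
Monte-Carlo bands tight enough to be meaningful while keeping the suite
quick: calibration of the permutation p-value over 1,000 null cohorts of
n = 100 at B = 200; family-wise error of max(T) over 500 all-null
3-hypothesis families; parameter recovery and signed-vs-unsigned power
ordering over 200 replicates of n = 2,000 with a planted β = 0.4 on a
9-variant, 1-negative/3-positive gene set (the negative gene carrying
the largest share of variants, echoing the cytoplasmic purine signature
the score was designed around); and one full-scale pipeline run
(480 × ~1,300, B = 10,000 on the 48-cell grid). The enumeration oracles
(20-arrangement and 252-arrangement families) pin the permutation and
max(T) code to brute-force results exactly.

# Known limitations

* The signed score assumes every variant in a gene pushes in the gene's
  designated direction with equal weight; benign and gain-of-function
  alleles are mis-scored by construction. The score is a screening
  statistic, not a metabolic prediction.
* Frequency-based imputation underestimates the LD information a
  haplotype imputer would exploit; with high missingness it will shrink
  case-control score differences toward zero.
* Exact conditional logistic inference is out of scope; the Firth
  fallback gives finite, approximately unbiased estimates under
  separation but its Wald CI is an approximation.
* max(T) across strata compares statistics on different sample sizes on
  a common absolute scale; cells from small strata are noisier and the
  t statistic's pivotality makes this reasonable but not perfect.
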