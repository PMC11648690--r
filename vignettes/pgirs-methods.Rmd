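---
title: "Polygenic and gene-environment interaction risk scores: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic and gene-environment interaction risk scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgirs)
```

## The problem

Conventional polygenic risk scores (PRS) summarize an individual's genetic
liability as a weighted sum of risk-allele dosages, with weights taken from a
genome-wide association scan. A PRS ignores that many variants act only — or
act differently — under particular environmental exposures. When a trait's
genetic sharing with another trait is carried by gene-environment (GxE)
interactions, a PRS can show no association at all while an
interaction-aware score succeeds.

`pgirs` implements the full construction and evaluation loop for a
polygenic and gene-environment interaction risk score (PGIRS):

1. per-SNP quality control,
2. a genome-wide SNP association and SNP-environment interaction scan
   (GWEIS),
3. P-value-ordered greedy LD clumping of the scan hits,
4. score construction (PRS, per-exposure GIRS, and their PGIRS sum),
5. stratified standardized association testing with Benjamini-Hochberg FDR
   control,
6. product-of-coefficients mediation analysis with bootstrap intervals, and
7. k-fold cross-validated model evaluation,

together with a synthetic cohort generator so the entire pipeline is
testable without access to restricted biobank data.

## The scan model

For each SNP $j$ and each exposure $E$ the scan fits, by ordinary least
squares on samples with complete data,

$$ y = b_0 + b_g G_j + b_e E + b_{ge} G_j\!\cdot\!E + \varepsilon, $$

where $G_j \in [0, 2]$ is the counted-allele dosage and $y$ is the outcome
after residualization on covariates (age, sex, age$^2$-style terms,
principal components). Two-sided t-tests give $P$-values for $b_g$ and
$b_{ge}$. Design choices worth stating:

* **One model per (SNP, exposure) pair.** The model statement contains a
  single $E$; with several exposures each is scanned separately and the
  final score sums per-exposure contributions. A consequence we document
  rather than hide: if a second exposure with a nonzero mean is *omitted*
  from the model, its interaction loci acquire genuine marginal main
  effects of size roughly $b_{ge}\,\mathrm{E}[E_\text{omitted}]$, and can
  enter the main-effect score. This is a property of per-exposure GWEIS
  models generally, and it is why the method-contrast simulations in the
  test suite use a single exposure.
* **Covariate adjustment by prior residualization** of the outcome
  (covariates-in-model is available via the `covariates` argument of
  `gweis_scan()`).
* **Missing dosages are mean-imputed** (twice the in-sample allele
  frequency), mirroring dosage conventions and keeping per-SNP sample sizes
  stable; rows with missing exposure or outcome are dropped per fit.
* **Homoscedastic OLS standard errors.** Under a strong polygenic GxE
  background the residual variance grows with $E^2$, and the nominal 95%
  intervals of single-SNP fits undercover by a few points (the test suite
  measures coverage near 0.91–0.94 under a 20-locus background, against a
  [0.90, 0.99] acceptance band). Robust (sandwich) errors are a possible
  extension; they are not part of the method being reproduced.

## Quality control

A SNP is removed when its call rate is below 0.90, its Hardy-Weinberg exact
test $P$-value is below 0.001, or its minor allele frequency is below 0.01;
equality passes, reading the rules as strict inequalities. The HWE test is
the two-sided exact test on hard genotype counts: conditional on allele
counts, all heterozygote counts of the same parity are enumerated and those
no more probable than the observed configuration are summed, without mid-P
correction — the common default in genetics toolchains. Imputed dosages
farther than $10^{-6}$ from an integer skip the HWE rule (the exact test is
defined on genotype counts only); such SNPs are flagged in the QC report.

## Clumping and scores

Candidates with $P$ below the inclusion threshold (default the genome-wide
suggestive level $10^{-5}$; $0.05$ as the sensitivity setting) are clumped
greedily: the smallest-$P$ candidate becomes an index SNP and absorbs all
candidates within 250 kb (symmetric, boundary inclusive) whose in-sample
$r^2 \ge 0.2$ with it. Ties in $P$ break by (chromosome, position, SNP id),
so output is deterministic and independent of input order. Main-effect SNPs
are ranked by $P_{b_g}$ and interaction SNPs by $P_{b_{ge}}$ of the given
exposure — ranking interaction candidates by their interaction $P$-value is
an assumption, flagged as such. $r^2$ is computed on mean-imputed in-sample
dosages; no external reference panel is used.

Scores follow the plain sums

$$ \mathrm{PRS} = \sum_i b_{gi} d_i, \qquad
   \mathrm{GIRS} = \Big(\sum_k b_{gek} f_k\Big)\cdot e, \qquad
   \mathrm{PGIRS} = \mathrm{PRS} + \sum_\text{exposures} \mathrm{GIRS}, $$

with $d_i, f_k$ counted-allele dosages (missing values mean-imputed) and
$e$ the individual's **raw** exposure value — no standardization and no
division by SNP count, because the formulas are plain sums
(`standardize_exposure = TRUE` exposes the alternative). Weights are signed
betas on the counted allele; counting the opposite allele flips dosages as
$2 - d$, which only shifts scores by a constant and leaves all
between-sample contrasts unchanged. A SNP may legitimately appear in both a
main-effect and an interaction set; each GIRS is computed independently and
shared SNPs contribute to both terms.

## Association testing, mediation, cross-validation

Associations are tested by standardized linear regression: score and
outcome are z-scored *within* each stratum (smokers, non-smokers, drinkers,
non-drinkers, both, neither; ever-exposure means frequency > 0), then the
outcome is regressed on the score plus covariates. Smoking strata
additionally adjust for drinking frequency and drinking strata for smoking
frequency. $P$-values are BH-adjusted within each stratum across all score
x trait tests of that stratum; the multiple-testing family is a stated
assumption, chosen because results are reported per stratum. Strata too
small to fit are reported as undefined rows rather than aborting a battery.

Mediation uses the product-of-coefficients decomposition (single mediator):
$a$ from $m \sim x$, $b$ and direct effect from $y \sim x + m$, total from
$y \sim x$, indirect $= a\,b$, with a percentile bootstrap interval over
row resamples (bias-corrected percentile behind `method = "bca"`). For
linear models total $=$ direct $+$ indirect holds exactly and is asserted.
The pipeline's mediation stage feeds it x = PGIRS, m = primary phenotype,
y = secondary trait purely to exercise the machinery on pipeline outputs;
no causal structure is claimed there.

Cross-validation shuffles complete cases under a seed into $k = 5$ folds
whose sizes differ by at most one, fits OLS on $k-1$ folds and evaluates
RMSE, MAE, and $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ on the held-out fold,
with SST about the held-out fold's own mean — the stricter convention, so
externally reported CV $R^2$ ranges computed against a training mean are
not directly comparable.

## What the generator emulates — and what it does not

`simulation_config()` defines the generative model, an exact mirror of the
scan model:

$$ Y = b_0 + \textstyle\sum b_g G + \sum b_e E + \sum b_{ge} G\!\cdot\!E +
   \text{covariate effects} + N(0, \sigma^2). $$

* **Genotypes**: biallelic dosages in LD blocks. Each block draws one
  allele frequency from `maf_range` (default 0.05–0.5) and generates
  haplotypes by a first-order copy process: each allele copies its
  neighbour with probability `ld_decay` (default 0.8), else is redrawn, so
  the adjacent-dosage correlation approximates `ld_decay`. Blocks are
  2 kb-spaced internally and separated by 300 kb — more than the 250 kb
  clumping window — so clumping is nontrivial but analyzable. Missingness
  is completely at random (default 2%), as no missingness mechanism is
  specified for the real data.
* **Exposures**: zero-inflated lognormal, mimicking the shape (point mass
  at zero, right skew) of consumption frequencies without claiming
  distributional fidelity. Defaults: a daily-smoking-frequency-like
  exposure (70% zeros; positive part lognormal around 10 units/day,
  matching roughly 30% ever-smokers in large UK cohort descriptives) and a
  weekly-drinking-frequency-like exposure (4% zeros; positive part around
  3 days/week). Exposures are generated independently; their joint
  distribution in real cohorts is unknown to us, so none is imposed.
* **Covariates**: age-like, sex-like, and ten PC-like columns; their
  effects on the phenotype default to zero to isolate method behaviour,
  and are configurable for confounding experiments.
* **Effect sizes**: when causal sets are not supplied, 20 main-effect loci
  (betas $U(0.3, 0.5)$ per allele) and 20 interaction loci (betas
  $U(0.05, 0.15)$ per allele per exposure unit) are placed on even grids in
  *disjoint* LD blocks. Main effects act on $G$ (sd $\approx 0.65$) while
  interactions act on $G\!\cdot\!E$ whose scale the exposure sets, so equal
  per-unit betas would make main effects undetectable next to
  frequency-scaled interactions; the default main-effect scale keeps both
  score components carrying detectable signal at the default study size.
* **Secondary traits** (`simulate_correlated_trait()`) reuse stated
  proportions of the primary trait's causal loci with re-drawn magnitudes
  (signs kept). `share_interaction = 1, share_main = 0` yields a trait
  whose genetic signal is purely GxE — the construction behind the
  "PGIRS detects what PRS misses" contrast.
* **Missing dosages contribute their in-sample mean** to the generative
  sum, exactly as the scan imputes them, so with `noise_sd = 0` the scan
  recovers configured effects to numerical precision — a deliberately
  closed loop used by the recovery tests.

What passing tests on this generator do **not** show: realism of allele
frequencies or LD maps, population structure and relatedness, confounding
between exposures and genotype, informative missingness, non-Gaussian
phenotypes, or exposure measurement error. Results on synthetic cohorts
validate the *machinery and its statistical calibration*, not effect sizes
in any real population.

## Calibration experiments and problem sizes

The test suite validates, at sizes chosen to finish in minutes on one CPU:

* exact-test, scan, clumping, and scoring equivalence against independent
  oracles (full enumeration, closed-form normal equations, brute-force
  greedy search, naive double loops);
* noiseless recovery of generative effects to $10^{-6}$;
* interaction-effect recovery over 20 replicates at n = 5000, m = 2000 with
  20 causal loci — mean bias below 0.01 and CI coverage inside
  [0.90, 0.99]. This experiment uses an exposure in standardized units
  (zero-inflated lognormal, unit median, sdlog 0.25): effects of 0.05–0.15
  per exposure unit with unit residual noise are statistically coherent
  only at an O(1) exposure scale — at a cigarettes-per-day scale the
  polygenic GxE background (variance growing with $E^2$) dominates the
  unit noise and homoscedastic intervals undercover badly;
* nominal 5% type-I error of the interaction test under outcome
  permutation (500 null SNPs, n = 2000);
* the method contrast: 50 interaction-driven secondary traits at n = 5000,
  with PGIRS reaching FDR < 0.05 in at least 90% of replicates while PRS
  does not in at least 80% (single-exposure design, for the marginalization
  reason above);
* BH familywise behaviour of the all-null battery (10 traits x 3 scores x
  200 replicates, per stratum);
* mediation: recovery of a generative indirect effect $0.5 \times 0.4$ at
  n = 5000, and ~95% null coverage over 200 replicates with the mediator
  independent of the score (one null path; with both paths null the
  percentile interval of a product is known to over-cover);
* CV fold-partition exactness and perfect-fit metrics;
* byte-identical pipeline reruns under a fixed configuration.

## Known limitations

* OLS-based intervals undercover mildly under strong shared-exposure GxE
  backgrounds (see above); quantitative traits only — no logistic scan.
* No mixed-model or relatedness correction; no reference-panel LD; no
  conditional/secondary-signal analysis; no shrinkage (LDpred-style)
  weighting.
* The HWE rule is skipped, not approximated, for materially non-integer
  dosages.
* Percentile bootstrap (default) is the simplest defensible interval for
  the indirect effect; BCa is available but neither matches any specific
  published tool's defaults.
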