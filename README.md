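# pgirs

Construction and evaluation of **polygenic and gene–environment interaction
risk scores (PGIRS)** from genotype dosage data, in R.

A conventional polygenic risk score (PRS) weights risk-allele dosages by
main-effect estimates from a genome-wide association scan and ignores the
environment. When a trait's genetic signal is carried by gene–environment
(G×E) interactions — variants that matter only in smokers, or only in
drinkers — a PRS can miss it entirely. `pgirs` implements the
interaction-aware alternative end to end, for statistical geneticists and
epidemiologists who want to build and stress-test such scores:

1. **QC** — per-SNP call rate, Hardy–Weinberg exact test, and minor allele
   frequency filters (`apply_qc()`, removal below 0.90 / 0.001 / 0.01);
2. **GWEIS** — per SNP and exposure, the ordinary least squares fit of
   `y = b0 + bg·G + be·E + bge·G·E + e` with t-test P-values
   (`gweis_scan()`, after `residualize()` covariate adjustment);
3. **LD clumping** — greedy P-ordered index-SNP selection within a 250 kb
   window at r² ≥ 0.2, inclusion threshold P = 1e-5 (`ld_clump()`);
4. **Scores** — `PRS = Σ b_gi·d_i`, `GIRS = (Σ b_gek·f_k)·e` with each
   individual's raw exposure `e`, and `PGIRS = PRS + Σ GIRS`
   (`compute_prs()`, `compute_girs()`, `compute_pgirs()`);
5. **Stratified association** — standardized linear regression within
   smoker/drinker strata with Benjamini–Hochberg FDR per stratum
   (`run_association_battery()`);
6. **Mediation** — product-of-coefficients with percentile bootstrap CIs
   (`mediate()`);
7. **Cross-validation** — 5-fold CV reporting RMSE, MAE, R² (`kfold_cv()`);
8. **Synthetic cohorts** — an LD-blocked genotype and zero-inflated
   exposure generator whose phenotype model mirrors the scan exactly
   (`simulate_cohort()`), so the whole pipeline is testable without
   restricted cohort data.

`run_pipeline()` chains all stages from one seeded configuration into a
directory of TSVs plus a checksummed manifest; a thin command-line wrapper
lives at `inst/cli/pgirs.R` (subcommands `simulate`, `qc`, `gweis`,
`clump`, `score`, `assoc`, `mediate`, `cv`, `run`). I/O covers VCF (GT or
DS dosages, biallelic) and a plain dosage-TSV dialect.

## Worked example

Simulate a cohort with 20 main-effect loci and 20 smoking-interaction loci,
build the scores, and test them against a secondary trait whose genetic
signal is *purely* G×E:

```r
library(pgirs)

cfg <- simulation_config(
  n_samples = 3000, n_snps = 500,
  exposure_specs = list(smoking = list(zero_fraction = 0.7,
                                       meanlog = log(10), sdlog = 0.5)),
  seed = 42)
cohort <- simulate_cohort(cfg)

qc <- apply_qc(cohort$genotypes)
y <- setNames(cohort$phenotype$phenotype, cohort$phenotype$sample_id)
covs <- cohort$covariates[setdiff(names(cohort$covariates), "sample_id")]
scan <- gweis_scan(qc$panel, residualize(y, covs), cohort$exposures)

main_es <- ld_clump(gweis_candidates(scan, "main"), qc$panel,
                    clump_params(1e-5))
int_es  <- ld_clump(gweis_candidates(scan, "interaction", "smoking"),
                    qc$panel,
                    clump_params(1e-5, p_source = "interaction:smoking"))
scores <- compute_scores(qc$panel, main_es, list(smoking = int_es),
                         cohort$exposures)
head(scores, 3)
#>   sample_id      PRS GIRS_smoking     PGIRS
#> 1    S00001 3.240730     0.000000  3.240730
#> 2    S00002 3.130601     8.743484 11.874085
#> 3    S00003 3.252923     0.000000  3.252923
```

`PGIRS = PRS + GIRS_smoking` per sample; GIRS is exactly zero for
non-smokers (`e = 0`). Now the contrast on an interaction-driven trait,
among smokers:

```r
trait <- simulate_correlated_trait(cohort, share_main = 0,
                                   share_interaction = 1, seed = 43)
d <- data.frame(sample_id = cohort$exposures$sample_id,
                smoking = cohort$exposures$smoking, trait = unname(trait))
run_association_battery(
  scores, d, traits = "trait",
  strata = list(stratum_spec("smokers", function(x) x$smoking > 0)),
  score_cols = c("PRS", "PGIRS"))
#>   score_name trait_name stratum    beta     se     p       fdr   n
#> 1      PGIRS      trait smokers  0.9343 0.0118 0.000 4.45e-308 911
#> 2        PRS      trait smokers -0.0405 0.0331 0.222  2.22e-01 911
```

The interaction-aware score captures the trait (standardized β = 0.93,
FDR ≈ 0) while the conventional PRS shows nothing (β = −0.04, FDR = 0.22)
— the qualitative signature the method exists for. Model quality by 5-fold
cross-validation:

```r
kfold_cv(merge(scores, d, by = "sample_id"), "PGIRS", "trait",
         k = 5, seed = 44)
#> 5-fold CV (seed 44): mean RMSE 2.07, MAE 1.424, R2 0.9413
```

The methods vignette (`vignettes/pgirs-methods.Rmd`) documents the models,
the generator's design and defaults, numerical conventions, and known
limitations.

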