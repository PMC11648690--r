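test_that("identical configurations reproduce cohorts bit-identically", {
  a <- simulate_cohort(tiny_config(n = 150, m = 30))
  b <- simulate_cohort(tiny_config(n = 150, m = 30))
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$exposures, b$exposures)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$phenotype, b$phenotype)
})

test_that("genotype panels honour missingness, MAF, LD, and spacing", {
  no_miss <- simulate_genotypes(tiny_config(n = 100, m = 20,
                                            missing_rate = 0))
  expect_false(anyNA(no_miss$dosage))

  # tight MAF target concentrates at n = 10000
  cfg <- tiny_config(n = 10000, m = 30, maf_range = c(0.3, 0.3))
  maf <- apply(simulate_genotypes(cfg)$dosage, 2, snp_maf)
  expect_true(all(maf >= 0.27 & maf <= 0.33))

  # ld_decay = 0: adjacent SNPs uncorrelated
  cfg0 <- tiny_config(n = 2000, m = 300, seed = 8, ld_decay = 0,
                      missing_rate = 0)
  d0 <- simulate_genotypes(cfg0)$dosage
  r0 <- abs(vapply(seq_len(ncol(d0) - 1),
                   function(j) cor(d0[, j], d0[, j + 1]), numeric(1)))
  expect_lt(mean(r0), 0.05)

  # ld_decay = 0.8: within-block adjacent correlation approximates 0.8
  cfg8 <- tiny_config(n = 2000, m = 300, seed = 8, ld_decay = 0.8,
                      missing_rate = 0, ld_block_size = 5)
  p8 <- simulate_genotypes(cfg8)
  within <- which(diff(p8$snps$pos) == 2000)
  r8 <- vapply(within, function(j) cor(p8$dosage[, j], p8$dosage[, j + 1]),
               numeric(1))
  expect_equal(mean(r8), 0.8, tolerance = 0.05)

  # blocks separated by more than the 250 kb clumping window
  expect_true(all(diff(p8$snps$pos)[diff(p8$snps$pos) != 2000] > 250000))
  expect_true(all(diff(p8$snps$pos) > 0))

  expect_error(tiny_config(n = 100, m = 10, maf_range = c(0, 0.5)),
               "maf_range")
  expect_error(tiny_config(n = 100, m = 10, missing_rate = 0.5),
               "missing_rate")
})

test_that("exposures honour zero inflation and naming", {
  cfg <- simulation_config(
    n_samples = 10000, n_snps = 10,
    exposure_specs = list(a = list(zero_fraction = 0.7, meanlog = 0,
                                   sdlog = 1),
                          b = list(zero_fraction = 1, meanlog = 0,
                                   sdlog = 1)),
    seed = 3)
  ex <- simulate_exposures(cfg, 10000, seed = 3)
  expect_named(ex, c("a", "b"))
  expect_true(all(ex$b == 0))
  expect_gte(mean(ex$a == 0), 0.68)
  expect_lte(mean(ex$a == 0), 0.72)
  expect_true(all(ex$a >= 0))
  expect_error(
    simulation_config(exposure_specs = list(a = list(zero_fraction = 1.4))),
    "zero_fraction")
})

test_that("phenotype is the exact generative formula", {
  # all effects zero, no noise: constant intercept
  cfg0 <- tiny_config(n = 50, m = 10, noise_sd = 0, b0 = 2.5,
                      causal_main = data.frame(snp = integer(0),
                                               beta = numeric(0)),
                      causal_interaction = list(
                        exposure = data.frame(snp = integer(0),
                                              beta = numeric(0))),
                      b_e = c(exposure = 0))
  co0 <- simulate_cohort(cfg0)
  expect_true(all(co0$phenotype$phenotype == 2.5))

  # single main causal SNP: exact affine function of its dosage
  cfg1 <- tiny_config(n = 80, m = 10, noise_sd = 0, b0 = 1,
                      missing_rate = 0,
                      causal_main = data.frame(snp = 4L, beta = 0.7),
                      causal_interaction = list(
                        exposure = data.frame(snp = integer(0),
                                              beta = numeric(0))),
                      b_e = c(exposure = 0))
  co1 <- simulate_cohort(cfg1)
  expect_equal(co1$phenotype$phenotype,
               1 + 0.7 * co1$genotypes$dosage[, 4], ignore_attr = TRUE)

  # interaction effect: plug dosage/exposure corners into the formula
  panel <- make_panel(cbind(s1 = c(0, 2, 0, 2)))
  cohort <- list(genotypes = panel,
                 exposures = data.frame(exposure = c(0, 0, 1, 1)),
                 covariates = data.frame(age = rep(0, 4)))
  cfg_ge <- tiny_config(n = 4, m = 1, noise_sd = 0, b0 = 0,
                        causal_main = data.frame(snp = integer(0),
                                                 beta = numeric(0)),
                        causal_interaction = list(
                          exposure = data.frame(snp = 1L, beta = 0.5)),
                        b_e = c(exposure = 0))
  y <- simulate_phenotype(cohort, cfg_ge)
  expect_equal(unname((y[4] - y[3]) - (y[2] - y[1])), 2 * 0.5)

  # causal SNP that default QC would remove triggers a warning
  low <- make_panel(cbind(rare = c(1, rep(0, 99))))
  bad_cohort <- list(genotypes = low,
                     exposures = data.frame(exposure = rep(1, 100)),
                     covariates = data.frame(age = rep(0, 100)))
  cfg_bad <- tiny_config(n = 100, m = 1, noise_sd = 0,
                         causal_main = data.frame(snp = 1L, beta = 1),
                         causal_interaction = list(
                           exposure = data.frame(snp = integer(0),
                                                 beta = numeric(0))))
  expect_warning(simulate_phenotype(bad_cohort, cfg_bad), "fail default QC")
})

test_that("secondary traits share causal loci as configured", {
  cfg <- tiny_config(n = 600, m = 40, seed = 21,
                     n_causal_main = 5, n_causal_interaction = 5)
  co <- simulate_cohort(cfg)

  # no sharing: independent of genotype
  t0 <- simulate_correlated_trait(co, 0, 0, trait_noise_sd = 1, seed = 1)
  G <- co$genotypes$dosage
  G[is.na(G)] <- 0
  r <- abs(cor(t0, G))
  expect_lt(max(r), 0.15)

  # pure interaction, no noise: constant within the unexposed stratum
  t1 <- simulate_correlated_trait(co, 0, 1, trait_noise_sd = 0, seed = 1)
  unexposed <- co$exposures$exposure == 0
  expect_true(all(t1[unexposed] == 0))

  # shared main loci induce positive correlation with the primary trait
  pos <- 0
  for (s in 1:20) {
    t2 <- simulate_correlated_trait(co, 1, 0, trait_noise_sd = 1, seed = s)
    pos <- pos + (cor(t2, co$phenotype$phenotype) > 0)
  }
  expect_gte(pos, 18)
  expect_error(simulate_correlated_trait(co, -0.1, 0), "share_main")
})

test_that("cohorts are written as readable TSV/VCF with true effects", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(tiny_config(n = 40, m = 12, seed = 77))
  write_cohort(co, dir)
  expect_identical(read_dosage_tsv(file.path(dir, "genotypes.tsv"))$dosage,
                   co$genotypes$dosage)
  expect_identical(read_vcf(file.path(dir, "genotypes.vcf"))$dosage,
                   co$genotypes$dosage)
  expect_equal(read_table(file.path(dir, "phenotype.tsv"))$phenotype,
               co$phenotype$phenotype)
  te <- utils::read.delim(file.path(dir, "true_effects.tsv"))
  expect_true(all(c("main", "interaction") %in% te$effect_type))
})
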