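test_that("residualization matches closed-form least squares", {
  y <- c(3.1, -0.4, 2.2, 0.9, 1.5, -2.0)
  names(y) <- paste0("s", 1:6)
  # intercept-only: centered outcome
  r0 <- residualize(y)
  expect_equal(unname(r0$residuals), unname(y - mean(y)))

  covs <- data.frame(age = c(40, 55, 61, 47, 52, 58),
                     sex = c(0, 1, 1, 0, 0, 1))
  r1 <- residualize(y, covs)
  X <- cbind(1, as.matrix(covs))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(r1$residuals), unname(drop(y - X %*% beta)),
               tolerance = 1e-10)
  expect_lt(abs(mean(r1$residuals)), 1e-10)

  # exactly linear outcome leaves zero residuals
  y_lin <- stats::setNames(2 + 0.5 * covs$age - covs$sex, names(y))
  expect_lt(max(abs(residualize(y_lin, covs)$residuals)), 1e-10)

  # collinear covariates are named in the error
  covs$age2 <- 2 * covs$age
  expect_error(residualize(y, covs), "collinear.*age2")

  # rows with missing covariates are dropped and recorded
  covs2 <- data.frame(age = c(40, NA, 61, 47, 52, 58))
  r2 <- residualize(y, covs2)
  expect_equal(r2$dropped, "s2")
  expect_equal(length(r2$residuals), 5L)
})

test_that("noiseless generative data is recovered exactly by the scan", {
  cfg <- tiny_config(n = 300, m = 20, noise_sd = 0, b0 = 0.3,
                     missing_rate = 0.05,
                     causal_main = data.frame(snp = 7L, beta = 0.25),
                     causal_interaction = list(
                       exposure = data.frame(snp = 7L, beta = 0.4)),
                     b_e = c(exposure = 0.15))
  co <- simulate_cohort(cfg)
  y <- stats::setNames(co$phenotype$phenotype, co$phenotype$sample_id)
  res <- gweis_scan(co$genotypes, y, co$exposures)
  row <- res[res$snp_id == co$genotypes$snps$snp_id[7], ]
  expect_equal(row$b_g, 0.25, tolerance = 1e-8)
  expect_equal(row$b_ge, 0.4, tolerance = 1e-8)
  expect_equal(row$b_e, 0.15, tolerance = 1e-8)
})

test_that("scan estimates match the normal-equations oracle on a fixture", {
  set.seed(14)
  n <- 8
  g1 <- c(0, 1, 2, 1, 0, 2, 1, 0)
  g2 <- c(2, 2, 1, 0, 1, 0, 0, 1)
  e <- c(0, 0, 3, 1, 2, 0, 4, 1)
  y <- c(0.3, -1.2, 2.5, 0.7, -0.2, 1.1, 3.0, -0.5)
  names(y) <- sprintf("s%d", 1:8)
  panel <- make_panel(cbind(g1, g2), ids = c("g1", "g2"))
  rownames(panel$dosage) <- names(y)
  expo <- data.frame(sample_id = names(y), e = e)
  res <- gweis_scan(panel, y, expo)
  for (j in 1:2) {
    g <- panel$dosage[, j]
    o <- ols_oracle(cbind(1, g, e, g * e), y)
    row <- res[j, ]
    expect_equal(c(row$b_g, row$b_e, row$b_ge), o$beta[c(2, 3, 4)],
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(c(row$se_g, row$se_ge), o$se[c(2, 4)], tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(c(row$p_g, row$p_ge), o$p[c(2, 4)], tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("scan flags monomorphic SNPs and validates exposure columns", {
  set.seed(6)
  panel <- make_panel(cbind(rep(1, 20), rbinom(20, 2, 0.5)),
                      ids = c("mono", "poly"))
  y <- stats::setNames(rnorm(20), rownames(panel$dosage))
  expo <- data.frame(sample_id = names(y), e = rlnorm(20))
  res <- gweis_scan(panel, y, expo)
  expect_true(is.na(res$b_g[res$snp_id == "mono"]))
  expect_equal(res$note[res$snp_id == "mono"], "monomorphic")
  expect_false(is.na(res$b_g[res$snp_id == "poly"]))
  expect_error(gweis_scan(panel, y, expo, exposure_cols = "smoke"),
               "exposure column")
})

test_that("rescaling an exposure rescales b_ge and b_e but not P-values", {
  cfg <- tiny_config(n = 250, m = 12, seed = 33)
  co <- simulate_cohort(cfg)
  y <- stats::setNames(co$phenotype$phenotype, co$phenotype$sample_id)
  res1 <- gweis_scan(co$genotypes, y, co$exposures)
  scaled <- co$exposures
  scaled$exposure <- scaled$exposure * 4
  res2 <- gweis_scan(co$genotypes, y, scaled)
  expect_equal(res2$b_ge, res1$b_ge / 4, tolerance = 1e-8)
  expect_equal(res2$b_e, res1$b_e / 4, tolerance = 1e-8)
  expect_equal(res2$p_ge, res1$p_ge, tolerance = 1e-8)
  expect_equal(res2$b_g, res1$b_g, tolerance = 1e-8)
})

test_that("scan results are keyed by sample id, not row order", {
  cfg <- tiny_config(n = 120, m = 8, seed = 5)
  co <- simulate_cohort(cfg)
  y <- stats::setNames(co$phenotype$phenotype, co$phenotype$sample_id)
  res1 <- gweis_scan(co$genotypes, y, co$exposures)
  shuffled <- co$exposures[sample(nrow(co$exposures)), ]
  res2 <- gweis_scan(co$genotypes, y, shuffled)
  expect_equal(res1$b_ge, res2$b_ge, tolerance = 1e-12)
})

test_that("summary TSV round-trips losslessly", {
  cfg <- tiny_config(n = 60, m = 6, seed = 2)
  co <- simulate_cohort(cfg)
  y <- stats::setNames(co$phenotype$phenotype, co$phenotype$sample_id)
  res <- gweis_scan(co$genotypes, y, co$exposures)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gweis_summary(res, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr, c("CHR", "POS", "ID", "A1", "EXPOSURE", "BETA_G", "SE_G",
                      "P_G", "BETA_E", "SE_E", "BETA_GxE", "SE_GxE",
                      "P_GxE", "N"))
  back <- read_gweis_summary(path)
  for (col in c("b_g", "se_g", "p_g", "b_e", "se_e", "b_ge", "se_ge",
                "p_ge")) {
    expect_identical(back[[col]], res[[col]])
  }
  # write -> read -> write is byte-stable
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_gweis_summary(back, path2)
  expect_identical(readLines(path2), readLines(path))

  # empty result: header only
  write_gweis_summary(res[0, ], path)
  expect_equal(length(readLines(path)), 1L)
})
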