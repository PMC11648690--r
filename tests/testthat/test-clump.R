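test_that("ld_r2 follows squared Pearson correlation on dosages", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(ld_r2(c(0, 1, 2), c(2, 1, 0)), 1)  # anticorrelation squares
  expect_equal(ld_r2(c(0, 1, 2, 0), c(1, 1, 1, 1)), 0)  # zero variance
  set.seed(4)
  a <- rbinom(10000, 2, 0.3)
  b <- rbinom(10000, 2, 0.3)
  expect_lt(ld_r2(a, b), 0.01)
  # missing values are mean-imputed before correlating
  am <- a; am[1:100] <- NA
  expect_equal(ld_r2(am, a), cor(ifelse(is.na(am), mean(am, na.rm = TRUE),
                                        am), a)^2)
})

test_that("clumping keeps the dominant SNP among correlated neighbours", {
  set.seed(2)
  g <- rbinom(200, 2, 0.4)
  panel <- make_panel(cbind(g, g, rbinom(200, 2, 0.4)),
                      pos = c(100000, 110000, 120000),
                      ids = c("a", "b", "c"))
  cand <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                     pos = c(100000, 110000, 120000),
                     p = c(1e-6, 1e-8, 1e-7),
                     beta = c(0.2, 0.3, -0.1))
  res <- ld_clump(cand, panel, clump_params(p_threshold = 1e-5))
  expect_equal(sort(res$snp_id), c("b", "c"))
  expect_equal(res$weight[res$snp_id == "b"], 0.3)

  # mutually independent candidates all become index SNPs
  res2 <- ld_clump(cand[c(1, 3), ], panel, clump_params(p_threshold = 1e-5))
  expect_equal(sort(res2$snp_id), c("a", "c"))

  # the p threshold is strict
  cand$p <- c(1e-5, 0.5, 1e-7)
  res3 <- ld_clump(cand, panel, clump_params(p_threshold = 1e-5))
  expect_equal(res3$snp_id, "c")
})

test_that("clumping validates candidate identity against the panel", {
  panel <- random_panel(50, 3, seed = 1)
  cand <- data.frame(snp_id = c("rs001", "nope"), chrom = "1",
                     pos = c(1e6, 2e6), p = c(1e-8, 1e-8), beta = 1)
  expect_error(ld_clump(cand, panel), "absent from panel")
  cand2 <- data.frame(snp_id = c("rs001", "rs002"), chrom = "1",
                      pos = c(1e6, 999), p = c(1e-8, 1e-8), beta = 1)
  expect_error(ld_clump(cand2, panel), "mismatch")
})

test_that("clumping matches the brute-force greedy oracle on block panels", {
  for (seed in 1:5) {
    cfg <- tiny_config(n = 300, m = 80, seed = seed, ld_decay = 0.85,
                       ld_block_size = 8)
    panel <- simulate_genotypes(cfg)
    set.seed(seed + 100)
    p <- 10^(-runif(80, 0, 8))
    cand <- data.frame(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                       pos = panel$snps$pos, p = p, beta = rnorm(80))
    params <- clump_params(p_threshold = 0.05)
    res <- ld_clump(cand, panel, params)
    expected <- clump_oracle(cand$snp_id, cand$chrom, cand$pos, cand$p,
                             panel$dosage, 0.05, params$window_bp,
                             params$r2_threshold)
    expect_equal(sort(res$snp_id), expected)
  }
})

test_that("clumping is order-invariant and satisfies its postconditions", {
  cfg <- tiny_config(n = 250, m = 60, seed = 9, ld_decay = 0.9,
                     ld_block_size = 6)
  panel <- simulate_genotypes(cfg)
  set.seed(11)
  cand <- data.frame(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                     pos = panel$snps$pos, p = 10^(-runif(60, 0, 6)),
                     beta = rnorm(60))
  params <- clump_params(p_threshold = 0.05)
  res <- ld_clump(cand, panel, params)
  shuf <- ld_clump(cand[sample(nrow(cand)), ], panel, params)
  expect_identical(res$snp_id, shuf$snp_id)

  # retained pairs within the window are below the r2 threshold
  dos <- panel$dosage[, match(res$snp_id, panel$snps$snp_id), drop = FALSE]
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (i < j && res$chrom[i] == res$chrom[j] &&
          abs(res$pos[i] - res$pos[j]) <= params$window_bp) {
        expect_lt(ld_r2(dos[, i], dos[, j]), params$r2_threshold)
      }
    }
  }

  # raising r2 threshold never shrinks the set; lowering p never grows it
  looser <- ld_clump(cand, panel, clump_params(0.05, r2_threshold = 0.5))
  expect_gte(nrow(looser), nrow(res))
  expect_true(all(res$snp_id %in% looser$snp_id))
  stricter_p <- ld_clump(cand, panel, clump_params(1e-4))
  expect_lte(nrow(stricter_p), nrow(res))
  expect_true(all(stricter_p$snp_id %in% cand$snp_id[cand$p < 1e-4]))
})

test_that("effect sets round-trip through their TSV form", {
  cfg <- tiny_config(n = 100, m = 20, seed = 3)
  panel <- simulate_genotypes(cfg)
  set.seed(5)
  cand <- data.frame(snp_id = panel$snps$snp_id, chrom = panel$snps$chrom,
                     pos = panel$snps$pos, p = runif(20, 0, 0.04),
                     beta = rnorm(20))
  es <- ld_clump(cand, panel, clump_params(0.05,
                                           p_source = "interaction:smoke"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_effect_set(es, path)
  back <- read_effect_set(path)
  expect_identical(back$snp_id, es$snp_id)
  expect_identical(back$weight, es$weight)
  expect_identical(attr(back, "effect_type"), "interaction:smoke")
})
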