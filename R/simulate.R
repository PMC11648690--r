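#' Configuration for the synthetic cohort generator
#'
#' Defines the generative model behind every simulated cohort. Genotypes are
#' biallelic dosages in LD blocks (first-order allele-copy process), exposures
#' are zero-inflated lognormal (a point mass at zero plus a right-skewed
#' positive part, mimicking daily smoking frequency and weekly drinking
#' frequency), and the quantitative phenotype follows
#' \deqn{Y = b_0 + \sum b_g G + \sum b_e E + \sum b_{ge} G \cdot E +
#'       \mathrm{cov.\ effects} + \varepsilon,\quad
#'       \varepsilon \sim N(0, \mathrm{noise\_sd}^2),}
#' the exact mirror of the model fitted by [gweis_scan()].
#'
#' When `causal_main` / `causal_interaction` are `NULL`, causal SNPs are
#' placed deterministically (evenly spaced, interleaved across LD blocks)
#' with effect sizes drawn once under `seed`: main effects from
#' `U(0.3, 0.5)` per allele, interaction effects from `U(0.05, 0.15)` per
#' allele per exposure unit.
#'
#' @param n_samples,n_snps Cohort dimensions.
#' @param maf_range Length-2 numeric in (0, 0.5]; each LD block draws one
#'   minor allele frequency uniformly from this range (the counted allele is
#'   the minor allele).
#' @param ld_block_size SNPs per LD block.
#' @param ld_decay Within-block adjacent-SNP allele copy probability in
#'   `[0, 1)`; the adjacent-dosage correlation approximates this value.
#' @param missing_rate Completely-at-random missing dosage proportion in
#'   `[0, 0.2]`.
#' @param exposure_specs Named list; each element a list with `zero_fraction`
#'   in `[0, 1]` and lognormal `meanlog`, `sdlog` for the positive part.
#' @param causal_main Data frame `snp` (index), `beta` or `NULL`.
#' @param causal_interaction Named list (one per exposure) of data frames
#'   `snp`, `beta`, or `NULL`.
#' @param b_e Named numeric: per-exposure main environment effect.
#' @param b0 Intercept.
#' @param covar_effects Named numeric of covariate effects on the phenotype
#'   (default: all zero, isolating genetic and interaction signal).
#' @param n_causal_main,n_causal_interaction Counts used when causal sets are
#'   auto-placed.
#' @param noise_sd Residual standard deviation (> 0 allowed to be 0 for
#'   deterministic checks).
#' @param seed Integer seed; identical configurations reproduce cohorts
#'   bit-identically.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 5000,
                              n_snps = 2000,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 10,
                              ld_decay = 0.8,
                              missing_rate = 0.02,
                              exposure_specs = list(
                                smoking = list(zero_fraction = 0.70,
                                               meanlog = log(10), sdlog = 0.5),
                                drinking = list(zero_fraction = 0.04,
                                                meanlog = log(3), sdlog = 0.5)),
                              causal_main = NULL,
                              causal_interaction = NULL,
                              b_e = NULL,
                              b0 = 0,
                              covar_effects = NULL,
                              n_causal_main = 20,
                              n_causal_interaction = 20,
                              noise_sd = 1,
                              seed = 1) {
  n_samples <- check_count(n_samples, "n_samples")
  n_snps <- check_count(n_snps, "n_snps")
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_config("maf_range", "must be an increasing pair in (0, 0.5]")
  }
  ld_block_size <- check_count(ld_block_size, "ld_block_size")
  check_scalar_number(ld_decay, "ld_decay", 0, 1, upper_open = TRUE)
  check_scalar_number(missing_rate, "missing_rate", 0, 0.2)
  check_scalar_number(noise_sd, "noise_sd", 0)
  if (!length(exposure_specs) || is.null(names(exposure_specs)) ||
      any(names(exposure_specs) == "")) {
    stop_config("exposure_specs", "must be a non-empty named list")
  }
  for (nm in names(exposure_specs)) {
    zf <- exposure_specs[[nm]]$zero_fraction
    check_scalar_number(zf, paste0("exposure_specs$", nm, "$zero_fraction"), 0, 1)
  }
  seed <- check_count(seed, "seed", min = 0L)

  if (is.null(b_e)) {
    b_e <- stats::setNames(rep(0.05, length(exposure_specs)),
                           names(exposure_specs))
  }
  if (is.null(causal_main) || is.null(causal_interaction)) {
    set.seed(seed)
    k_m <- min(n_causal_main, n_snps)
    k_i <- min(n_causal_interaction, n_snps)
    # deterministic placement: main loci on an even grid, interaction loci
    # shifted by one full LD block so the two sets sit in distinct blocks
    # (no LD between them: clumped main index SNPs never tag interaction
    # loci and vice versa)
    main_idx <- unique(round(seq(1, n_snps, length.out = max(k_m, 1L))))[seq_len(k_m)]
    int_idx <- ((main_idx - 1L + ld_block_size) %% n_snps) + 1L
    if (is.null(causal_main)) {
      # main effects act on G (sd ~ 0.65); interaction effects act on G*E
      # whose scale is set by the exposure, so default main effect sizes are
      # larger per unit to contribute comparable, detectable signal
      causal_main <- data.frame(snp = main_idx,
                                beta = stats::runif(k_m, 0.3, 0.5))
    }
    if (is.null(causal_interaction)) {
      causal_interaction <- lapply(seq_along(exposure_specs), function(e) {
        idx <- ((int_idx - 1L + (e - 1L)) %% n_snps) + 1L
        data.frame(snp = idx, beta = stats::runif(k_i, 0.05, 0.15))
      })
      names(causal_interaction) <- names(exposure_specs)
    }
  }
  if (length(causal_main) && nrow(causal_main) &&
      any(causal_main$snp < 1 | causal_main$snp > n_snps)) {
    stop_config("causal_main", "contains SNP indices outside 1..n_snps")
  }
  for (nm in names(causal_interaction)) {
    ci <- causal_interaction[[nm]]
    if (nrow(ci) && any(ci$snp < 1 | ci$snp > n_snps)) {
      stop_config(paste0("causal_interaction$", nm),
                  "contains SNP indices outside 1..n_snps")
    }
  }
  missing_exp <- setdiff(names(causal_interaction), names(exposure_specs))
  if (length(missing_exp)) {
    stop_config("causal_interaction",
                paste0("names unknown exposure(s): ",
                       paste(missing_exp, collapse = ", ")))
  }
  if (is.null(covar_effects)) covar_effects <- numeric(0)
  structure(list(n_samples = n_samples, n_snps = n_snps,
                 maf_range = maf_range, ld_block_size = ld_block_size,
                 ld_decay = ld_decay, missing_rate = missing_rate,
                 exposure_specs = exposure_specs,
                 causal_main = causal_main,
                 causal_interaction = causal_interaction,
                 b_e = b_e, b0 = b0, covar_effects = covar_effects,
                 noise_sd = noise_sd, seed = seed),
            class = "simulation_config")
}

#' Simulate an LD-blocked genotype panel
#'
#' Each LD block shares one allele frequency drawn from `maf_range`; within a
#' block each haplotype allele copies the previous SNP's allele with
#' probability `ld_decay` and is redrawn otherwise, giving adjacent-SNP
#' dosage correlation close to `ld_decay`. Blocks are separated by 300 kb
#' (more than the 250 kb clumping window); within-block spacing is 2 kb.
#' Missingness is completely at random at `missing_rate`.
#'
#' @param config A [simulation_config()].
#' @return A [genotype_panel()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_snps
  bs <- config$ld_block_size
  block <- rep(seq_len(ceiling(m / bs)), each = bs)[seq_len(m)]
  n_blocks <- max(block)
  p_block <- stats::runif(n_blocks, config$maf_range[1], config$maf_range[2])
  hap <- function() {
    h <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      p <- p_block[block[j]]
      fresh <- stats::rbinom(n, 1L, p)
      if (j > 1L && block[j] == block[j - 1L] && config$ld_decay > 0) {
        copy <- stats::runif(n) < config$ld_decay
        h[, j] <- ifelse(copy, h[, j - 1L], fresh)
      } else {
        h[, j] <- fresh
      }
    }
    h
  }
  dosage <- hap() + hap()
  storage.mode(dosage) <- "double"
  if (config$missing_rate > 0) {
    dosage[stats::runif(n * m) < config$missing_rate] <- NA_real_
  }
  # positions: 2 kb within a block, 300 kb gap between blocks (> clump window)
  pos <- numeric(m)
  cur <- 1
  for (j in seq_len(m)) {
    if (j > 1L) {
      cur <- cur + if (block[j] == block[j - 1L]) 2000 else 300000
    }
    pos[j] <- cur
  }
  snps <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                     chrom = "1", pos = pos,
                     counted_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  genotype_panel(dosage, snps,
                 sample_ids = sprintf("S%05d", seq_len(n)))
}

#' Simulate zero-inflated exposure variables
#'
#' Each exposure is 0 with probability `zero_fraction` and lognormal
#' (`meanlog`, `sdlog`) otherwise; exposures are mutually independent.
#'
#' @param config A [simulation_config()] carrying `exposure_specs`.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Data frame with one non-negative column per exposure.
#' @export
simulate_exposures <- function(config, n = config$n_samples,
                               seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  n <- check_count(n, "n")
  set.seed(seed)
  out <- lapply(config$exposure_specs, function(sp) {
    zero <- stats::runif(n) < sp$zero_fraction
    val <- stats::rlnorm(n, sp$meanlog %||% 0, sp$sdlog %||% 1)
    ifelse(zero, 0, val)
  })
  as.data.frame(out)
}

simulate_covariates <- function(n, seed) {
  set.seed(seed)
  cv <- data.frame(age = stats::rnorm(n, 56.4, 7.5),
                   sex = stats::rbinom(n, 1, 0.5))
  for (k in 1:10) cv[[paste0("PC", k)]] <- stats::rnorm(n)
  cv
}

#' Simulate the primary phenotype from the generative model
#'
#' Applies `Y = b0 + sum(b_g G) + sum(b_e E) + sum(b_ge G*E) + covariate
#' effects + noise`. Missing dosages contribute the SNP's mean non-missing
#' dosage (twice the empirical allele frequency), matching the scan's
#' mean-imputation so noiseless data is recovered exactly.
#'
#' @param cohort List with `genotypes` ([genotype_panel()]), `exposures`, and
#'   `covariates` data frames (row-aligned to the panel's samples).
#' @param config The [simulation_config()] holding the true effects.
#' @param seed Seed for the Gaussian noise.
#' @return Named numeric vector of phenotype values (names = sample ids).
#' @export
simulate_phenotype <- function(cohort, config, seed = config$seed + 3L) {
  stopifnot(inherits(config, "simulation_config"))
  panel <- cohort$genotypes
  G <- impute_dosage(panel$dosage)
  n <- nrow(G)
  y <- rep(config$b0, n)
  warn_removable <- function(idx) {
    cr <- colMeans(!is.na(panel$dosage[, idx, drop = FALSE]))
    p <- colMeans(panel$dosage[, idx, drop = FALSE], na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    bad <- idx[cr < 0.90 | maf < 0.01]
    if (length(bad)) {
      warning("causal SNP(s) would fail default QC: ",
              paste(panel$snps$snp_id[bad], collapse = ", "), call. = FALSE)
    }
  }
  cm <- config$causal_main
  if (!is.null(cm) && nrow(cm)) {
    warn_removable(cm$snp)
    y <- y + G[, cm$snp, drop = FALSE] %*% cm$beta
  }
  for (nm in names(config$exposure_specs)) {
    e <- cohort$exposures[[nm]]
    y <- y + (config$b_e[[nm]] %||% 0) * e
    ci <- config$causal_interaction[[nm]]
    if (!is.null(ci) && nrow(ci)) {
      warn_removable(ci$snp)
      y <- y + (G[, ci$snp, drop = FALSE] %*% ci$beta) * e
    }
  }
  if (length(config$covar_effects)) {
    for (nm in names(config$covar_effects)) {
      y <- y + config$covar_effects[[nm]] * cohort$covariates[[nm]]
    }
  }
  if (config$noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(n, 0, config$noise_sd)
  }
  stats::setNames(as.numeric(y), rownames(panel$dosage))
}

#' Simulate a complete synthetic cohort
#'
#' Orchestrates [simulate_genotypes()], [simulate_exposures()], covariate
#' generation, and [simulate_phenotype()] under seeds derived from
#' `config$seed`, so identical configurations yield bit-identical cohorts.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort`: list with `genotypes`, `exposures`,
#'   `covariates`, `phenotype` (all sample-aligned), `true_effects`, and the
#'   `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  genotypes <- simulate_genotypes(config)
  ids <- rownames(genotypes$dosage)
  exposures <- simulate_exposures(config, config$n_samples,
                                  seed = config$seed + 1L)
  covariates <- simulate_covariates(config$n_samples, config$seed + 2L)
  exposures <- cbind(sample_id = ids, exposures, stringsAsFactors = FALSE)
  covariates <- cbind(sample_id = ids, covariates, stringsAsFactors = FALSE)
  cohort <- list(genotypes = genotypes,
                 exposures = exposures,
                 covariates = covariates)
  y <- simulate_phenotype(cohort, config, seed = config$seed + 3L)
  cohort$phenotype <- data.frame(sample_id = ids, phenotype = unname(y),
                                 stringsAsFactors = FALSE)
  cohort$true_effects <- list(causal_main = config$causal_main,
                              causal_interaction = config$causal_interaction,
                              b_e = config$b_e, b0 = config$b0,
                              noise_sd = config$noise_sd)
  cohort$config <- config
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d SNPs, exposures: %s\n",
              nrow(x$genotypes$dosage), ncol(x$genotypes$dosage),
              paste(names(x$config$exposure_specs), collapse = ", ")))
  invisible(x)
}

#' Simulate a secondary trait sharing the primary trait's causal loci
#'
#' Builds a trait from stated proportions of the primary phenotype's causal
#' main and interaction loci: the first `ceiling(share * k)` loci of each set
#' are reused with effect sizes rescaled by an independent `U(0.5, 1.5)`
#' factor (signs preserved), plus Gaussian noise. With `share_interaction =
#' 1, share_main = 0` the trait's genetic signal is purely gene-environment
#' interaction — the construction behind the PGIRS-vs-PRS contrast.
#'
#' @param cohort A `synthetic_cohort`.
#' @param share_main,share_interaction Proportions in `[0, 1]` of causal
#'   main / interaction loci shared with the primary trait.
#' @param trait_noise_sd Residual standard deviation of the trait.
#' @param seed Integer seed.
#' @return Named numeric vector of trait values.
#' @export
simulate_correlated_trait <- function(cohort, share_main = 0,
                                      share_interaction = 1,
                                      trait_noise_sd = 1,
                                      seed = cohort$config$seed + 4L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  check_scalar_number(share_main, "share_main", 0, 1)
  check_scalar_number(share_interaction, "share_interaction", 0, 1)
  check_scalar_number(trait_noise_sd, "trait_noise_sd", 0)
  set.seed(seed)
  G <- impute_dosage(cohort$genotypes$dosage)
  n <- nrow(G)
  y <- numeric(n)
  te <- cohort$true_effects
  take <- function(df, share) {
    k <- ceiling(share * nrow(df))
    if (k == 0) return(df[0, , drop = FALSE])
    df[seq_len(k), , drop = FALSE]
  }
  cm <- take(te$causal_main, share_main)
  if (nrow(cm)) {
    b <- cm$beta * stats::runif(nrow(cm), 0.5, 1.5)
    y <- y + G[, cm$snp, drop = FALSE] %*% b
  }
  for (nm in names(te$causal_interaction)) {
    ci <- take(te$causal_interaction[[nm]], share_interaction)
    if (nrow(ci)) {
      b <- ci$beta * stats::runif(nrow(ci), 0.5, 1.5)
      y <- y + (G[, ci$snp, drop = FALSE] %*% b) * cohort$exposures[[nm]]
    }
  }
  if (trait_noise_sd > 0) y <- y + stats::rnorm(n, 0, trait_noise_sd)
  stats::setNames(as.numeric(y), rownames(G))
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits the genotype panel in both the dosage-TSV dialect and VCF, the
#' exposure/covariate/phenotype study tables, and the true causal effects
#' (for parameter-recovery checks).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dosage_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_table(cohort$exposures, file.path(dir, "exposures.tsv"))
  write_table(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_table(cohort$phenotype, file.path(dir, "phenotype.tsv"))
  te <- cohort$true_effects
  rows <- data.frame(effect_type = character(0), exposure = character(0),
                     snp_id = character(0), beta = numeric(0))
  ids <- cohort$genotypes$snps$snp_id
  if (nrow(te$causal_main)) {
    rows <- rbind(rows, data.frame(effect_type = "main", exposure = "",
                                   snp_id = ids[te$causal_main$snp],
                                   beta = te$causal_main$beta))
  }
  for (nm in names(te$causal_interaction)) {
    ci <- te$causal_interaction[[nm]]
    if (nrow(ci)) {
      rows <- rbind(rows, data.frame(effect_type = "interaction",
                                     exposure = nm, snp_id = ids[ci$snp],
                                     beta = ci$beta))
    }
  }
  utils::write.table(rows, file.path(dir, "true_effects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
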