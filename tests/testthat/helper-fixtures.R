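# In-code fixtures shared across test files.

make_panel <- function(dosage, pos = NULL, chrom = "1",
                       ids = sprintf("rs%03d", seq_len(ncol(dosage)))) {
  if (is.null(pos)) pos <- seq_len(ncol(dosage)) * 1e6
  genotype_panel(dosage,
                 data.frame(snp_id = ids, chrom = chrom, pos = pos,
                            counted_allele = "A", other_allele = "G",
                            stringsAsFactors = FALSE))
}

random_panel <- function(n, m, seed = 1, maf = 0.3, missing_rate = 0) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, maf), n, m)
  storage.mode(d) <- "double"
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA
  make_panel(d)
}

# Small one-exposure cohort config used by several modules.
tiny_config <- function(n = 400, m = 60, seed = 42, noise_sd = 1,
                        ld_block_size = 5, ...) {
  simulation_config(
    n_samples = n, n_snps = m, ld_block_size = ld_block_size,
    exposure_specs = list(exposure = list(zero_fraction = 0.3,
                                          meanlog = 0, sdlog = 0.5)),
    noise_sd = noise_sd, seed = seed, ...)
}

# A handwritten 3-sample, 2-SNP VCF with GT calls.
write_gt_vcf_fixture <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tIND1\tIND2\tIND3",
    "1\t1000\trs1\tG\tA\t.\t.\t.\tGT\t0/0\t0/1\t1/1",
    "2\t5000\trs2\tT\tC\t.\t.\t.\tGT\t0|1\t./.\t1/1"), path)
  path
}
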