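#' Per-SNP quality-control thresholds
#'
#' SNPs with call rate below `min_call_rate`, HWE exact test P-value below
#' `min_hwe_p`, or minor allele frequency below `min_maf` are removed;
#' equality with a threshold passes (the removal rules are strict
#' inequalities).
#'
#' @param min_call_rate Minimum non-missing fraction (default 0.90).
#' @param min_hwe_p Minimum HWE exact P-value (default 0.001).
#' @param min_maf Minimum minor allele frequency (default 0.01).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_hwe_p = 0.001,
                          min_maf = 0.01) {
  check_scalar_number(min_call_rate, "min_call_rate", 0, 1)
  check_scalar_number(min_hwe_p, "min_hwe_p", 0, 1)
  check_scalar_number(min_maf, "min_maf", 0, 0.5)
  structure(list(min_call_rate = min_call_rate, min_hwe_p = min_hwe_p,
                 min_maf = min_maf), class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test on hard genotype counts. Conditional on the observed
#' allele counts, the probability of every heterozygote count of the same
#' parity is evaluated and those no more probable than the observed
#' configuration are summed (no mid-P correction).
#'
#' @param n_hom_ref,n_het,n_hom_alt Non-negative genotype counts.
#' @return Exact P-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("hwe_exact_test: genotype counts must be non-negative integers",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) {
    stop("hwe_exact_test: all genotype counts are zero", call. = FALSE)
  }
  nA <- 2 * n_hom_ref + n_het
  nB <- 2 * n_hom_alt + n_het
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  h <- seq.int(rare %% 2, rare, by = 2)
  # log P(h) up to a shared constant, conditional on allele counts
  lp <- -lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((nB - h) / 2 + 1) + h * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[h == n_het]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Per-SNP call rate and minor allele frequency
#'
#' Call rate is the non-missing fraction; MAF is `min(p, 1 - p)` with `p`
#' half the mean non-missing dosage (continuous dosages allowed). An
#' all-missing column yields call rate 0 and `NA` MAF.
#'
#' @param dosage Numeric dosage vector for one SNP (NA = missing).
#' @return A proportion ([snp_call_rate()]) or a frequency ([snp_maf()]).
#' @export
snp_call_rate <- function(dosage) {
  if (!length(dosage)) stop("snp_call_rate: empty column", call. = FALSE)
  mean(!is.na(dosage))
}

#' @rdname snp_call_rate
#' @export
snp_maf <- function(dosage) {
  if (!length(dosage)) stop("snp_maf: empty column", call. = FALSE)
  if (all(is.na(dosage))) return(NA_real_)
  p <- mean(dosage, na.rm = TRUE) / 2
  min(p, 1 - p)
}

#' Apply per-SNP quality control to a genotype panel
#'
#' A SNP is kept iff `call_rate >= min_call_rate`, `hwe_p >= min_hwe_p`, and
#' `maf >= min_maf`. The HWE exact test needs hard genotype calls: dosages
#' are rounded to the nearest integer, and SNPs with any dosage farther than
#' 1e-6 from an integer skip the HWE rule (noted in the report) since the
#' exact test is defined on genotype counts only. The sample set is never
#' changed.
#'
#' @param panel A [genotype_panel()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `panel` (filtered) and `report` (per-SNP data frame
#'   with `call_rate`, `maf`, `hwe_p`, `kept`, `reasons`, `note`).
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(thresholds, "qc_thresholds"))
  if (ncol(panel$dosage) == 0L) stop("apply_qc: empty panel", call. = FALSE)
  m <- ncol(panel$dosage)
  cr <- apply(panel$dosage, 2L, snp_call_rate)
  maf <- apply(panel$dosage, 2L, snp_maf)
  hwe <- rep(NA_real_, m)
  note <- character(m)
  for (j in seq_len(m)) {
    d <- panel$dosage[, j]
    d <- d[!is.na(d)]
    if (!length(d)) {
      note[j] <- "all_missing"
      next
    }
    hard <- round(d)
    if (any(abs(d - hard) > 1e-6)) {
      note[j] <- "non_integer_dosage_hwe_skipped"
      next
    }
    hwe[j] <- hwe_exact_test(sum(hard == 0), sum(hard == 1), sum(hard == 2))
  }
  fail_cr <- cr < thresholds$min_call_rate
  fail_maf <- !is.na(maf) & maf < thresholds$min_maf
  fail_hwe <- !is.na(hwe) & hwe < thresholds$min_hwe_p
  reasons <- vapply(seq_len(m), function(j) {
    paste(c(if (fail_cr[j]) "call_rate",
            if (fail_hwe[j]) "hwe",
            if (fail_maf[j]) "maf"), collapse = ",")
  }, character(1))
  kept <- !(fail_cr | fail_maf | fail_hwe)
  report <- data.frame(snp_id = panel$snps$snp_id, call_rate = cr,
                       maf = maf, hwe_p = hwe, kept = kept,
                       reasons = reasons, note = note,
                       stringsAsFactors = FALSE)
  filtered <- genotype_panel(panel$dosage[, kept, drop = FALSE],
                             panel$snps[kept, , drop = FALSE],
                             rownames(panel$dosage))
  list(panel = filtered, report = report)
}
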