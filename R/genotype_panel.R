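#' Construct a genotype panel
#'
#' A genotype panel bundles a sample-by-SNP dosage matrix with per-SNP
#' metadata. Dosages are expected counts of the counted allele in `[0, 2]`;
#' `NA` encodes a missing call and is distinct from dosage 0.
#'
#' @param dosage Numeric matrix, samples in rows, SNPs in columns. Row names
#'   (or `sample_ids`) identify samples; column names must match
#'   `snps$snp_id`.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos` (1-based),
#'   `counted_allele`, `other_allele`, one row per SNP in column order.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage` and `snps`.
#' @export
genotype_panel <- function(dosage, snps, sample_ids = rownames(dosage)) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%05d", seq_len(nrow(dosage)))
  }
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("genotype panel: duplicated sample identifiers", call. = FALSE)
  }
  req <- c("snp_id", "chrom", "pos", "counted_allele", "other_allele")
  missing_cols <- setdiff(req, names(snps))
  if (length(missing_cols)) {
    stop("genotype panel: snps table lacks column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  snps <- as.data.frame(snps)[, req]
  snps$snp_id <- as.character(snps$snp_id)
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.numeric(snps$pos)
  if (anyDuplicated(snps$snp_id)) {
    stop("genotype panel: duplicated SNP identifiers", call. = FALSE)
  }
  if (ncol(dosage) != nrow(snps)) {
    stop("genotype panel: dosage has ", ncol(dosage),
         " columns but snps table has ", nrow(snps), " rows", call. = FALSE)
  }
  # positions ascending within each chromosome run (VCF file order)
  for (ch in unique(snps$chrom)) {
    p <- snps$pos[snps$chrom == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop("genotype panel: positions not strictly increasing on chromosome ",
           ch, call. = FALSE)
    }
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 2)) {
    stop("genotype panel: dosages must lie in [0, 2]", call. = FALSE)
  }
  rownames(dosage) <- sample_ids
  colnames(dosage) <- snps$snp_id
  structure(list(dosage = dosage, snps = snps), class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a panel to a set of SNPs
#'
#' @param panel A `genotype_panel`.
#' @param snp_ids Character vector of SNP identifiers to keep (order kept
#'   as in the panel).
#' @return A `genotype_panel` restricted to the requested SNPs.
#' @export
subset_snps <- function(panel, snp_ids) {
  keep <- panel$snps$snp_id %in% snp_ids
  genotype_panel(panel$dosage[, keep, drop = FALSE],
                 panel$snps[keep, , drop = FALSE],
                 rownames(panel$dosage))
}

sample_ids <- function(panel) rownames(panel$dosage)
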