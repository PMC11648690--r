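#' Read a biallelic VCF into a genotype panel
#'
#' Dosages are taken from the `DS` FORMAT field when present, otherwise from
#' `GT` as the count of ALT alleles (`./.` becomes missing). The counted
#' allele is always ALT. Multiallelic records are rejected.
#'
#' @param path Path to a VCF file (plain or bgzipped, v4.2).
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read VCF: no such file: ", path, call. = FALSE)
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1L]
    stop(sprintf("multiallelic record at %s:%s not supported",
                 fix[i, "CHROM"], fix[i, "POS"]), call. = FALSE)
  }
  fmt <- v@gt[, "FORMAT"]
  has_ds <- all(vapply(strsplit(fmt, ":", fixed = TRUE),
                       function(f) "DS" %in% f, logical(1)))
  if (has_ds) {
    dm <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dm <- apply(gt, c(1, 2), gt_to_dosage)
  }
  ids <- fix[, "ID"]
  need_id <- is.na(ids) | ids == "."
  ids[need_id] <- paste0(fix[need_id, "CHROM"], ":", fix[need_id, "POS"])
  snps <- data.frame(snp_id = ids,
                     chrom = fix[, "CHROM"],
                     pos = as.numeric(fix[, "POS"]),
                     counted_allele = alt,
                     other_allele = fix[, "REF"],
                     stringsAsFactors = FALSE)
  genotype_panel(t(dm), snps, sample_ids = colnames(dm))
}

gt_to_dosage <- function(g) {
  if (is.na(g)) return(NA_real_)
  alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)[[1L]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles == "1")
}

#' Write a genotype panel as a VCF with DS dosages
#'
#' Emits a plain-text VCF v4.2 whose single FORMAT field is `DS`; missing
#' dosages are written as `.`. REF is the other allele, ALT the counted
#' allele, so [read_vcf()] round-trips the panel.
#'
#' @param panel A [genotype_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  s <- panel$snps
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(panel$dosage)), collapse = "\t"))
  body <- vapply(seq_len(nrow(s)), function(j) {
    d <- panel$dosage[, j]
    vals <- ifelse(is.na(d), ".", sprintf("%.17g", d))
    paste(c(s$chrom[j], format(s$pos[j], scientific = FALSE), s$snp_id[j],
            s$other_allele[j], s$counted_allele[j], ".", ".", ".", "DS",
            vals), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read/write the tabular dosage dialect
#'
#' The dosage TSV has a `sample_id` column followed by one numeric column per
#' SNP (header row carries SNP ids); missing dosages are `NA`. SNP metadata
#' (chromosome, position, alleles) travels in a companion file
#' `<path>.snps.tsv`; when the companion is absent on read, SNPs are placed
#' on chromosome `"1"` at 1 Mb spacing with alleles `A`/`B`.
#'
#' @param path Path of the dosage TSV.
#' @return [read_dosage_tsv()] returns a [genotype_panel()].
#' @export
read_dosage_tsv <- function(path) {
  tab <- read_numeric_tsv(path, key = "sample_id")
  meta_path <- paste0(path, ".snps.tsv")
  m <- as.matrix(tab[, setdiff(names(tab), "sample_id"), drop = FALSE])
  if (file.exists(meta_path)) {
    snps <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                              colClasses = "character")
    snps$pos <- as.numeric(snps$pos)
  } else {
    snps <- data.frame(snp_id = colnames(m), chrom = "1",
                       pos = seq_len(ncol(m)) * 1e6,
                       counted_allele = "A", other_allele = "B",
                       stringsAsFactors = FALSE)
  }
  genotype_panel(m, snps, sample_ids = tab$sample_id)
}

#' @rdname read_dosage_tsv
#' @param panel A [genotype_panel()] to write.
#' @export
write_dosage_tsv <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", panel$snps$snp_id), collapse = "\t"), con)
  for (i in seq_len(nrow(panel$dosage))) {
    writeLines(paste(c(rownames(panel$dosage)[i],
                       format_full(panel$dosage[i, ])), collapse = "\t"), con)
  }
  s <- panel$snps
  s$pos <- format(s$pos, scientific = FALSE, trim = TRUE)
  utils::write.table(s, paste0(path, ".snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write study tables
#'
#' Study tables are TSVs with a `sample_id` key column and named numeric
#' columns (phenotypes, exposures, covariates). Writing renders floats at
#' full round-trip precision; `NA` encodes missing values.
#'
#' @param path File path.
#' @return [read_table()] returns a data frame keyed by `sample_id`.
#' @export
read_table <- function(path) {
  read_numeric_tsv(path, key = "sample_id")
}

#' @rdname read_table
#' @param table Data frame with a `sample_id` column and numeric columns.
#' @export
write_table <- function(table, path) {
  stopifnot("sample_id" %in% names(table))
  if (anyDuplicated(table$sample_id)) {
    stop("write_table: duplicated sample_id values", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  cols <- names(table)
  writeLines(paste(cols, collapse = "\t"), con)
  num <- setdiff(cols, "sample_id")
  if (nrow(table)) {
    mat <- vapply(num, function(cn) format_full(as.numeric(table[[cn]])),
                  character(nrow(table)))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(table))
    lines <- apply(cbind(as.character(table$sample_id), mat), 1L,
                   paste, collapse = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

# Shared strict numeric-TSV reader: header required, unique ids, every
# non-key cell numeric or "NA", errors name the offending row/column.
read_numeric_tsv <- function(path, key = "sample_id") {
  if (!file.exists(path)) {
    stop("cannot read table: no such file: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (!(key %in% names(raw))) {
    stop("table ", path, " lacks required key column `", key, "`",
         call. = FALSE)
  }
  if (anyDuplicated(names(raw))) {
    stop("table ", path, ": duplicated column names", call. = FALSE)
  }
  if (anyDuplicated(raw[[key]])) {
    stop("table ", path, ": duplicated `", key, "` values", call. = FALSE)
  }
  for (cn in setdiff(names(raw), key)) {
    v <- raw[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & !(v %in% c("NA", "", "NaN")))
    if (length(bad)) {
      stop(sprintf("table %s: non-numeric value '%s' at row %d, column %s",
                   path, v[bad[1L]], bad[1L], cn), call. = FALSE)
    }
    raw[[cn]] <- num
  }
  raw
}
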