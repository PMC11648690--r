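#' LD clumping parameters
#'
#' Defaults follow the standard clumping recipe for score construction: a
#' 250 kb window, an \eqn{r^2} threshold of 0.2, and the genome-wide
#' suggestive inclusion threshold `P = 1e-5` (with `P = 0.05` as the usual
#' sensitivity setting).
#'
#' @param p_threshold Candidate inclusion P-value threshold (strict `<`).
#' @param window_bp Clumping window in base pairs, measured symmetrically
#'   from the index SNP, boundary inclusive.
#' @param r2_threshold Squared-correlation threshold at or above which a
#'   nearby candidate is absorbed by the index SNP.
#' @param p_source Label of the ranking P-value column (`"main"` or
#'   `"interaction:<exposure>"`); recorded as the effect type of the output.
#' @return A `clump_params` list.
#' @export
clump_params <- function(p_threshold = 1e-5, window_bp = 250000,
                         r2_threshold = 0.2, p_source = "main") {
  check_scalar_number(p_threshold, "p_threshold", 0, 1, lower_open = TRUE)
  check_scalar_number(window_bp, "window_bp", 0, Inf, lower_open = TRUE)
  check_scalar_number(r2_threshold, "r2_threshold", 0, 1)
  structure(list(p_threshold = p_threshold, window_bp = window_bp,
                 r2_threshold = r2_threshold, p_source = p_source),
            class = "clump_params")
}

#' Squared LD correlation between two dosage vectors
#'
#' Pearson correlation squared, after mean-imputing missing dosages. A
#' zero-variance vector makes the correlation undefined; it is treated as
#' \eqn{r^2 = 0}.
#'
#' @param dosage_a,dosage_b Numeric dosage vectors of equal length.
#' @return Squared correlation in `[0, 1]`.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b), length(dosage_a) >= 2L)
  a <- dosage_a
  b <- dosage_b
  if (anyNA(a)) a[is.na(a)] <- mean(a, na.rm = TRUE)
  if (anyNA(b)) b[is.na(b)] <- mean(b, na.rm = TRUE)
  if (stats::var(a) == 0 || stats::var(b) == 0) return(0)
  stats::cor(a, b)^2
}

#' Greedy P-value-ordered LD clumping
#'
#' Repeatedly takes the smallest-P remaining candidate as an index SNP and
#' removes all remaining candidates on the same chromosome within
#' `window_bp` of it whose in-sample \eqn{r^2} with the index is at or above
#' `r2_threshold`. P-value ties break by (chromosome, position, snp_id)
#' ascending, so the output is deterministic and independent of candidate
#' ordering.
#'
#' @param candidates Data frame with `snp_id`, `chrom`, `pos`, `p`, `beta`,
#'   and optionally `counted_allele` (e.g. from [gweis_candidates()]).
#' @param panel [genotype_panel()] supplying in-sample dosages for
#'   \eqn{r^2}; candidate ids and positions must match the panel.
#' @param params A [clump_params()].
#' @return An `effect_set`: data frame `snp_id`, `counted_allele`, `weight`,
#'   `p`, `chrom`, `pos` of index SNPs, with attributes `effect_type` and
#'   `params`.
#' @export
ld_clump <- function(candidates, panel, params = clump_params()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(params, "clump_params"))
  need <- c("snp_id", "chrom", "pos", "p", "beta")
  if (!all(need %in% names(candidates))) {
    stop("ld_clump: candidates need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  idx <- match(candidates$snp_id, panel$snps$snp_id)
  if (anyNA(idx)) {
    stop("ld_clump: candidate SNP(s) absent from panel: ",
         paste(utils::head(candidates$snp_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  mismatch <- candidates$pos != panel$snps$pos[idx] |
    candidates$chrom != panel$snps$chrom[idx]
  if (any(mismatch)) {
    stop("ld_clump: position/chromosome mismatch with panel for: ",
         paste(utils::head(candidates$snp_id[mismatch], 5), collapse = ", "),
         call. = FALSE)
  }
  if (!("counted_allele" %in% names(candidates))) {
    candidates$counted_allele <- panel$snps$counted_allele[idx]
  }
  keep <- !is.na(candidates$p) & candidates$p < params$p_threshold
  cand <- candidates[keep, , drop = FALSE]
  cand <- cand[order(cand$p, cand$chrom, cand$pos, cand$snp_id), ,
               drop = FALSE]
  dos <- impute_dosage(panel$dosage[, match(cand$snp_id, panel$snps$snp_id),
                                    drop = FALSE])
  alive <- rep(TRUE, nrow(cand))
  index <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!alive[i]) next
    index[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive &
                    cand$chrom == cand$chrom[i] &
                    abs(cand$pos - cand$pos[i]) <= params$window_bp)
    if (length(near)) {
      r2 <- vapply(near, function(j) ld_r2(dos[, i], dos[, j]), numeric(1))
      alive[near[r2 >= params$r2_threshold]] <- FALSE
    }
  }
  out <- data.frame(snp_id = cand$snp_id[index],
                    counted_allele = cand$counted_allele[index],
                    weight = cand$beta[index],
                    p = cand$p[index],
                    chrom = cand$chrom[index],
                    pos = cand$pos[index],
                    stringsAsFactors = FALSE)
  # stable presentation order: genomic
  out <- out[order(out$chrom, out$pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, effect_type = params$p_source, params = params,
            class = c("effect_set", "data.frame"))
}

#' Write / read an effect set TSV
#'
#' Columns: `ID A1 EFFECT_TYPE BETA P CHR POS`.
#'
#' @param effects An `effect_set`.
#' @param path File path.
#' @return [read_effect_set()] returns an `effect_set`.
#' @export
write_effect_set <- function(effects, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("ID", "A1", "EFFECT_TYPE", "BETA", "P", "CHR", "POS"),
                   collapse = "\t"), con)
  if (nrow(effects)) {
    et <- attr(effects, "effect_type") %||% "main"
    lines <- apply(cbind(effects$snp_id, effects$counted_allele, et,
                         format_full(effects$weight), format_full(effects$p),
                         effects$chrom,
                         format(effects$pos, scientific = FALSE, trim = TRUE)),
                   1L, paste, collapse = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_effect_set
#' @export
read_effect_set <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  out <- data.frame(snp_id = raw$ID, counted_allele = raw$A1,
                    weight = as.numeric(raw$BETA), p = as.numeric(raw$P),
                    chrom = raw$CHR, pos = as.numeric(raw$POS),
                    stringsAsFactors = FALSE)
  structure(out, effect_type = if (nrow(raw)) raw$EFFECT_TYPE[1L] else "main",
            class = c("effect_set", "data.frame"))
}
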