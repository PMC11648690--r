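#' Residualize an outcome on covariates
#'
#' Ordinary least squares of the outcome on the covariates plus an
#' intercept; the residuals are the adjusted outcome used by the scan
#' (mirroring the practice of regressing a quantitative symptom score on
#' age, sex, socioeconomic covariates and principal components before
#' genome-wide analysis). Rows with missing covariate or outcome values are
#' dropped and recorded.
#'
#' @param outcome Named numeric vector (names = sample ids).
#' @param covariates Data frame of numeric covariate columns row-aligned to
#'   `outcome`, or `NULL`/zero-column for intercept-only adjustment.
#' @return An `adjusted_phenotype`: list with `residuals` (named numeric,
#'   mean zero), `covariates_used`, and `dropped` (ids of removed rows).
#' @export
residualize <- function(outcome, covariates = NULL) {
  if (is.null(names(outcome))) {
    names(outcome) <- sprintf("S%05d", seq_along(outcome))
  }
  if (is.null(covariates) || NCOL(covariates) == 0L) {
    keep <- !is.na(outcome)
    res <- outcome[keep] - mean(outcome[keep])
    return(structure(list(residuals = res, covariates_used = character(0),
                          dropped = names(outcome)[!keep]),
                     class = "adjusted_phenotype"))
  }
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(outcome))
  keep <- !is.na(outcome) & stats::complete.cases(covariates)
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates[keep, , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("residualize: collinear covariate column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  res <- stats::setNames(qr.resid(qx, outcome[keep]), names(outcome)[keep])
  structure(list(residuals = res, covariates_used = colnames(covariates),
                 dropped = names(outcome)[!keep]),
            class = "adjusted_phenotype")
}

#' Genome-wide SNP association and SNP-environment interaction scan
#'
#' For every SNP and every exposure, fits the ordinary least squares model
#' \deqn{y = b_0 + b_g G + b_e E + b_{ge} G \cdot E + \varepsilon} on
#' samples with complete outcome and exposure data, reporting coefficient
#' estimates, standard errors, and two-sided t-test P-values. One model is
#' fitted per (SNP, exposure) pair. Missing dosages are mean-imputed (twice
#' the in-sample allele frequency); SNPs monomorphic among analyzed samples
#' are reported with `NA` estimates and a `monomorphic` note.
#'
#' @param panel A (QC'd) [genotype_panel()].
#' @param y Adjusted outcome: an [residualize()] result or a named numeric
#'   vector keyed by sample id.
#' @param exposures Data frame with `sample_id` plus one numeric column per
#'   exposure to scan.
#' @param exposure_cols Exposure column names (default: all non-key
#'   columns).
#' @param covariates Optional data frame (`sample_id` + numeric columns) of
#'   covariates to include inside each SNP model instead of, or in addition
#'   to, pre-residualization.
#' @return A `gweis_result` data frame: one row per (SNP, exposure) with
#'   `snp_id`, `chrom`, `pos`, `counted_allele`, `exposure`, `b_g`, `se_g`,
#'   `p_g`, `b_e`, `se_e`, `b_ge`, `se_ge`, `p_ge`, `n_used`, `note`.
#' @export
gweis_scan <- function(panel, y, exposures, exposure_cols = NULL,
                       covariates = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (inherits(y, "adjusted_phenotype")) y <- y$residuals
  if (is.null(names(y))) {
    stop("gweis_scan: outcome must be named by sample id", call. = FALSE)
  }
  if (is.null(exposure_cols)) {
    exposure_cols <- setdiff(names(exposures), "sample_id")
  }
  absent <- setdiff(exposure_cols, names(exposures))
  if (length(absent)) {
    stop("gweis_scan: exposure column(s) not found: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ids <- intersect(sample_ids(panel), names(y))
  if ("sample_id" %in% names(exposures)) {
    ids <- intersect(ids, exposures$sample_id)
    erow <- match(ids, exposures$sample_id)
  } else {
    stopifnot(nrow(exposures) == nrow(panel$dosage))
    erow <- match(ids, sample_ids(panel))
  }
  cov_mat <- NULL
  if (!is.null(covariates)) {
    crow <- match(ids, covariates$sample_id)
    cov_mat <- as.matrix(covariates[crow,
                                    setdiff(names(covariates), "sample_id"),
                                    drop = FALSE])
  }
  prow <- match(ids, sample_ids(panel))
  yv <- y[ids]
  out <- vector("list", length(exposure_cols))
  for (ei in seq_along(exposure_cols)) {
    ename <- exposure_cols[ei]
    E_all <- exposures[[ename]][erow]
    ok <- !is.na(yv) & !is.na(E_all)
    if (!is.null(cov_mat)) ok <- ok & stats::complete.cases(cov_mat)
    E <- E_all[ok]
    yy <- yv[ok]
    Gm <- impute_dosage(panel$dosage[prow[ok], , drop = FALSE])
    n_used <- length(yy)
    m <- ncol(Gm)
    res <- matrix(NA_real_, m, 7,
                  dimnames = list(NULL, c("b_g", "se_g", "p_g", "b_e",
                                          "se_e", "b_ge", "se_ge")))
    p_ge <- rep(NA_real_, m)
    note <- character(m)
    base <- if (is.null(cov_mat)) NULL else cov_mat[ok, , drop = FALSE]
    for (j in seq_len(m)) {
      g <- Gm[, j]
      if (length(unique(g)) < 2L) {
        note[j] <- "monomorphic"
        next
      }
      X <- cbind(`(Intercept)` = 1, G = g, E = E, GxE = g * E)
      if (!is.null(base)) X <- cbind(X, base)
      fit <- ols_fit(X, yy)
      res[j, ] <- c(fit$coef["G"], fit$se["G"], fit$p["G"],
                    fit$coef["E"], fit$se["E"],
                    fit$coef["GxE"], fit$se["GxE"])
      p_ge[j] <- fit$p["GxE"]
    }
    out[[ei]] <- data.frame(snp_id = panel$snps$snp_id,
                            chrom = panel$snps$chrom,
                            pos = panel$snps$pos,
                            counted_allele = panel$snps$counted_allele,
                            exposure = ename,
                            as.data.frame(res),
                            p_ge = p_ge,
                            n_used = n_used,
                            note = note,
                            stringsAsFactors = FALSE)
  }
  result <- do.call(rbind, out)
  rownames(result) <- NULL
  class(result) <- c("gweis_result", "data.frame")
  result
}

#' Write / read a scan summary TSV
#'
#' Column layout: `CHR POS ID A1 EXPOSURE BETA_G SE_G P_G BETA_E SE_E
#' BETA_GxE SE_GxE P_GxE N`. Floats are rendered at full round-trip
#' precision so write-read-write is lossless.
#'
#' @param result A `gweis_result`.
#' @param path File path.
#' @return [read_gweis_summary()] returns a `gweis_result`.
#' @export
write_gweis_summary <- function(result, path) {
  cols <- c("CHR", "POS", "ID", "A1", "EXPOSURE", "BETA_G", "SE_G", "P_G",
            "BETA_E", "SE_E", "BETA_GxE", "SE_GxE", "P_GxE", "N")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(result)) {
    lines <- apply(cbind(result$chrom,
                         format(result$pos, scientific = FALSE, trim = TRUE),
                         result$snp_id, result$counted_allele,
                         result$exposure,
                         format_full(result$b_g), format_full(result$se_g),
                         format_full(result$p_g), format_full(result$b_e),
                         format_full(result$se_e), format_full(result$b_ge),
                         format_full(result$se_ge), format_full(result$p_ge),
                         as.character(result$n_used)),
                   1L, paste, collapse = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_gweis_summary
#' @export
read_gweis_summary <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  num <- function(x) suppressWarnings(as.numeric(x))
  result <- data.frame(snp_id = raw$ID, chrom = raw$CHR, pos = num(raw$POS),
                       counted_allele = raw$A1, exposure = raw$EXPOSURE,
                       b_g = num(raw$BETA_G), se_g = num(raw$SE_G),
                       p_g = num(raw$P_G), b_e = num(raw$BETA_E),
                       se_e = num(raw$SE_E), b_ge = num(raw$BETA_GxE),
                       se_ge = num(raw$SE_GxE), p_ge = num(raw$P_GxE),
                       n_used = as.integer(raw$N), note = "",
                       stringsAsFactors = FALSE)
  class(result) <- c("gweis_result", "data.frame")
  result
}

#' Extract clumping candidates from a scan result
#'
#' Maps a `gweis_result` to the (SNP, position, P, weight) list consumed by
#' [ld_clump()]: main-effect candidates rank by `p_g` and carry `b_g`;
#' interaction candidates rank by `p_ge` of the given exposure and carry
#' `b_ge`. Rows with undefined estimates (e.g. monomorphic SNPs) are
#' dropped.
#'
#' @param result A `gweis_result`.
#' @param effect `"main"` or `"interaction"`.
#' @param exposure Exposure name; defaults to the scan's first exposure.
#' @return Data frame `snp_id`, `chrom`, `pos`, `counted_allele`, `p`,
#'   `beta`.
#' @export
gweis_candidates <- function(result, effect = c("main", "interaction"),
                             exposure = NULL) {
  effect <- match.arg(effect)
  if (is.null(exposure)) exposure <- result$exposure[1L]
  rows <- result[result$exposure == exposure, , drop = FALSE]
  if (!nrow(rows)) {
    stop("gweis_candidates: no rows for exposure '", exposure, "'",
         call. = FALSE)
  }
  if (effect == "main") {
    out <- data.frame(snp_id = rows$snp_id, chrom = rows$chrom,
                      pos = rows$pos, counted_allele = rows$counted_allele,
                      p = rows$p_g, beta = rows$b_g,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(snp_id = rows$snp_id, chrom = rows$chrom,
                      pos = rows$pos, counted_allele = rows$counted_allele,
                      p = rows$p_ge, beta = rows$b_ge,
                      stringsAsFactors = FALSE)
  }
  out[!is.na(out$p), , drop = FALSE]
}
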