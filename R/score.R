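#' Polygenic risk score
#'
#' \deqn{\mathrm{PRS} = \sum_{i=1}^{j} b_{gi} d_i} — the weighted sum of
#' counted-allele dosages over the main-effect set. Missing dosages are
#' replaced by the SNP's mean non-missing dosage. If an effect entry's
#' counted allele is the panel's other allele, the dosage is flipped as
#' `2 - d` (a note is emitted), which is mathematically equivalent to
#' re-polarizing the weight.
#'
#' @param panel A [genotype_panel()].
#' @param effects An `effect_set` of main-effect weights.
#' @return Named numeric vector of per-sample scores, with attribute
#'   `n_snps` (number of SNPs used).
#' @export
compute_prs <- function(panel, effects) {
  D <- effect_dosage_matrix(panel, effects)
  score <- drop(D %*% effects$weight)
  structure(stats::setNames(score, rownames(panel$dosage)),
            n_snps = nrow(effects))
}

#' Gene-environment interaction risk score
#'
#' \deqn{\mathrm{GIRS} = \left(\sum_{k=1}^{m} b_{gek} f_k\right) \cdot e} —
#' the interaction-weighted dosage sum multiplied by each individual's own
#' exposure value `e` (raw, unstandardized). Samples with missing exposure
#' are excluded from the result.
#'
#' @param panel A [genotype_panel()].
#' @param effects An `effect_set` of interaction weights for one exposure.
#' @param exposure Named numeric vector of exposure values keyed by sample
#'   id (or unnamed, row-aligned to the panel).
#' @param standardize_exposure If `TRUE`, z-score the exposure before
#'   multiplying (off by default: the score formula uses the raw exposure).
#' @return Named numeric vector of per-sample scores (samples with missing
#'   exposure dropped), with attribute `n_snps`.
#' @export
compute_girs <- function(panel, effects, exposure,
                         standardize_exposure = FALSE) {
  if (is.null(names(exposure))) {
    stopifnot(length(exposure) == nrow(panel$dosage))
    names(exposure) <- rownames(panel$dosage)
  }
  ids <- intersect(rownames(panel$dosage), names(exposure))
  e <- exposure[ids]
  keep <- !is.na(e)
  ids <- ids[keep]
  e <- e[keep]
  if (standardize_exposure) e <- as.numeric(scale(e))
  D <- effect_dosage_matrix(panel, effects)[ids, , drop = FALSE]
  score <- drop(D %*% effects$weight) * e
  structure(stats::setNames(score, ids), n_snps = nrow(effects))
}

#' Combine PRS and per-exposure GIRS into PGIRS
#'
#' \deqn{\mathrm{PGIRS} = \mathrm{PRS} + \sum \mathrm{GIRS}} — elementwise
#' over samples, aligned by sample id. With no GIRS inputs, PGIRS equals
#' PRS. Sample sets must agree (the score table covers the intersection of
#' genotyped and exposure-measured samples; callers pass aligned inputs).
#'
#' @param prs Named numeric vector from [compute_prs()].
#' @param ... Named `GIRS` vectors from [compute_girs()], one per exposure
#'   (argument names become `GIRS_<name>` columns).
#' @return A `score_table` data frame: `sample_id`, `PRS`,
#'   `GIRS_<exposure>`..., `PGIRS`, plus `n_snps_*` attributes.
#' @export
compute_pgirs <- function(prs, ...) {
  girs <- list(...)
  ids <- names(prs)
  for (g in girs) {
    if (is.null(names(g))) {
      stop("compute_pgirs: GIRS inputs must be named by sample id",
           call. = FALSE)
    }
    ids <- intersect(ids, names(g))
  }
  if (length(girs) &&
      !all(vapply(girs, function(g) setequal(names(g), ids) &&
                    setequal(names(prs), ids), logical(1)))) {
    stop("compute_pgirs: sample sets of PRS and GIRS inputs are misaligned",
         call. = FALSE)
  }
  out <- data.frame(sample_id = ids, PRS = unname(prs[ids]),
                    stringsAsFactors = FALSE)
  total <- out$PRS
  n_snps <- list(PRS = attr(prs, "n_snps"))
  if (length(girs)) {
    if (is.null(names(girs)) || any(names(girs) == "")) {
      names(girs) <- paste0("e", seq_along(girs))
    }
    for (nm in names(girs)) {
      col <- paste0("GIRS_", nm)
      out[[col]] <- unname(girs[[nm]][ids])
      total <- total + out[[col]]
      n_snps[[col]] <- attr(girs[[nm]], "n_snps")
    }
  }
  out$PGIRS <- total
  structure(out, n_snps = n_snps, class = c("score_table", "data.frame"))
}

#' Compute all scores for a panel and exposure table
#'
#' Convenience wrapper: PRS from the main effect set, one GIRS per
#' interaction effect set, and their PGIRS sum. The result covers samples
#' with genotypes and complete exposures.
#'
#' @param panel A [genotype_panel()].
#' @param main_effects `effect_set` of main-effect weights.
#' @param interaction_effects Named list of interaction `effect_set`s, one
#'   per exposure (names must match exposure columns).
#' @param exposures Data frame with `sample_id` and exposure columns.
#' @param standardize_exposure Passed to [compute_girs()].
#' @return A `score_table`.
#' @export
compute_scores <- function(panel, main_effects, interaction_effects,
                           exposures, standardize_exposure = FALSE) {
  prs <- compute_prs(panel, main_effects)
  girs <- lapply(names(interaction_effects), function(nm) {
    e <- stats::setNames(exposures[[nm]], exposures$sample_id)
    compute_girs(panel, interaction_effects[[nm]], e,
                 standardize_exposure = standardize_exposure)
  })
  names(girs) <- names(interaction_effects)
  keep <- Reduce(intersect, c(list(names(prs)), lapply(girs, names)))
  prs <- structure(prs[keep], n_snps = attr(prs, "n_snps"))
  girs <- lapply(girs, function(g) structure(g[keep],
                                             n_snps = attr(g, "n_snps")))
  do.call(compute_pgirs, c(list(prs = prs), girs))
}

# Dosage matrix restricted to an effect set, mean-imputed, allele-aligned.
effect_dosage_matrix <- function(panel, effects) {
  stopifnot(inherits(panel, "genotype_panel"))
  idx <- match(effects$snp_id, panel$snps$snp_id)
  if (anyNA(idx)) {
    stop("effect SNP(s) absent from panel: ",
         paste(effects$snp_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  D <- impute_dosage(panel$dosage[, idx, drop = FALSE])
  flip <- effects$counted_allele != panel$snps$counted_allele[idx]
  if (any(flip)) {
    bad <- flip & effects$counted_allele != panel$snps$other_allele[idx]
    if (any(bad)) {
      stop("effect allele matches neither panel allele for: ",
           paste(effects$snp_id[bad], collapse = ", "), call. = FALSE)
    }
    message("flipping dosage (2 - d) for ", sum(flip),
            " SNP(s) counted on the opposite allele")
    D[, flip] <- 2 - D[, flip, drop = FALSE]
  }
  D
}
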