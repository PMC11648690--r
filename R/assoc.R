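#' Define an exposure stratum
#'
#' A stratum is a named deterministic predicate over a study table plus any
#' stratum-specific extra covariates (e.g. adjusting smoking strata for
#' drinking frequency).
#'
#' @param name Stratum label.
#' @param predicate Function taking the merged analysis data frame and
#'   returning a logical vector of membership.
#' @param extra_covariates Character vector of additional covariate columns
#'   for this stratum.
#' @return A `stratum_spec`.
#' @export
stratum_spec <- function(name, predicate, extra_covariates = character(0)) {
  stopifnot(is.character(name), length(name) == 1L, is.function(predicate))
  structure(list(name = name, predicate = predicate,
                 extra_covariates = extra_covariates),
            class = "stratum_spec")
}

#' The six standard exposure strata
#'
#' Smokers / non-smokers / drinkers / non-drinkers / both / neither, with
#' ever-exposure defined as frequency > 0. Smoking strata additionally
#' adjust for the drinking frequency and drinking strata for the smoking
#' frequency.
#'
#' @param smoking_col,drinking_col Exposure frequency column names.
#' @return List of six [stratum_spec()]s.
#' @export
default_strata <- function(smoking_col = "smoking",
                           drinking_col = "drinking") {
  list(
    stratum_spec("smokers", function(d) d[[smoking_col]] > 0, drinking_col),
    stratum_spec("non_smokers", function(d) d[[smoking_col]] == 0,
                 drinking_col),
    stratum_spec("drinkers", function(d) d[[drinking_col]] > 0, smoking_col),
    stratum_spec("non_drinkers", function(d) d[[drinking_col]] == 0,
                 smoking_col),
    stratum_spec("both", function(d) d[[smoking_col]] > 0 &
                   d[[drinking_col]] > 0),
    stratum_spec("neither", function(d) d[[smoking_col]] == 0 &
                   d[[drinking_col]] == 0)
  )
}

#' Standardized linear regression of an outcome on a score
#'
#' Z-scores the score and the outcome within the analyzed sample, regresses
#' the standardized outcome on the standardized score plus covariates (an
#' intercept is always included), and returns the score coefficient with a
#' two-sided t-test P-value. Constant covariate columns are dropped with a
#' message; a zero-variance score yields a flagged undefined result.
#'
#' @param score,outcome Numeric vectors.
#' @param covariates Optional data frame of numeric covariates, row-aligned.
#' @param label Context label used in error messages (e.g. a stratum name).
#' @return List `beta`, `se`, `p`, `n`, `note`.
#' @export
standardized_regression <- function(score, outcome, covariates = NULL,
                                    label = "analysis") {
  stopifnot(length(score) == length(outcome))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(score))
  }
  ok <- !is.na(score) & !is.na(outcome)
  if (!is.null(covariates) && ncol(covariates)) {
    ok <- ok & stats::complete.cases(covariates)
  }
  n <- sum(ok)
  n_cov <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n < n_cov + 3L) {
    stop(sprintf("standardized_regression: too few complete samples in %s (n=%d)",
                 label, n), call. = FALSE)
  }
  s <- score[ok]
  y <- outcome[ok]
  if (stats::sd(s) == 0 || stats::sd(y) == 0) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n,
                note = "zero_variance"))
  }
  s <- (s - mean(s)) / stats::sd(s)
  y <- (y - mean(y)) / stats::sd(y)
  X <- cbind(`(Intercept)` = 1, score = s)
  if (!is.null(covariates) && ncol(covariates)) {
    cm <- as.matrix(covariates[ok, , drop = FALSE])
    const <- apply(cm, 2L, function(v) stats::sd(v) == 0)
    if (any(const)) {
      message("dropping constant covariate(s) in ", label, ": ",
              paste(colnames(cm)[const], collapse = ", "))
      cm <- cm[, !const, drop = FALSE]
    }
    if (ncol(cm)) X <- cbind(X, cm)
  }
  fit <- ols_fit(X, y)
  list(beta = unname(fit$coef["score"]), se = unname(fit$se["score"]),
       p = unname(fit$p["score"]), n = n, note = "")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values with enforced monotonicity, capped at 1;
#' `FDR < 0.05` is the conventional significance rule.
#'
#' @param p_values Numeric vector of P-values in (0, 1].
#' @return Adjusted FDR values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("bh_fdr: p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Stratified association battery with per-stratum FDR
#'
#' Tests every score x trait combination within every stratum via
#' [standardized_regression()], then adjusts P-values by Benjamini-Hochberg
#' within each stratum (the FDR family is all score x trait tests of that
#' stratum). Results are sorted by (stratum, trait, score).
#'
#' @param scores A `score_table` (or data frame with `sample_id` and score
#'   columns).
#' @param data Study table with `sample_id`, the trait columns, the exposure
#'   columns the strata reference, and the covariates.
#' @param traits Character vector of trait column names in `data`.
#' @param strata List of [stratum_spec()]s.
#' @param covariates Character vector of covariate column names applied in
#'   every stratum (stratum `extra_covariates` are appended).
#' @param score_cols Score columns to test (default: all non-key columns of
#'   `scores`).
#' @return Data frame with `score_name`, `trait_name`, `stratum`, `beta`,
#'   `se`, `p`, `fdr`, `n`.
#' @export
run_association_battery <- function(scores, data, traits, strata,
                                    covariates = character(0),
                                    score_cols = NULL) {
  if (is.null(score_cols)) {
    score_cols <- setdiff(names(scores), "sample_id")
  }
  merged <- merge(as.data.frame(scores), data, by = "sample_id",
                  sort = TRUE)
  rows <- list()
  for (st in strata) {
    member <- st$predicate(merged)
    member[is.na(member)] <- FALSE
    sub <- merged[member, , drop = FALSE]
    covs <- unique(c(covariates, st$extra_covariates))
    covs <- intersect(covs, names(sub))
    st_rows <- list()
    for (tr in traits) {
      for (sc in score_cols) {
        # a stratum too small to fit (e.g. near-empty exposure group) is
        # reported as an undefined row rather than aborting the battery
        res <- tryCatch(
          standardized_regression(
            sub[[sc]], sub[[tr]],
            if (length(covs)) sub[covs] else NULL,
            label = paste0(st$name, "/", tr, "/", sc)),
          error = function(e) list(beta = NA_real_, se = NA_real_,
                                   p = NA_real_, n = nrow(sub),
                                   note = conditionMessage(e)))
        st_rows[[paste(tr, sc)]] <- data.frame(
          score_name = sc, trait_name = tr, stratum = st$name,
          beta = res$beta, se = res$se, p = res$p, fdr = NA_real_,
          n = res$n, stringsAsFactors = FALSE)
      }
    }
    st_df <- do.call(rbind, st_rows)
    def <- !is.na(st_df$p)
    # degenerate perfect fits can yield p = 0 exactly; clamp to the smallest
    # positive double so the BH family stays in (0, 1]
    if (any(def)) {
      st_df$fdr[def] <- bh_fdr(pmax(st_df$p[def], .Machine$double.xmin))
    }
    rows[[st$name]] <- st_df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$stratum, out$trait_name, out$score_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
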