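# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_config(field, "must be a single non-missing number")
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_config(field, sprintf("must be in %s%s, %s%s (got %g)",
                               if (lower_open) "(" else "[", format(lower),
                               format(upper), if (upper_open) ")" else "]", x))
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_config(field, sprintf("must be an integer >= %d", min))
  as.integer(x)
}

# Round-trip-safe decimal rendering: %.17g reproduces any double exactly.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

# OLS by QR with coefficient standard errors and two-sided t-test P-values.
# Aliased (rank-deficient) columns get NA estimates.
ols_fit <- function(X, y) {
  stopifnot(nrow(X) == length(y))
  fit <- stats::lm.fit(X, y)
  p <- ncol(X)
  n <- nrow(X)
  rk <- fit$rank
  df <- n - rk
  coef <- fit$coefficients
  se <- rep(NA_real_, p)
  if (df > 0 && rk > 0) {
    sigma2 <- sum(fit$residuals^2) / df
    R <- qr.R(fit$qr)[seq_len(rk), seq_len(rk), drop = FALSE]
    xtx_inv <- chol2inv(R)
    piv <- fit$qr$pivot[seq_len(rk)]
    se[piv] <- sqrt(pmax(diag(xtx_inv), 0) * sigma2)
  }
  tval <- coef / se
  pval <- 2 * stats::pt(-abs(tval), df)
  names(coef) <- names(se) <- names(pval) <- colnames(X)
  list(coef = coef, se = se, p = pval, df = df, rank = rk,
       residuals = fit$residuals)
}

# Fast coefficient-only OLS (bootstrap inner loops).
ols_coef <- function(X, y) {
  stats::.lm.fit(X, y)$coefficients
}

# Mean-impute missing dosages column-wise; columns that are all-missing
# become their expected value 0 contribution (kept as 0).
impute_dosage <- function(dosage) {
  if (!anyNA(dosage)) return(dosage)
  mu <- colMeans(dosage, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(dosage), arr.ind = TRUE)
  dosage[idx] <- mu[idx[, 2L]]
  dosage
}
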