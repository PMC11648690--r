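#' K-fold cross-validation of a linear model
#'
#' Shuffles complete cases under `seed`, splits them into `k` folds whose
#' sizes differ by at most one, and for each fold fits OLS of the outcome on
#' the predictors (plus intercept) on the remaining folds and evaluates on
#' the held-out fold. Reported metrics per fold and as a simple mean:
#' \eqn{\mathrm{RMSE} = \sqrt{\mathrm{mean}(e^2)}},
#' \eqn{\mathrm{MAE} = \mathrm{mean}(|e|)}, and
#' \eqn{R^2 = 1 - \mathrm{SSE}/\mathrm{SST}} with SST taken about the
#' held-out fold's own mean.
#'
#' @param data Data frame holding predictors and outcome.
#' @param predictors Character vector of predictor column names.
#' @param outcome Outcome column name.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the fold shuffle.
#' @return A `cv_report`: list with `k`, `seed`, `folds` (per-fold data
#'   frame: `fold`, `n_test`, `rmse`, `mae`, `r2`), and `mean` (named
#'   vector of mean metrics).
#' @export
kfold_cv <- function(data, predictors, outcome, k = 5, seed = 1) {
  k <- check_count(k, "k", min = 2L)
  stopifnot(all(c(predictors, outcome) %in% names(data)))
  d <- data[stats::complete.cases(data[c(predictors, outcome)]),
            c(predictors, outcome), drop = FALSE]
  n <- nrow(d)
  if (k > n) {
    stop_config("k", sprintf("exceeds the number of complete cases (%d)", n))
  }
  set.seed(seed)
  ord <- sample.int(n)
  fold_id <- integer(n)
  fold_id[ord] <- rep(seq_len(k), length.out = n)
  X <- cbind(`(Intercept)` = 1, as.matrix(d[predictors]))
  y <- d[[outcome]]
  per_fold <- lapply(seq_len(k), function(f) {
    test <- fold_id == f
    beta <- ols_coef(X[!test, , drop = FALSE], y[!test])
    beta[is.na(beta)] <- 0
    pred <- drop(X[test, , drop = FALSE] %*% beta)
    err <- y[test] - pred
    sst <- sum((y[test] - mean(y[test]))^2)
    data.frame(fold = f, n_test = sum(test),
               rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
               r2 = 1 - sum(err^2) / sst)
  })
  folds <- do.call(rbind, per_fold)
  stopifnot(sum(folds$n_test) == n,
            max(folds$n_test) - min(folds$n_test) <= 1L)
  structure(list(k = k, seed = seed, folds = folds,
                 mean = c(rmse = mean(folds$rmse), mae = mean(folds$mae),
                          r2 = mean(folds$r2))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d): mean RMSE %.4g, MAE %.4g, R2 %.4g\n",
              x$k, x$seed, x$mean["rmse"], x$mean["mae"], x$mean["r2"]))
  invisible(x)
}
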