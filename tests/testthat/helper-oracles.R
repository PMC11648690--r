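# Independent oracles used to cross-check the implementation. Each is a
# deliberately naive, separately derived computation.

# HWE exact test by direct multinomial enumeration with choose() (the
# package uses a log-gamma formulation).
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nA <- 2 * n_hom_ref + n_het
  nB <- 2 * n_hom_alt + n_het
  rare <- min(nA, nB)
  if (rare == 0) return(1)
  h <- seq(rare %% 2, rare, by = 2)
  ways <- vapply(h, function(k) {
    choose(n, (nA - k) / 2) * choose(n - (nA - k) / 2, k) * 2^k
  }, numeric(1))
  pr <- ways / sum(ways)
  min(1, sum(pr[pr <= pr[h == n_het] * (1 + 1e-12)]))
}

# Closed-form normal-equations OLS: beta, se, p.
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  p <- 2 * pt(-abs(beta / se), df)
  list(beta = beta, se = se, p = p)
}

# Brute-force greedy clumping on plain vectors, recomputing r^2 with cor()
# and rescanning the candidate list from scratch at every step.
clump_oracle <- function(snp_id, chrom, pos, p, dosage, p_threshold,
                        window_bp, r2_threshold) {
  keep <- p < p_threshold
  snp_id <- snp_id[keep]; chrom <- chrom[keep]; pos <- pos[keep]
  p <- p[keep]
  dosage <- dosage[, keep, drop = FALSE]
  dosage <- apply(dosage, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  })
  chosen <- character(0)
  remaining <- seq_along(snp_id)
  while (length(remaining)) {
    ord <- order(p[remaining], chrom[remaining], pos[remaining],
                 snp_id[remaining])
    i <- remaining[ord[1L]]
    chosen <- c(chosen, snp_id[i])
    drop_set <- i
    for (j in setdiff(remaining, i)) {
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window_bp) {
        r <- if (sd(dosage[, i]) == 0 || sd(dosage[, j]) == 0) 0 else
          cor(dosage[, i], dosage[, j])
        if (r^2 >= r2_threshold) drop_set <- c(drop_set, j)
      }
    }
    remaining <- setdiff(remaining, drop_set)
  }
  sort(chosen)
}

# Naive per-sample, per-SNP double-loop scores.
prs_oracle <- function(dosage, weights) {
  dosage <- apply(dosage, 2, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  })
  out <- numeric(nrow(dosage))
  for (i in seq_len(nrow(dosage))) {
    for (j in seq_len(ncol(dosage))) {
      out[i] <- out[i] + weights[j] * dosage[i, j]
    }
  }
  out
}

girs_oracle <- function(dosage, weights, exposure) {
  prs_oracle(dosage, weights) * exposure
}
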