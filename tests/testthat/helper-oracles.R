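# Independent oracles, written as naive loops before (and independently of)
# the package implementations they check.

# brute-force KNN imputation: standardize each feature on observed values,
# exhaustive pairwise RMS distance over co-observed samples, average the k
# nearest features observed at the target sample, back-transform; median
# fallback when no qualifying neighbour.
oracle_knn_impute <- function(a, k) {
  n <- nrow(a); p <- ncol(a)
  mu <- numeric(p); sg <- numeric(p)
  z <- a
  for (j in seq_len(p)) {
    obs <- a[!is.na(a[, j]), j]
    mu[j] <- mean(obs)
    sg[j] <- stats::sd(obs)
    if (is.na(sg[j]) || sg[j] == 0) sg[j] <- 1
    z[, j] <- (a[, j] - mu[j]) / sg[j]
  }
  d <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) for (l in seq_len(p)) {
    if (j == l) next
    both <- which(!is.na(a[, j]) & !is.na(a[, l]))
    if (length(both)) d[j, l] <- sqrt(mean((z[both, j] - z[both, l])^2))
  }
  out <- a
  for (j in seq_len(p)) {
    if (all(is.na(a[, j]))) next
    med_j <- stats::median(a[!is.na(a[, j]), j])
    for (i in seq_len(n)) {
      if (!is.na(a[i, j])) next
      ord <- order(d[, j], na.last = NA)
      neigh <- ord[!is.na(a[i, ord])]
      neigh <- neigh[seq_len(min(k, length(neigh)))]
      out[i, j] <- if (length(neigh)) mu[j] + mean(z[i, neigh]) * sg[j] else med_j
    }
  }
  out
}

# closed-form OLS via normal equations: per-SD metabolite estimate and SE
oracle_ols <- function(y, metab, covars = NULL) {
  z <- (metab - mean(metab)) / stats::sd(metab)
  X <- cbind(1, z)
  if (!is.null(covars)) X <- cbind(X, as.matrix(covars))
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / (length(y) - ncol(X))
  se <- sqrt(diag(XtX_inv) * s2)
  list(estimate = unname(beta[2, 1]), se = unname(se[2]))
}

# step-up BH by hand
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  agree <- sum_comb(tab) # pairs together in both
  a_pairs <- sum_comb(rowSums(tab)); b_pairs <- sum_comb(colSums(tab))
  total <- choose(n, 2)
  (total + 2 * agree - a_pairs - b_pairs) / total
}
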