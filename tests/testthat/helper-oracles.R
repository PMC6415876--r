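# Independent brute-force oracles. Deliberately written with explicit loops
# and naive enumeration, sharing no code with the package implementation.

# Passing-Bablok slope/intercept by exhaustive enumeration of pairwise slopes.
oracle_pb <- function(x, y) {
  slopes <- c()
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (x[j] != x[i]) {
        s <- (y[j] - y[i]) / (x[j] - x[i])
        if (s != -1) slopes <- c(slopes, s)
      }
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- 0
  for (s in slopes) if (s < -1) K <- K + 1
  if (N %% 2 == 1) {
    b <- slopes[(N + 1) / 2 + K]
  } else {
    b <- (slopes[N / 2 + K] + slopes[N / 2 + 1 + K]) / 2
  }
  resid <- numeric(n)
  for (i in seq_len(n)) resid[i] <- y[i] - b * x[i]
  list(slope = b, intercept = median(resid), n_slopes = N, K = K)
}

# AUC by counting concordant (positive, negative) pairs, ties worth 1/2.
oracle_auc <- function(pred, truth) {
  pos <- pred[truth]
  neg <- pred[!truth]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) total <- total + 1
      else if (p == q) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# OLS via the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

# Clopper-Pearson bounds by direct numeric inversion of the binomial tails.
oracle_cp <- function(k, n, conf = 0.95) {
  a <- 1 - conf
  lower <- if (k == 0) 0 else
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - a / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}
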