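# Independent oracles used to validate the package implementations.
# These deliberately use the most naive correct formulation available.

# AUC by exhaustive positive-negative pair counting (ties count 1/2)
bruteForceAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the textbook step-up definition
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}

# Efron-approximation Cox partial log-likelihood, written directly from
# the definition (no reuse of the survival package machinery)
efronLogLik <- function(beta, X, time, status) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    sumR <- sum(w[R]); sumD <- sum(w[D])
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sumR - (l / d) * sumD)
  }
  ll
}

# brute-force Newton-style optimisation of the Efron partial likelihood
coxOracleFit <- function(X, time, status) {
  X <- as.matrix(X)
  optim(rep(0, ncol(X)),
        function(b) -efronLogLik(b, X, time, status),
        method = "BFGS", control = list(maxit = 500, reltol = 1e-14))$par
}

# per-marker linear-model effects through the normal equations
lmOracle <- function(Y, design) {
  XtXinv <- solve(crossprod(design))
  out <- apply(as.matrix(Y), 2, function(y) {
    b <- XtXinv %*% crossprod(design, y)
    res <- y - design %*% b
    s2 <- sum(res^2) / (length(y) - ncol(design))
    se <- sqrt(s2 * diag(XtXinv))
    c(beta = unname(b[2]), se = unname(se[2]))
  })
  t(out)
}

# algebraic reconstruction of a deleted cell of an exact rank-1 matrix
rank1CellOracle <- function(m, i, j, i2, j2) {
  m[i, j2] * m[i2, j] / m[i2, j2]
}

# all permutations of a small vector (used for exhaustive BH checks)
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPerms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
  out
}
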