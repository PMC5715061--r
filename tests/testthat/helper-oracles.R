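# Independent reference implementations used as oracles. These deliberately
# avoid the package's code paths (and where possible its numerical routines)
# so that agreement is evidence, not tautology.

# OLS via explicit normal equations.
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  as.vector(solve(t(Xi) %*% Xi, t(Xi) %*% y))[-1]
}

# Spearman rho via the classical rank-difference formula (tie-free data).
oracle_spearman <- function(a, b) {
  d <- rank(a) - rank(b)
  n <- length(a)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Step-by-step match-vs-mismatch RSA: demean, leave-one-block-per-condition
# folds, rank-formula Spearman, clipped atanh, plain means.
oracle_rsa <- function(patterns, labels, clip = 1 - 1e-7) {
  patterns <- patterns - rowMeans(patterns)
  conds <- sort(unique(labels))
  n_per <- min(table(labels))
  match_z <- numeric(0)
  mismatch_z <- numeric(0)
  for (f in seq_len(n_per)) {
    held <- vapply(conds, function(cc) which(labels == cc)[f], integer(1))
    for (k in held) {
      zs <- vapply(conds, function(cc) {
        keep <- setdiff(which(labels == cc), held)
        proto <- colMeans(patterns[keep, , drop = FALSE])
        rho <- oracle_spearman(patterns[k, ], proto)
        atanh(max(min(rho, clip), -clip))
      }, numeric(1))
      match_z <- c(match_z, zs[conds == labels[k]])
      mismatch_z <- c(mismatch_z, mean(zs[conds != labels[k]]))
    }
  }
  mean(match_z) - mean(mismatch_z)
}

# BGC by direct elementwise summation.
oracle_bgc <- function(W, labels) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0; cnt <- 0
    for (j in seq_len(n)) {
      if (labels[j] != labels[i]) { acc <- acc + W[i, j]; cnt <- cnt + 1 }
    }
    out[i] <- acc / cnt
  }
  out
}

# Intercept-free logistic regression by direct likelihood maximization,
# with leave-one-out predictions.
oracle_logistic_loo <- function(X, y) {
  nll <- function(beta, X, y) {
    eta <- as.vector(X %*% beta)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  K <- nrow(X)
  pred <- integer(K)
  for (k in seq_len(K)) {
    fit <- optim(rep(0, ncol(X)), nll, X = X[-k, , drop = FALSE], y = y[-k],
                 method = "BFGS")
    pred[k] <- as.integer(1 / (1 + exp(-sum(X[k, ] * fit$par))) > 0.5)
  }
  list(predicted = pred, accuracy = mean(pred == y))
}

# Small synthetic activation set: condition templates plus noise.
make_patterns <- function(n_cond = 4, blocks_per_cond = 4, n_feat = 20,
                          snr = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  templates <- matrix(rnorm(n_cond * n_feat, sd = snr), n_cond, n_feat)
  labels <- rep(seq_len(n_cond), each = blocks_per_cond)
  patterns <- templates[labels, ] + matrix(rnorm(length(labels) * n_feat),
                                           length(labels), n_feat)
  list(patterns = patterns, labels = labels, templates = templates)
}
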