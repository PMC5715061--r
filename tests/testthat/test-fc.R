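test_that("multiple-regression FC recovers a planted linear relation", {
  set.seed(42)
  n <- 5; T <- 600
  X <- matrix(rnorm(n * T), nrow = n)
  X[3, ] <- 0.5 * X[1, ] - 0.25 * X[2, ] + rnorm(T, sd = 0.05)
  fc <- multreg_fc(timeseries_matrix(X, 1, "bold"))
  expect_equal(fc$coefficients[1, 3], 0.5, tolerance = 0.02)
  expect_equal(fc$coefficients[2, 3], -0.25, tolerance = 0.02)
  expect_true(all(diag(fc$coefficients) == 0))
})

test_that("multiple-regression FC equals the normal-equations oracle", {
  set.seed(7)
  n <- 12; T <- 150
  X <- matrix(rnorm(n * T), nrow = n)
  fc <- multreg_fc(timeseries_matrix(X, 1, "bold"))
  Xt <- t(X)
  for (i in c(1, 5, 12)) {
    b <- oracle_ols(Xt[, -i, drop = FALSE], Xt[, i])
    expect_lt(max(abs(fc$coefficients[-i, i] - b)), 1e-8)
  }
})

test_that("independent white-noise nodes give near-zero coefficients", {
  set.seed(13)
  X <- matrix(rnorm(5 * 600), nrow = 5)
  fc <- multreg_fc(timeseries_matrix(X, 1, "bold"))
  # OLS standard error of each coefficient under independence ~ 1/sqrt(T)
  se <- 1 / sqrt(600)
  off <- fc$coefficients[row(fc$coefficients) != col(fc$coefficients)]
  expect_true(all(abs(off) < 4 * se))
})

test_that("multreg FC is scale-covariant and leaves orthogonal residuals", {
  set.seed(19)
  n <- 8; T <- 200
  X <- matrix(rnorm(n * T), nrow = n)
  X[2, ] <- X[2, ] + 0.5 * X[1, ]
  fc1 <- multreg_fc(timeseries_matrix(X, 1, "bold"))
  Xs <- X; Xs[1, ] <- 3 * Xs[1, ]
  fc2 <- multreg_fc(timeseries_matrix(Xs, 1, "bold"))
  # scaling a source by c divides its outgoing coefficients by c
  expect_equal(fc2$coefficients[1, -1], fc1$coefficients[1, -1] / 3,
               tolerance = 1e-10)
  # residuals orthogonal to regressors for a representative target
  i <- 2
  Xc <- t(scale(t(X), scale = FALSE))
  resid <- Xc[i, ] - as.vector(fc1$coefficients[-i, i] %*% Xc[-i, ])
  expect_lt(max(abs(Xc[-i, ] %*% resid)) / T, 1e-10)
})

test_that("multreg FC signals degenerate inputs", {
  X <- matrix(rnorm(5 * 4), nrow = 5)
  expect_error(multreg_fc(timeseries_matrix(X, 1, "bold")),
               "under-determined")
  Y <- matrix(rnorm(3 * 50), nrow = 3)
  Y[2, ] <- 1
  Y[2, 1] <- 1  # constant node
  expect_error(multreg_fc(timeseries_matrix(Y, 1, "bold")), "constant")
  Z <- matrix(rnorm(4 * 50), nrow = 4)
  Z[4, ] <- Z[1, ] + Z[2, ]  # exact collinearity
  expect_error(multreg_fc(timeseries_matrix(Z, 1, "bold")),
               "rank-deficient")
})

test_that("principal-components regression reduces to OLS at full rank", {
  set.seed(23)
  S <- matrix(rnorm(10 * 200), nrow = 10)
  y <- as.vector(0.8 * S[3, ] - 0.3 * S[7, ] + rnorm(200, sd = 0.1))
  beta_pc <- pcreg_fc(S, y, n_components = 10)
  beta_ols <- oracle_ols(t(S), y)
  expect_lt(max(abs(beta_pc - beta_ols)), 1e-6)
})

test_that("pcreg handles masks, nulls, and rank limits", {
  set.seed(29)
  S <- matrix(rnorm(8 * 100), nrow = 8)
  y <- rnorm(100)
  mask <- rep(FALSE, 8); mask[c(2, 5)] <- TRUE
  beta <- pcreg_fc(S, y, n_components = 4, mask = mask)
  expect_identical(beta[c(2, 5)], c(0, 0))
  # independent target: coefficients small
  beta0 <- pcreg_fc(S, y, n_components = 8)
  expect_true(all(abs(beta0) < 4 / sqrt(100)))
  # rank overflow is an error naming the attained rank
  expect_error(pcreg_fc(S, y, n_components = 9), "rank")
})

test_that("BGC equals direct summation on a printed 6-node toy", {
  W <- matrix(c(0, 2, 1, 0, 1, 3,
                1, 0, 2, 1, 0, 1,
                2, 1, 0, 3, 1, 0,
                0, 1, 1, 0, 2, 1,
                1, 0, 2, 1, 0, 2,
                1, 1, 0, 2, 1, 0), 6, 6, byrow = TRUE)
  labels <- c("a", "a", "a", "b", "b", "b")
  res <- bgc(fc_matrix(W, method = "multreg"), network_partition(labels))
  expect_identical(res$node$bgc, oracle_bgc(W, labels))
  expect_identical(res$network$bgc,
                   c(mean(oracle_bgc(W, labels)[1:3]),
                     mean(oracle_bgc(W, labels)[4:6])))
})

test_that("BGC of a constant off-diagonal matrix is constant", {
  W <- matrix(1, 8, 8); diag(W) <- 0
  res <- bgc(fc_matrix(W), network_partition(rep(1:2, each = 4)))
  expect_true(all(res$node$bgc == 1))
})

test_that("BGC under permuted equal-size labels keeps its expected grand mean", {
  set.seed(31)
  W <- matrix(rnorm(100), 10, 10); diag(W) <- 0
  labels <- rep(1:2, each = 5)
  base <- bgc(fc_matrix(W), network_partition(labels))$node$bgc
  gms <- replicate(300, {
    mean(bgc(fc_matrix(W), network_partition(sample(labels)))$node$bgc)
  })
  # per-node values move with the labels, but the grand mean stays centered
  # on the mean off-diagonal coefficient
  expect_gt(sd(replicate(20, bgc(fc_matrix(W),
    network_partition(sample(labels)))$node$bgc[1])), 0)
  target <- mean(W[row(W) != col(W)])
  expect_lt(abs(mean(gms) - target), 3 * sd(gms) / sqrt(length(gms)) + 1e-3)
})

test_that("BGC rejects single-network partitions and coverage gaps", {
  W <- matrix(0, 4, 4)
  expect_error(bgc(fc_matrix(W), network_partition(rep(1, 4))),
               "single-network")
  expect_error(bgc(fc_matrix(W), network_partition(rep(1:2, 4))),
               "covers 8 nodes")
})

test_that("FC container enforces its invariants", {
  expect_error(fc_matrix(matrix(1, 3, 3)), "diagonal")
  M <- matrix(0, 3, 3); M[1, 2] <- Inf
  expect_error(fc_matrix(M), "finite")
  expect_error(fc_matrix(matrix(0, 2, 3)), "square")
})
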