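#' One-sample group t-tests across subjects
#'
#' One-sample t-test of each column (comparison) against zero across rows
#' (subjects). The default alternative is `greater`, matching the use of
#' positive information estimates as evidence of task representation.
#'
#' @param values subject-by-comparison numeric matrix (or vector for a
#'   single comparison).
#' @param alternative `"greater"` (default), `"less"`, or `"two.sided"`.
#' @return a data frame of class `group_result`: `mean`, `t`, `df`, `p`.
#'   Zero-variance comparisons get `NA` statistics with a warning.
#' @export
group_ttest <- function(values, alternative = c("greater", "less",
                                                "two.sided")) {
  alternative <- match.arg(alternative)
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 2) stop("at least two subjects are required")
  m <- colMeans(values)
  s <- apply(values, 2, sd)
  degen <- s == 0
  if (any(degen))
    warning(sprintf("%d zero-variance comparison(s); statistics set to NA",
                    sum(degen)))
  tstat <- ifelse(degen, NA_real_, m / (s / sqrt(n)))
  df <- n - 1
  p <- switch(alternative,
              greater = pt(tstat, df, lower.tail = FALSE),
              less = pt(tstat, df),
              two.sided = 2 * pt(abs(tstat), df, lower.tail = FALSE))
  out <- data.frame(mean = m, t = tstat, df = df, p = p)
  class(out) <- c("group_result", "data.frame")
  out
}

#' Max-statistic permutation FWE correction
#'
#' Family-wise error corrected p-values for a family of one-sample
#' comparisons, via the permutation distribution of the maximum
#' t-statistic: each permutation flips the sign of every subject's entire
#' row of values (valid under the symmetric null), recomputes all column
#' t-statistics and records the maximum; the corrected p of a comparison is
#' `(1 + #{max-null >= t_obs}) / (n_perm + 1)`. The smallest attainable
#' corrected p is therefore `1/(n_perm + 1)`.
#'
#' @param values subject-by-comparison matrix.
#' @param n_perm number of sign-flip permutations (>= 100).
#' @return a data frame of class `group_result`: `mean`, `t`, `df`, `p`
#'   (uncorrected one-sided permutation p from each comparison's own
#'   sign-flip null), `p_fwe`.
#' @export
fwe_maxstat <- function(values, n_perm = 1000) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  values <- as.matrix(values)
  n <- nrow(values)
  res <- group_ttest(values, alternative = "greater")
  # Under row sign flips the column sums of squares are unchanged, so the
  # permuted t only needs the permuted means.
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  pm <- (signs %*% values) / n
  ss <- matrix(colSums(values^2), n_perm, ncol(values), byrow = TRUE)
  pvar <- (ss - n * pm^2) / (n - 1)
  pt_mat <- pm / sqrt(pvar / n)
  max_null <- apply(pt_mat, 1, max, na.rm = TRUE)
  # uncorrected p from each comparison's own sign-flip null, so the
  # corrected value can never undercut it (max >= own column t)
  res$p <- vapply(seq_along(res$t), function(j) {
    if (is.na(res$t[j])) return(NA_real_)
    (1 + sum(pt_mat[, j] >= res$t[j])) / (n_perm + 1)
  }, numeric(1))
  res$p_fwe <- vapply(res$t, function(t0) {
    if (is.na(t0)) return(NA_real_)
    (1 + sum(max_null >= t0)) / (n_perm + 1)
  }, numeric(1))
  res
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values; a thin wrapper over [stats::p.adjust()] kept
#' for a uniform correction interface.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values, never below the input.
#' @export
fdr_correct <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Decode task performance from information estimates
#'
#' Within-subject behavioral decoding: a miniblock is labeled 1 when more
#' than half of its trials were performed correctly and 0 otherwise, and an
#' intercept-free logistic regression predicts that label from the block's
#' information (or transfer) estimates — one predictor per rule domain.
#' Removing the intercept centers the predicted probability at 0.5, which
#' compensates for imbalanced class frequencies. Accuracy is estimated by
#' leave-one-block-out cross-validation with predicted class
#' `probability > 0.5`.
#'
#' @param block_estimates miniblock-by-predictor matrix (e.g. the three
#'   rule-domain estimates per block).
#' @param block_accuracy fraction of correct trials per miniblock, in
#'   `[0, 1]` (or an already-binarized 0/1 outcome).
#' @return list of class `decode_result`: `accuracy` (cross-validated
#'   fraction of correctly predicted blocks), `predicted`, `outcome`,
#'   `n_blocks`.
#' @export
decode_performance <- function(block_estimates, block_accuracy) {
  X <- as.matrix(block_estimates)
  y <- as.integer(block_accuracy > 0.5)
  if (length(y) != nrow(X)) stop("one accuracy value per miniblock is required")
  if (length(unique(y)) < 2)
    stop("single-class outcomes: task performance is undecodable")
  tab <- table(y)
  if (max(tab) / min(tab) > 4)
    warning(sprintf("class imbalance %d:%d exceeds 4:1; interpret cautiously",
                    max(tab), min(tab)))
  K <- nrow(X)
  pred <- integer(K)
  for (k in seq_len(K)) {
    fit <- suppressWarnings(
      glm.fit(X[-k, , drop = FALSE], y[-k], family = binomial(),
              intercept = FALSE))
    pred[k] <- as.integer(plogis(sum(X[k, ] * coef(fit))) > 0.5)
  }
  structure(list(accuracy = mean(pred == y), predicted = pred, outcome = y,
                 n_blocks = K), class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat(sprintf("Behavioral decoding: %.1f%% cross-validated accuracy over %d miniblocks\n",
              100 * x$accuracy, x$n_blocks))
  invisible(x)
}
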