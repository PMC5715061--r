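#' Leave-one-block-per-condition cross-validation folds
#'
#' Builds the fold structure used by the information estimate: each fold
#' holds out exactly one miniblock of every condition, so condition
#' prototypes are always averages over the same number of blocks. With
#' unequal condition counts, smaller conditions' blocks are cycled so every
#' block is held out at least once.
#'
#' @param labels condition label per miniblock.
#' @return list of integer vectors (block indices), one per fold.
#' @export
cv_folds <- function(labels) {
  conds <- sort(unique(labels))
  by_cond <- lapply(conds, function(cc) which(labels == cc))
  n_folds <- max(lengths(by_cond))
  lapply(seq_len(n_folds), function(f) {
    vapply(by_cond, function(idx) idx[(f - 1L) %% length(idx) + 1L],
           integer(1))
  })
}

#' Condition prototypes with held-out blocks
#'
#' The prototype of a condition is the mean activation pattern over that
#' condition's miniblocks, excluding any held-out blocks.
#'
#' @param patterns an `activation_set` or miniblock-by-node matrix.
#' @param labels condition label per miniblock (taken from the
#'   `activation_set` when omitted).
#' @param holdout_blocks integer indices of blocks excluded from every
#'   prototype.
#' @return node-by-condition matrix of prototype patterns.
#' @export
condition_prototypes <- function(patterns, labels = NULL,
                                 holdout_blocks = integer(0)) {
  pb <- pattern_block(patterns, labels)
  conds <- sort(unique(pb$labels))
  protos <- vapply(conds, function(cc) {
    keep <- setdiff(which(pb$labels == cc), holdout_blocks)
    if (length(keep) == 0)
      stop(sprintf("condition '%s' has no blocks left after holdout", cc))
    colMeans(pb$patterns[keep, , drop = FALSE])
  }, numeric(ncol(pb$patterns)))
  colnames(protos) <- as.character(conds)
  protos
}

#' Cross-validated match-versus-mismatch information estimate
#'
#' Quantifies how much task information an activation pattern set carries.
#' All miniblock patterns are first spatially demeaned (mean over nodes
#' removed), so the score reflects the multivariate pattern rather than a
#' region-level mean shift. Then, per held-out miniblock k, the Fisher
#' z-transformed Spearman correlation with the prototype of k's own
#' condition (the match) is compared with the mean of the Fisher-z Spearman
#' correlations with the other conditions' prototypes (the mismatches);
#' prototypes are built from the remaining blocks under the
#' leave-one-block-per-condition scheme of [cv_folds()]. The estimate is
#'
#' `IE = mean_k match_k - mean_k mismatch_k`
#'
#' and is positive when patterns are reliably more similar to their own
#' condition's prototype than to other conditions'.
#'
#' Blocks whose pattern has zero variance after demeaning (rank correlation
#' undefined) are excluded from both means, with a warning.
#'
#' @param patterns an `activation_set` or miniblock-by-node matrix.
#' @param labels condition label per miniblock; defaults to the
#'   `activation_set`'s `condition` column.
#' @param rule_domain when `patterns` carries several label columns (one
#'   per rule domain), the column to use.
#' @return an object of class `information_estimate`: `value`,
#'   `match_mean`, `mismatch_mean`, `per_block` (match - mismatch per
#'   block, for behavioral decoding), `n_blocks`, `n_conditions`,
#'   `n_degenerate`.
#' @export
information_estimate <- function(patterns, labels = NULL, rule_domain = NULL) {
  pb <- pattern_block(patterns, labels, rule_domain)
  rsa_match_mismatch(pb$patterns, pb$patterns, pb$labels)
}

# Core match-vs-mismatch RSA shared by the information estimate (eval ==
# actual) and the transfer estimate (eval = FC-mapped predictions).
# Prototypes are always built from `actual`; `eval_patterns` supplies the
# held-out patterns being scored. Both inputs are spatially demeaned.
# Split into a prototype precompute and a scoring pass so permutation
# tests, which rescore many eval sets against fixed actual patterns, do
# not rebuild prototypes every time.
rsa_match_mismatch <- function(eval_patterns, actual_patterns, labels,
                               clip = 1 - 1e-7) {
  eval_patterns <- as.matrix(eval_patterns)
  if (nrow(eval_patterns) != NROW(actual_patterns))
    stop("eval patterns, actual patterns and labels must agree on block count")
  rsa_score(eval_patterns, rsa_precompute(actual_patterns, labels, clip))
}

rsa_precompute <- function(actual_patterns, labels, clip = 1 - 1e-7) {
  actual_patterns <- as.matrix(actual_patterns)
  if (nrow(actual_patterns) != length(labels))
    stop("eval patterns, actual patterns and labels must agree on block count")
  if (ncol(actual_patterns) < 2)
    stop("at least two features are required for a pattern correlation")
  conds <- sort(unique(labels))
  if (any(table(labels) < 2))
    stop("every condition needs at least two blocks")
  actual_patterns <- actual_patterns - rowMeans(actual_patterns)
  folds <- cv_folds(labels)
  proto_ranks <- lapply(folds, function(fold) {
    apply(vapply(conds, function(cc) {
      keep <- setdiff(which(labels == cc), fold)
      colMeans(actual_patterns[keep, , drop = FALSE])
    }, numeric(ncol(actual_patterns))), 2, rank)
  })
  list(folds = folds, proto_ranks = proto_ranks, conds = conds,
       labels = labels, clip = clip)
}

rsa_score <- function(eval_patterns, pre) {
  eval_patterns <- as.matrix(eval_patterns)
  K <- nrow(eval_patterns)
  if (K != length(pre$labels))
    stop("eval patterns, actual patterns and labels must agree on block count")
  eval_patterns <- eval_patterns - rowMeans(eval_patterns)
  match_z <- mismatch_z <- rep(NA_real_, K)
  for (f in seq_along(pre$folds)) {
    pr <- pre$proto_ranks[[f]]
    for (k in pre$folds[[f]]) {
      z <- fisher_z_spearman(eval_patterns[k, ], pr, pre$clip)
      is_match <- pre$conds == pre$labels[k]
      match_z[k] <- z[is_match]
      mismatch_z[k] <- mean(z[!is_match])
    }
  }
  valid <- is.finite(match_z) & is.finite(mismatch_z)
  n_degenerate <- sum(!valid)
  if (n_degenerate > 0)
    warning(sprintf("%d block(s) with degenerate (zero-variance) patterns excluded",
                    n_degenerate))
  structure(list(value = mean(match_z[valid]) - mean(mismatch_z[valid]),
                 match_mean = mean(match_z[valid]),
                 mismatch_mean = mean(mismatch_z[valid]),
                 per_block = match_z - mismatch_z,
                 n_blocks = K, n_conditions = length(pre$conds),
                 n_degenerate = n_degenerate),
            class = "information_estimate")
}

# Fisher-z Spearman correlations of one pattern against pre-ranked
# prototype columns. |rho| is clipped below 1 so atanh stays finite on
# noiseless data. Zero-variance inputs give NA.
fisher_z_spearman <- function(x, proto_ranks, clip = 1 - 1e-7) {
  rx <- rank(x)
  if (sd(rx) == 0) return(rep(NA_real_, ncol(proto_ranks)))
  rho <- suppressWarnings(as.vector(cor(rx, proto_ranks)))
  atanh(pmin(pmax(rho, -clip), clip))
}

#' @export
print.information_estimate <- function(x, ...) {
  cat(sprintf("Information estimate: %.4f (match %.4f - mismatch %.4f; %d blocks, %d conditions)\n",
              x$value, x$match_mean, x$mismatch_mean, x$n_blocks,
              x$n_conditions))
  invisible(x)
}

# Resolve patterns + labels from an activation_set or a bare matrix.
pattern_block <- function(patterns, labels = NULL, rule_domain = NULL) {
  if (inherits(patterns, "activation_set")) {
    if (is.null(labels)) {
      col <- if (!is.null(rule_domain)) rule_domain else "condition"
      if (!col %in% names(patterns$labels))
        stop(sprintf("no label column '%s' in the activation set", col))
      labels <- patterns$labels[[col]]
    }
    patterns <- patterns$betas
  } else {
    patterns <- as.matrix(patterns)
    if (is.null(labels)) stop("labels are required for a bare pattern matrix")
  }
  if (length(labels) != nrow(patterns))
    stop("one label per miniblock is required")
  list(patterns = patterns, labels = labels)
}
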