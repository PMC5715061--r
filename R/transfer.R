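#' Activity flow mapping between regions
#'
#' Predicts a target region's activation pattern as the dot product of the
#' source region's pattern with the source-by-target block of resting-state
#' FC weights: `predicted_target = source_pattern %*% fc_block`. Several
#' patterns may be mapped at once by passing a miniblock-by-source matrix.
#'
#' @param source_pattern numeric vector (one pattern) or miniblock-by-source
#'   matrix.
#' @param fc_block source-node by target-node weight matrix (a block of an
#'   `fc_matrix`'s coefficients).
#' @return predicted pattern vector, or miniblock-by-target matrix.
#' @export
activity_flow_map <- function(source_pattern, fc_block) {
  fc_block <- as.matrix(fc_block)
  if (is.matrix(source_pattern)) {
    if (ncol(source_pattern) != nrow(fc_block))
      stop(sprintf("source patterns have %d nodes but the FC block has %d rows",
                   ncol(source_pattern), nrow(fc_block)))
    return(source_pattern %*% fc_block)
  }
  if (length(source_pattern) != nrow(fc_block))
    stop(sprintf("source pattern has length %d but the FC block has %d rows",
                 length(source_pattern), nrow(fc_block)))
  as.vector(source_pattern %*% fc_block)
}

#' Information transfer estimate between a source and a target region
#'
#' Scores how much task information survives the connectivity-based mapping
#' from source to target: each miniblock's source pattern is mapped through
#' the FC block ([activity_flow_map()]), the predicted target patterns are
#' spatially demeaned, and a cross-validated match-versus-mismatch
#' representational similarity analysis compares each predicted pattern with
#' the *actual* target condition prototypes (built with the block's fold
#' held out, exactly as in [information_estimate()]). Positive values mean
#' the FC topology preserves condition-specific pattern geometry.
#'
#' @param source,target `activation_set`s (or miniblock-by-node matrices)
#'   over the same miniblocks, with identical labels.
#' @param fc_block source-node by target-node FC weight block.
#' @param labels condition labels (defaults to the source set's labels).
#' @param rule_domain label column when several rule domains are present.
#' @return an object of class `information_estimate` whose `value` is the
#'   transfer estimate; `per_block` holds the miniblock-wise values used by
#'   behavioral decoding.
#' @export
info_transfer_estimate <- function(source, target, fc_block, labels = NULL,
                                   rule_domain = NULL) {
  sb <- pattern_block(source, labels, rule_domain)
  tb <- pattern_block(target, sb$labels, rule_domain)
  if (!identical(nrow(sb$patterns), nrow(tb$patterns)))
    stop("source and target must cover the same miniblocks")
  predicted <- activity_flow_map(sb$patterns, fc_block)
  rsa_match_mismatch(predicted, tb$patterns, sb$labels)
}

#' Pairwise information transfer mapping
#'
#' Computes [info_transfer_estimate()] for every ordered (source, target)
#' pair of networks (or regions) in a partition. At the region level,
#' source nodes flagged in the exclusion mask against any node of the
#' target region contribute zero weight, preventing spatial-proximity
#' leakage; self-pairs are undefined (NA diagonal).
#'
#' @param activations an `activation_set` covering all nodes.
#' @param fc an `fc_matrix` over the same nodes.
#' @param partition a [network_partition()] (or label vector) assigning
#'   nodes to networks/regions.
#' @param labels,rule_domain condition labels, as in
#'   [info_transfer_estimate()].
#' @param exclusion_mask optional node-by-node 0/1 matrix; 1 marks a
#'   (source node, target node) pair whose FC weight is zeroed before
#'   mapping.
#' @return an object of class `transfer_matrix`: `estimates` (source
#'   network x target network), `per_block` (named list of per-block value
#'   vectors), `networks`.
#' @export
pairwise_transfer_mapping <- function(activations, fc, partition,
                                      labels = NULL, rule_domain = NULL,
                                      exclusion_mask = NULL) {
  pb <- pattern_block(activations, labels, rule_domain)
  nets_of <- partition_labels(partition, ncol(pb$patterns))
  nets <- sort(unique(nets_of))
  W <- fc$coefficients
  est <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(source = as.character(nets),
                                target = as.character(nets)))
  per_block <- list()
  for (a in seq_along(nets)) {
    src_nodes <- which(nets_of == nets[a])
    for (b in seq_along(nets)) {
      if (a == b) next
      tgt_nodes <- which(nets_of == nets[b])
      blk <- W[src_nodes, tgt_nodes, drop = FALSE]
      if (!is.null(exclusion_mask))
        blk[exclusion_mask[src_nodes, tgt_nodes, drop = FALSE] == 1] <- 0
      te <- rsa_match_mismatch(
        activity_flow_map(pb$patterns[, src_nodes, drop = FALSE], blk),
        pb$patterns[, tgt_nodes, drop = FALSE], pb$labels)
      est[a, b] <- te$value
      per_block[[paste(nets[a], nets[b], sep = "->")]] <- te$per_block
    }
  }
  structure(list(estimates = est, per_block = per_block, networks = nets),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("Information transfer estimates (source network in rows):\n")
  print(round(x$estimates, 4))
  invisible(x)
}

#' FC-topology permutation test for a transfer estimate
#'
#' Tests whether a transfer estimate depends on the fine-grained FC
#' topology rather than, e.g., the overall weight scale: the estimate is
#' recomputed under permutations of the FC block that destroy the
#' source-to-target correspondence while preserving the weight
#' distribution, and the p-value is the permutation tail probability
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param source,target,fc_block,labels,rule_domain as in
#'   [info_transfer_estimate()].
#' @param n_perm number of permutations (>= 100).
#' @param scheme `"column"` (default: shuffle target-node columns,
#'   preserving each source node's outgoing weight multiset), `"row"`, or
#'   `"full"` (shuffle all entries).
#' @return list with `p`, `observed`, `null` (the permutation estimates).
#' @export
fc_permutation_test <- function(source, target, fc_block, labels = NULL,
                                rule_domain = NULL, n_perm = 1000,
                                scheme = c("column", "row", "full")) {
  scheme <- match.arg(scheme)
  if (n_perm < 100) stop("n_perm must be at least 100")
  sb <- pattern_block(source, labels, rule_domain)
  tb <- pattern_block(target, sb$labels, rule_domain)
  fc_block <- as.matrix(fc_block)
  pre <- rsa_precompute(tb$patterns, sb$labels)
  observed <- rsa_score(activity_flow_map(sb$patterns, fc_block), pre)$value
  null <- vapply(seq_len(n_perm), function(p) {
    blk <- permute_fc_block(fc_block, scheme)
    rsa_score(activity_flow_map(sb$patterns, blk), pre)$value
  }, numeric(1))
  list(p = (1 + sum(null >= observed)) / (n_perm + 1),
       observed = observed, null = null, scheme = scheme)
}

permute_fc_block <- function(blk, scheme) {
  switch(scheme,
         column = blk[, sample.int(ncol(blk)), drop = FALSE],
         row = blk[sample.int(nrow(blk)), , drop = FALSE],
         full = matrix(sample(blk), nrow(blk), ncol(blk)))
}
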