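#' Multiple-regression functional connectivity
#'
#' For each target node i, fits the ordinary-least-squares regression of its
#' time series on the time series of all other nodes (plus an intercept,
#' absorbed by per-node demeaning) and stores the coefficient of source j
#' predicting target i at `coefficients[j, i]`. The diagonal is exactly
#' zero: a node never predicts itself. These semipartial estimates retain
#' the scaling of each source into the target's units, which is what the
#' activity-flow mapping in [activity_flow_map()] requires.
#'
#' @param timeseries a `timeseries_matrix` or a node-by-timepoint matrix.
#' @return an object of class `fc_matrix` with `coefficients` (source x
#'   target), `node_ids`, and `method = "multreg"`.
#' @export
multreg_fc <- function(timeseries) {
  X <- fc_input_matrix(timeseries)        # timepoints x nodes
  n <- ncol(X)
  if (nrow(X) <= n)
    stop(sprintf("under-determined system: %d timepoints for %d nodes; use pcreg_fc()",
                 nrow(X), n))
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant time series for node(s): ",
         paste(which(sds == 0), collapse = ", "))
  Xc <- sweep(X, 2, colMeans(X))
  qrX <- qr(Xc)
  if (qrX$rank < n) {
    bad <- sort(qrX$pivot[seq(qrX$rank + 1L, n)])
    stop("rank-deficient regressor matrix; offending node(s): ",
         paste(bad, collapse = ", "))
  }
  B <- multreg_coefficients(Xc)
  fc_matrix(B, node_ids = colnames(X), method = "multreg")
}

#' Principal-components regression connectivity for one target
#'
#' Used when sources outnumber timepoints (vertex-level FC). Masked sources
#' are removed before component extraction; the target is regressed on the
#' leading principal components of the remaining (demeaned) source matrix;
#' coefficients are back-projected to source space; masked sources receive a
#' coefficient of exactly 0.
#'
#' @param sources a `timeseries_matrix` or node-by-timepoint matrix of
#'   source signals.
#' @param target numeric vector, the target signal.
#' @param n_components number of leading components to retain.
#' @param mask optional logical/0-1 vector over sources; `TRUE`/1 marks a
#'   source excluded from the regression (e.g. spatial-proximity exclusion).
#' @return numeric coefficient vector over all sources (masked entries 0).
#' @export
pcreg_fc <- function(sources, target, n_components = 500, mask = NULL) {
  X <- fc_input_matrix(sources)
  if (length(target) != nrow(X))
    stop("target length does not match the number of timepoints")
  keep <- seq_len(ncol(X))
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    if (length(mask) != ncol(X)) stop("mask length must equal source count")
    keep <- which(!mask)
  }
  Xk <- sweep(X[, keep, drop = FALSE], 2, colMeans(X[, keep, drop = FALSE]))
  y <- target - mean(target)
  sv <- svd(Xk, nu = 0)
  rank <- sum(sv$d > sv$d[1] * max(dim(Xk)) * .Machine$double.eps)
  if (n_components > rank)
    stop(sprintf("n_components = %d exceeds the attained rank %d",
                 n_components, rank))
  V <- sv$v[, seq_len(n_components), drop = FALSE]
  scores <- Xk %*% V
  gamma <- qr.coef(qr(scores), y)
  beta <- numeric(ncol(X))
  beta[keep] <- as.vector(V %*% gamma)
  beta
}

#' Between-network global connectivity
#'
#' For node i in network C, BGC_i is the sum of its FC estimates to all
#' nodes outside C, divided by the number of such nodes
#' (`N_total - N_C`). The network-level BGC is the mean over member nodes.
#'
#' @param fc an `fc_matrix` (rows are source nodes).
#' @param partition a [network_partition()] or a label vector over nodes.
#' @return a list with `node` (data frame: node, network, bgc) and
#'   `network` (data frame: network, bgc).
#' @export
bgc <- function(fc, partition) {
  W <- fc$coefficients
  labels <- partition_labels(partition, nrow(W))
  nets <- sort(unique(labels))
  if (length(nets) < 2)
    stop("BGC is undefined for a single-network partition")
  n_total <- nrow(W)
  node_bgc <- vapply(seq_len(n_total), function(i) {
    out <- labels != labels[i]
    sum(W[i, out]) / sum(out)
  }, numeric(1))
  net_bgc <- vapply(nets, function(g) mean(node_bgc[labels == g]), numeric(1))
  list(node = data.frame(node = seq_len(n_total), network = labels,
                         bgc = node_bgc),
       network = data.frame(network = nets, bgc = net_bgc))
}

#' Functional connectivity matrix container
#'
#' @param coefficients source-by-target numeric matrix; `[j, i]` holds the
#'   coefficient of source j predicting target i. Diagonal must be zero.
#' @param node_ids optional node identifiers.
#' @param method estimation method label.
#' @return an object of class `fc_matrix`.
#' @export
fc_matrix <- function(coefficients, node_ids = NULL,
                      method = c("multreg", "pcreg")) {
  method <- match.arg(method)
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != ncol(coefficients))
    stop("coefficients must be square")
  if (any(diag(coefficients) != 0))
    stop("diagonal of an FC matrix must be exactly zero")
  if (!all(is.finite(coefficients)))
    stop("FC coefficients must be finite")
  if (is.null(node_ids)) node_ids <- as.character(seq_len(nrow(coefficients)))
  structure(list(coefficients = coefficients, node_ids = node_ids,
                 method = method), class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("FC matrix (%s): %d x %d, mean |coef| %.4g\n", x$method,
              nrow(x$coefficients), ncol(x$coefficients),
              mean(abs(x$coefficients))))
  invisible(x)
}

#' Network partition
#'
#' @param labels vector assigning each node to exactly one network.
#' @return an object of class `network_partition`.
#' @export
network_partition <- function(labels) {
  if (any(is.na(labels))) stop("every node needs a network label")
  structure(list(labels = labels, networks = sort(unique(labels))),
            class = "network_partition")
}

partition_labels <- function(partition, n_nodes) {
  labels <- if (inherits(partition, "network_partition")) partition$labels else partition
  if (length(labels) != n_nodes)
    stop(sprintf("partition covers %d nodes but the FC matrix has %d",
                 length(labels), n_nodes))
  if (any(is.na(labels))) stop("every node needs a network label")
  labels
}

#' Pearson-correlation FC (diagnostic export only)
#'
#' Provided for comparison with [multreg_fc()]; the transfer pipeline never
#' uses it.
#'
#' @inheritParams multreg_fc
#' @return an `fc_matrix`-shaped plain matrix of correlations, zero diagonal.
#' @export
pearson_fc <- function(timeseries) {
  X <- fc_input_matrix(timeseries)
  r <- cor(X)
  diag(r) <- 0
  r
}

# Accept a timeseries_matrix (nodes x time) or plain matrix in either
# orientation convention; returns timepoints x nodes.
fc_input_matrix <- function(timeseries) {
  if (inherits(timeseries, "timeseries_matrix")) t(timeseries$data)
  else t(as.matrix(timeseries))
}
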