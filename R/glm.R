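#' Miniblock task GLM
#'
#' Fits a standard block general linear model to BOLD: one boxcar regressor
#' per miniblock, convolved with the canonical double-gamma HRF, fit jointly
#' with an intercept and any nuisance regressors by ordinary least squares.
#' The result is one beta pattern (one value per node) per miniblock, with
#' the design table's condition labels attached; these block-wise patterns
#' are the decoding unit for [information_estimate()] and the transfer
#' mapping.
#'
#' Regressors are built by sampling each block's boxcar on a fine grid
#' (`oversample` points per TR), convolving with the HRF at that resolution
#' and decimating to the TR grid, mirroring the forward model in
#' [to_bold()].
#'
#' @param bold a `timeseries_matrix` of kind `"bold"`.
#' @param design a block design table (data frame with columns `block`,
#'   `condition` — or several condition columns — `onset_s`, `duration_s`),
#'   or a `task_design`.
#' @param nuisance optional timepoint-by-regressor nuisance matrix fit
#'   alongside the block regressors.
#' @param oversample fine-grid points per TR used to build the regressors.
#' @param vif_threshold warn when any block regressor's variance inflation
#'   factor exceeds this (overlapping convolved blocks).
#' @return an object of class `activation_set`: `betas` (miniblock x node),
#'   `labels` (design table rows), `node_ids`.
#' @export
estimate_betas <- function(bold, design, nuisance = NULL, oversample = 16,
                           vif_threshold = 30) {
  stopifnot(inherits(bold, "timeseries_matrix"))
  if (inherits(design, "task_design")) design <- design$schedule
  tr <- bold$sampling_interval
  Tn <- ncol(bold$data)
  run_len <- Tn * tr
  if (any(design$onset_s < 0) || any(design$onset_s + design$duration_s > run_len))
    stop("design onsets/durations fall outside the run")
  if (any(diff(design$onset_s[order(design$onset_s)]) <
          design$duration_s[order(design$onset_s)][-nrow(design)]))
    stop("overlapping blocks within the run")

  R <- block_regressors(design, Tn, tr, oversample)
  vif <- regressor_vif(R)
  if (any(vif > vif_threshold))
    warning(sprintf("collinear convolved design: max VIF %.1f (blocks %s)",
                    max(vif),
                    paste(which(vif > vif_threshold), collapse = ", ")))
  X <- cbind(1, R)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != Tn) stop("nuisance matrix has wrong row count")
    X <- cbind(X, nuisance)
  }
  fit <- qr.coef(qr(X), t(bold$data))
  betas <- fit[1 + seq_len(ncol(R)), , drop = FALSE]     # miniblock x node
  activation_set(betas, labels = design,
                 node_ids = as.character(seq_len(nrow(bold$data))))
}

# Boxcar-convolved block regressors on the TR grid. One column per block.
block_regressors <- function(design, n_timepoints, tr, oversample = 16) {
  fine_dt <- tr / oversample
  n_fine <- n_timepoints * oversample
  fine_t <- (seq_len(n_fine) - 1) * fine_dt
  box <- matrix(0, nrow(design), n_fine)
  for (b in seq_len(nrow(design))) {
    box[b, fine_t >= design$onset_s[b] &
          fine_t < design$onset_s[b] + design$duration_s[b]] <- 1
  }
  h <- canonical_hrf(seq(0, 32, by = fine_dt))
  t(convolve_decimate(box, h, as.integer(oversample)))
}

regressor_vif <- function(R) {
  Rc <- sweep(R, 2, colMeans(R))
  cc <- crossprod(scale(Rc, center = FALSE,
                        scale = sqrt(colSums(Rc^2))))
  inv <- tryCatch(solve(cc), error = function(e) NULL)
  if (is.null(inv)) return(rep(Inf, ncol(R)))
  diag(inv)
}

#' Activation pattern container
#'
#' @param betas miniblock-by-node matrix of GLM beta estimates.
#' @param labels data frame of per-miniblock labels (at least a `condition`
#'   column, or one column per rule domain).
#' @param node_ids optional node identifiers.
#' @return an object of class `activation_set`.
#' @export
activation_set <- function(betas, labels, node_ids = NULL) {
  betas <- as.matrix(betas)
  labels <- as.data.frame(labels)
  if (nrow(labels) != nrow(betas))
    stop("one label row per miniblock is required")
  if (is.null(node_ids)) node_ids <- as.character(seq_len(ncol(betas)))
  structure(list(betas = betas, labels = labels, node_ids = node_ids),
            class = "activation_set")
}

#' @export
print.activation_set <- function(x, ...) {
  cat(sprintf("Activation set: %d miniblocks x %d nodes\n",
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}
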