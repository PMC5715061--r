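#' Read and write delimited matrices and tables
#'
#' All text interchange uses tab-separated UTF-8 files with a mandatory
#' header row and '.' as the decimal mark. Matrices are written nodes in
#' rows with a header of timepoint/column indices; round-trips are lossless
#' to full double precision (values are serialized with 17 significant
#' digits).
#'
#' @param m numeric matrix.
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix; writers return the
#'   path invisibly.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  df <- as.data.frame(formatC(m, format = "g", digits = 17))
  names(df) <- if (!is.null(colnames(m))) colnames(m) else
    paste0("t", seq_len(ncol(m)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) == 0) stop("malformed matrix file (no columns): ", path)
  as.matrix(vapply(df, as.numeric, numeric(nrow(df))))
}

#' Write / read a time-series matrix
#'
#' The data file holds nodes in rows; an accompanying `<path>.json` records
#' the sampling interval and kind so a round-trip restores the full object.
#'
#' @param ts a `timeseries_matrix`.
#' @param path data file path (the attribute sidecar gets `.json` appended).
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  write_matrix_tsv(ts$data, path)
  jsonlite::write_json(list(sampling_interval = ts$sampling_interval,
                            kind = ts$kind),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  attrs <- jsonlite::read_json(paste0(path, ".json"))
  timeseries_matrix(read_matrix_tsv(path),
                    sampling_interval = attrs$sampling_interval,
                    kind = attrs$kind)
}

#' Write / read a ground-truth synaptic network
#'
#' Writes `weights.tsv`, `structure.tsv` and `community.tsv` (node,
#' community, is_hub) under a directory.
#'
#' @param network a `synaptic_network`.
#' @param dir output directory (created if needed).
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(network$weights, file.path(dir, "weights.tsv"))
  write_matrix_tsv(network$structure, file.path(dir, "structure.tsv"))
  comm <- data.frame(node = seq_len(network$n_nodes),
                     community = network$community,
                     is_hub = as.integer(network$community ==
                                           network$hub_community))
  write.table(comm, file.path(dir, "community.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  comm <- read.delim(file.path(dir, "community.tsv"))
  structure(list(weights = read_matrix_tsv(file.path(dir, "weights.tsv")),
                 structure = read_matrix_tsv(file.path(dir, "structure.tsv")),
                 community = comm$community,
                 hub_community = unique(comm$community[comm$is_hub == 1]),
                 n_nodes = nrow(comm)),
            class = "synaptic_network")
}

#' Read / write design and partition tables
#'
#' Design tables carry one row per miniblock (`block`, `condition`,
#' `onset_s`, `duration_s`); partition files are two-column
#' (`node_id`, `network_label`) with full coverage required.
#'
#' @param design,path,partition arguments as named.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_design <- function(design, path) {
  if (inherits(design, "task_design")) design <- design$schedule
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_design <- function(path) {
  df <- read.delim(path)
  need <- c("block", "condition", "onset_s", "duration_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("design table lacks column(s): ", paste(missing, collapse = ", "))
  df
}

#' @rdname table_io
#' @export
write_partition <- function(partition, path) {
  labels <- if (inherits(partition, "network_partition")) partition$labels else partition
  write.table(data.frame(node_id = seq_along(labels),
                         network_label = labels),
               path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_partition <- function(path, n_nodes = NULL) {
  df <- read.delim(path)
  if (!all(c("node_id", "network_label") %in% names(df)))
    stop("partition file needs node_id and network_label columns")
  if (any(is.na(df$network_label)))
    stop("partition does not cover all nodes: node(s) ",
         paste(df$node_id[is.na(df$network_label)], collapse = ", "),
         " lack a label")
  if (!is.null(n_nodes)) {
    missing <- setdiff(seq_len(n_nodes), df$node_id)
    if (length(missing))
      stop("partition does not cover all nodes: node(s) ",
           paste(missing, collapse = ", "), " lack a label")
  }
  network_partition(df$network_label[order(df$node_id)])
}

#' Write / read a subject container
#'
#' One directory per subject holding the rest and task BOLD runs, the block
#' design table, the ground-truth network, and a JSON attribute file
#' (sampling intervals, seed). Round-trips are lossless.
#'
#' @param subject a `subject_run` from [simulate_subject()].
#' @param dir container directory.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_timeseries(subject$rest, file.path(dir, "rest.tsv"))
  write_timeseries(subject$task, file.path(dir, "task.tsv"))
  write_design(subject$schedule, file.path(dir, "design.tsv"))
  write_network(subject$network, file.path(dir, "network"))
  jsonlite::write_json(list(seed = subject$seed,
                            stim_sets = subject$design$stim_sets,
                            amplitude = subject$design$amplitude),
                       file.path(dir, "attrs.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_subject
#' @export
read_subject <- function(dir) {
  attrs <- jsonlite::read_json(file.path(dir, "attrs.json"),
                               simplifyVector = TRUE)
  design <- structure(list(stim_sets = as.matrix(attrs$stim_sets),
                           schedule = read_design(file.path(dir, "design.tsv")),
                           amplitude = attrs$amplitude),
                      class = "task_design")
  structure(list(network = read_network(file.path(dir, "network")),
                 design = design,
                 rest = read_timeseries(file.path(dir, "rest.tsv")),
                 task = read_timeseries(file.path(dir, "task.tsv")),
                 schedule = design$schedule,
                 seed = attrs$seed),
            class = "subject_run")
}
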