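# Plain-text readers and writers for the pipeline's tabular formats:
# timeseries TSV, motion TSV, trials CSV, square-matrix CSV, edge-list TSV
# and network/partition JSON.

#' Write / read ROI timeseries as TSV
#'
#' The TSV carries one header row of ROI names and one row per scan;
#' run labels, the repetition time and the scan mask travel in leading
#' `run`/`retained` columns and a `# tr=<seconds>` comment line.
#'
#' @param ts a [roi_timeseries].
#' @param path file path.
#' @return `write_timeseries_tsv` returns `path` invisibly;
#'   `read_timeseries_tsv` returns a [roi_timeseries].
#' @export
write_timeseries_tsv <- function(ts, path) {
  stopifnot(inherits(ts, "roi_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr=%.17g", ts$tr), con)
  df <- data.frame(run = ts$run, retained = as.integer(ts$scan_mask),
                   ts$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_tsv
#' @export
read_timeseries_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# tr=", first)) stop("malformed timeseries TSV (", path,
                                    "): missing '# tr=' header line")
  tr <- as.numeric(sub("^# tr=", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1,
                          check.names = FALSE)
  if (!all(c("run", "retained") %in% names(df)))
    stop("malformed timeseries TSV (", path, "): need run/retained columns")
  vals <- as.matrix(df[, setdiff(names(df), c("run", "retained")), drop = FALSE])
  roi_timeseries(vals, tr = tr, run = df$run,
                 scan_mask = df$retained == 1)
}

#' Write / read a six-parameter motion trace as TSV
#' @param motion scans x 6 matrix.
#' @param path file path.
#' @export
write_motion_tsv <- function(motion, path) {
  m <- as.matrix(motion); class(m) <- "matrix"
  utils::write.table(as.data.frame(m), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_tsv
#' @export
read_motion_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
  if (ncol(m) != 6) stop("malformed motion TSV (", path, "): expected 6 columns")
  m
}

#' Write / read 2AFC trials as CSV (mixture, truth, response)
#' @param trials trial data frame.
#' @param path file path.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(trials[, c("mixture", "truth", "response")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mixture", "truth", "response") %in% names(df)))
    stop("malformed trials CSV (", path, ")")
  df
}

#' Write / read a square named matrix as CSV (header row and column)
#' @param m square matrix with dimnames.
#' @param path file path.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write a network as a three-column edge list TSV (node_a, node_b, weight)
#' @param net adjacency matrix (binary or weighted).
#' @param path file path.
#' @export
write_edgelist_tsv <- function(net, path) {
  A <- unclass_network(net)
  nm <- node_names(A)
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  df <- data.frame(node_a = nm[idx[, 1]], node_b = nm[idx[, 2]],
                   weight = A[idx])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a network with node roles, or a partition, as JSON
#' @param net a `binary_network`.
#' @param path file path.
#' @export
write_network_json <- function(net, path) {
  A <- unclass_network(net)
  nm <- node_names(A)
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  obj <- list(nodes = nm,
              roles = as.list(attr(net, "roles") %||% stats::setNames(
                rep("node", length(nm)), nm)),
              edges = unname(apply(idx, 1, function(r) list(nm[r[1]], nm[r[2]]))),
              density_percent = network_density(net))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @param partition a `network_partition`.
#' @rdname write_network_json
#' @export
write_partition_json <- function(partition, path) {
  jsonlite::write_json(list(membership = as.list(partition$membership),
                            q = partition$q, algorithm = partition$algorithm,
                            n_modules = partition$n_modules),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
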