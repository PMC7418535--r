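# Group olfactory network construction: Fisher-z correlation matrices,
# global-baseline t-tests, per-node proportional thresholding, seeded
# admission of secondary regions, and the cross-modality control.

FISHER_Z_CAP <- 0.9999999  # |r| at/above this is capped before atanh

#' Pairwise Fisher-z connectivity from a cleaned timeseries
#'
#' Pearson correlations over the retained scans, Fisher z-transformed
#' (atanh). Correlations at |r| = 1 (e.g. duplicated ROIs) are capped just
#' below 1 with a warning rather than mapped to infinity; zero-variance
#' ROIs yield flagged `NA` entries.
#'
#' @param ts a [roi_timeseries] (only scans with `scan_mask = TRUE` enter).
#' @param level `"subject"` or `"group"` annotation.
#' @return a symmetric matrix of Fisher-z values (class
#'   `connectivity_matrix`), diagonal `NA`, with the raw correlation matrix
#'   in attribute `"r"`.
#' @export
correlation_matrix <- function(ts, level = "subject") {
  stopifnot(inherits(ts, "roi_timeseries"))
  x <- retained_values(ts)
  if (nrow(x) < 3) stop("need at least 3 retained scans")
  if (ncol(x) < 2) stop("need at least 2 ROIs")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    warning("zero-variance ROI(s) flagged as NA: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
  r <- suppressWarnings(stats::cor(x))
  r[, sds == 0] <- NA; r[sds == 0, ] <- NA
  off <- abs(r) >= FISHER_Z_CAP & upper.tri(r)
  if (any(off, na.rm = TRUE))
    warning(sum(off, na.rm = TRUE),
            " correlation(s) at |r| ~ 1 capped before Fisher transform")
  rc <- pmin(pmax(r, -FISHER_Z_CAP), FISHER_Z_CAP)
  z <- atanh(rc)
  diag(z) <- NA
  structure(z, class = c("connectivity_matrix", "matrix"),
            r = r, level = level)
}

#' Average subject Fisher-z matrices into a group matrix
#'
#' @param z_list list of `connectivity_matrix` objects on the same nodes.
#' @return the element-wise mean as a group-level `connectivity_matrix`.
#' @export
group_connectivity <- function(z_list) {
  stopifnot(length(z_list) >= 1)
  nm <- node_names(z_list[[1]])
  for (z in z_list)
    if (!identical(node_names(z), nm)) stop("subject matrices must share nodes")
  zbar <- Reduce(`+`, lapply(z_list, unclass)) / length(z_list)
  rbar <- Reduce(`+`, lapply(z_list, function(z) attr(z, "r"))) / length(z_list)
  structure(zbar, class = c("connectivity_matrix", "matrix"),
            r = rbar, level = "group")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("%s-level Fisher-z connectivity: %d x %d nodes\n",
              attr(x, "level") %||% "subject", nrow(x), ncol(x)))
  invisible(x)
}

#' Per-node global baseline connectivity
#'
#' A node's baseline is the mean of its Fisher-z values to all other
#' regions of the whole-brain context matrix; a node pair's baseline is the
#' mean of its two nodes' baselines.
#'
#' @param whole_brain a whole-brain `connectivity_matrix`.
#' @return named numeric vector of per-node baselines.
#' @export
global_baseline <- function(whole_brain) {
  check_square_symmetric(unclass(whole_brain), what = "whole-brain matrix")
  z <- unclass(whole_brain)
  diag(z) <- NA
  rowMeans(z, na.rm = TRUE)
}

#' One-sample t-test of pair connectivity against its global baseline
#'
#' For each ROI pair, tests across subjects whether the pair's Fisher z
#' exceeds the pair's global baseline (mean of the two nodes' baselines),
#' returning the t statistic and the one-tailed exceedance p value.
#' Zero-variance differences are capped at t = +/-Inf (p = 0 or 1); an
#' all-zero difference gives t = 0, p = 0.5.
#'
#' @param subject_z list of subject `connectivity_matrix` objects
#'   restricted to the ROI set.
#' @param subject_baselines subjects x nodes matrix of per-subject global
#'   baselines for those nodes (from [global_baseline] on each subject's
#'   whole-brain matrix).
#' @return list of symmetric matrices `t` and `p` over the ROI pairs.
#' @export
edge_ttest <- function(subject_z, subject_baselines) {
  n <- length(subject_z)
  if (n < 2) stop("need at least 2 subjects")
  nm <- node_names(subject_z[[1]])
  if (!all(nm %in% colnames(subject_baselines)))
    stop("subject_baselines must cover all ROI nodes")
  p <- length(nm)
  tmat <- pmat <- matrix(NA_real_, p, p, dimnames = list(nm, nm))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    d <- vapply(seq_len(n), function(s)
      unclass(subject_z[[s]])[i, j] -
        (subject_baselines[s, nm[i]] + subject_baselines[s, nm[j]]) / 2,
      numeric(1))
    m <- mean(d); sdev <- stats::sd(d)
    tv <- if (sdev == 0) {
      if (m == 0) 0 else sign(m) * Inf
    } else m / (sdev / sqrt(n))
    tmat[i, j] <- tmat[j, i] <- tv
    pmat[i, j] <- pmat[j, i] <- stats::pt(tv, df = n - 1, lower.tail = FALSE)
  }
  list(t = tmat, p = pmat)
}

#' Per-node proportional thresholding to a binary network
#'
#' For each node, its `k = floor(density * (N - 1))` strongest connections
#' within the context matrix are marked; an edge is suprathreshold iff it
#' is marked from at least one endpoint (union rule; the stricter
#' both-endpoint rule is available via `rule = "and"`). Rank ties are
#' broken by partner-name lexicographic order for determinism.
#'
#' @param z a `connectivity_matrix` (the ranking context; may include
#'   whole-brain regions beyond the ROI set).
#' @param density proportion of connections retained per node, in (0, 1).
#' @param rule `"union"` (default) or `"and"` symmetrization.
#' @return a 0/1 adjacency matrix of class `binary_network`.
#' @export
threshold_proportional <- function(z, density = 0.05, rule = c("union", "and")) {
  rule <- match.arg(rule)
  zm <- unclass(z)
  check_square_symmetric(zm, what = "connectivity matrix")
  nm <- node_names(zm)
  N <- length(nm)
  k <- floor(density * (N - 1))
  if (density <= 0 || density >= 1) stop("density must lie in (0, 1)")
  if (k < 1)
    stop(sprintf("density %g retains no connections for %d nodes (k = 0)",
                 density, N))
  marked <- matrix(FALSE, N, N, dimnames = list(nm, nm))
  lex <- rank(nm)  # lexicographic tie-break on partner names
  for (i in seq_len(N)) {
    zi <- zm[i, ]; zi[i] <- -Inf; zi[is.na(zi)] <- -Inf
    o <- order(-zi, lex)
    marked[i, o[seq_len(k)]] <- TRUE
  }
  A <- if (rule == "union") (marked | t(marked)) else (marked & t(marked))
  A <- matrix(as.numeric(A), N, N, dimnames = list(nm, nm))
  diag(A) <- 0
  structure(A, class = c("binary_network", "matrix"), density = density)
}

# strip the class/attrs from a binary_network, keeping dimnames
unclass_network <- function(net) {
  A <- unclass(net)
  attr(A, "density") <- NULL; attr(A, "roles") <- NULL
  A
}

#' @export
print.binary_network <- function(x, ...) {
  A <- unclass_network(x)
  n <- nrow(A); e <- sum(A) / 2
  cat(sprintf("Binary network: %d nodes, %d edges (density %.1f%%)\n",
              n, e, 100 * e / (n * (n - 1) / 2)))
  roles <- attr(x, "roles")
  if (!is.null(roles))
    cat("  roles:", paste(sprintf("%s=%d", names(table(roles)), table(roles)),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Seed the network from key regions and admit connected candidates
#'
#' Key nodes are always retained; a candidate is admitted iff it has at
#' least one suprathreshold edge to a key node. The returned network is the
#' induced subgraph among retained nodes, annotated with node roles
#' (`key` / `secondary` / `rejected`, the latter recorded in the `roles`
#' attribute over the full key + candidate set).
#'
#' @param adjacency a `binary_network` covering keys and candidates.
#' @param key_nodes seed node names.
#' @param candidate_nodes candidate node names (disjoint from keys).
#' @param significant optional symmetric logical matrix (e.g. baseline
#'   t-test `p < alpha`); when supplied, an edge counts only if also
#'   significant (conjunction mode).
#' @return the induced `binary_network` over retained nodes.
#' @export
build_seeded_network <- function(adjacency, key_nodes, candidate_nodes,
                                 significant = NULL) {
  if (length(key_nodes) == 0) stop("key node set must not be empty")
  A <- unclass_network(adjacency)
  nm <- node_names(A)
  if (!all(key_nodes %in% nm)) stop("key nodes missing from adjacency")
  if (!all(candidate_nodes %in% nm)) stop("candidate nodes missing from adjacency")
  if (length(intersect(key_nodes, candidate_nodes)))
    stop("candidates must be disjoint from key nodes")
  if (!is.null(significant)) {
    sig <- significant[nm, nm]
    sig[is.na(sig)] <- FALSE
    A <- A * (sig * 1)
  }
  linked <- rowSums(A[candidate_nodes, key_nodes, drop = FALSE]) > 0
  admitted <- candidate_nodes[linked]
  keep <- c(key_nodes, admitted)
  roles <- c(stats::setNames(rep("key", length(key_nodes)), key_nodes),
             stats::setNames(ifelse(linked, "secondary", "rejected"),
                             candidate_nodes))
  sub <- A[keep, keep, drop = FALSE]
  structure(sub, class = c("binary_network", "matrix"),
            density = attr(adjacency, "density"), roles = roles)
}

#' Suprathreshold edge counts between two disjoint node sets
#'
#' The cross-modality specificity control: thresholds the context matrix at
#' each density and counts suprathreshold edges crossing the two sets.
#'
#' @param z the context `connectivity_matrix` covering both sets.
#' @param set_a,set_b disjoint node-name sets.
#' @param densities densities to evaluate (default 5%, 10%, 15%).
#' @return named numeric vector of cross-set edge counts per density.
#' @export
cross_modality_control <- function(z, set_a, set_b,
                                   densities = c(0.05, 0.10, 0.15)) {
  if (length(intersect(set_a, set_b))) stop("node sets must be disjoint")
  vapply(densities, function(d) {
    A <- unclass_network(threshold_proportional(z, d))
    sum(A[set_a, set_b, drop = FALSE])
  }, numeric(1)) -> counts
  names(counts) <- sprintf("%g%%", 100 * densities)
  counts
}

#' Connection density of a binary network, in percent
#'
#' @param net a `binary_network` (or plain 0/1 adjacency matrix).
#' @return `100 * E / (n (n - 1) / 2)`.
#' @export
network_density <- function(net) {
  A <- unclass_network(net)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 nodes")
  100 * (sum(A != 0) / 2) / (n * (n - 1) / 2)
}
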