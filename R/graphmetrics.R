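# Graph-theoretic characterization: clustering, efficiency, centralities,
# composite hubness, participation, Louvain and Girvan-Newman modularity
# with degree-preserving permutation nulls, small-world indices, node
# deletion resilience, and standardized Rand partition similarity.
#
# igraph provides the graph algorithms (shortest paths, betweenness,
# community detection, degree-preserving rewiring); the quantities the
# analysis reports (modularity formula, Onnela weighted clustering, global
# efficiency, participation, composite scores, z-Rand) are computed here
# explicitly so every reported number has a closed-form definition.

# adjacency (weights allowed) -> igraph, edge lengths = 1/weight when weighted
as_graph <- function(A, weighted = FALSE) {
  mode <- if (weighted) "undirected" else "undirected"
  g <- igraph::graph_from_adjacency_matrix(A, mode = mode,
                                           weighted = if (weighted) TRUE else NULL,
                                           diag = FALSE)
  g
}

# shortest-path distance matrix; weighted uses length = 1/weight
distance_matrix <- function(A, weighted = FALSE) {
  if (any(A < 0)) stop("negative weights are not supported")
  g <- as_graph(A, weighted)
  w <- if (weighted) 1 / igraph::E(g)$weight else NULL
  igraph::distances(g, weights = w)
}

#' Mean clustering coefficient (binary or Onnela weighted)
#'
#' Binary: each node's fraction of closed triangles among its neighbor
#' pairs; nodes of degree < 2 contribute 0. Weighted: the geometric-mean
#' triangle form on weights normalized by the maximum weight, with the
#' degree taken from the binary support. Reduces to the binary form when
#' all weights are 1.
#'
#' @param net adjacency matrix (0/1 or non-negative weights).
#' @param weighted use the weighted form.
#' @return list with per-node `local` values and the network mean `C`.
#' @export
clustering_coefficient <- function(net, weighted = FALSE) {
  A <- unclass_network(net)
  if (nrow(A) < 3) stop("need at least 3 nodes")
  B <- (A != 0) * 1
  k <- rowSums(B)
  W <- if (weighted) {
    mx <- max(A)
    if (mx == 0) stop("all-zero network")
    (A / mx)^(1 / 3)
  } else B
  tri <- diag(W %*% W %*% W) / 2
  denom <- k * (k - 1) / 2
  local <- ifelse(denom > 0, tri / denom, 0)
  names(local) <- rownames(A)
  list(local = local, C = mean(local))
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length;
#' disconnected pairs contribute 0. Weighted paths use edge length
#' 1/weight.
#'
#' @param net adjacency matrix.
#' @param weighted use weighted path lengths.
#' @return the scalar efficiency `G`.
#' @export
global_efficiency <- function(net, weighted = FALSE) {
  A <- unclass_network(net)
  if (nrow(A) < 2) stop("need at least 2 nodes")
  D <- distance_matrix(A, weighted)
  inv <- 1 / D
  diag(inv) <- NA
  inv[is.infinite(D)] <- 0
  mean(inv, na.rm = TRUE)
}

# characteristic path length over finite off-diagonal distances
char_path_length <- function(A, weighted = FALSE) {
  D <- distance_matrix(A, weighted)
  diag(D) <- NA
  mean(D[is.finite(D)], na.rm = TRUE)
}

#' Node centralities: degree, betweenness, closeness
#'
#' Betweenness is the fraction of all shortest paths passing through a node
#' (Brandes fractional counting over path multiplicities, endpoints
#' excluded, normalized by `(n-1)(n-2)/2`). Closeness is the reciprocal of
#' the node's mean distance to the others; on a disconnected graph it is
#' computed per reachable set with a warning, and isolated nodes score 0.
#'
#' @param net binary adjacency matrix.
#' @return data frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
centralities <- function(net) {
  A <- unclass_network(net)
  nm <- node_names(A)
  g <- as_graph(A)
  n <- nrow(A)
  btw <- igraph::betweenness(g, normalized = TRUE, weights = NA)
  D <- distance_matrix(A)
  diag(D) <- NA
  if (any(is.infinite(D)))
    warning("graph is disconnected; closeness computed per reachable set")
  clo <- apply(D, 1, function(d) {
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else 1 / mean(d)
  })
  data.frame(node = nm, degree = rowSums(A != 0),
             betweenness = as.numeric(btw), closeness = as.numeric(clo),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Composite hubness from the three centrality metrics
#'
#' Each centrality is z-scored across nodes (a zero-variance metric
#' contributes 0, with a warning); the composite z is the mean of the three
#' z-scores and the composite rank the mean of the three descending
#' within-metric ranks.
#'
#' @param metrics data frame from [centralities].
#' @return the input extended with `z_degree`, `z_betweenness`,
#'   `z_closeness`, `composite_z`, `composite_rank`.
#' @export
composite_hubness <- function(metrics) {
  if (nrow(metrics) < 2) stop("need at least 2 nodes")
  zcol <- function(x, label) {
    s <- stats::sd(x)
    if (s == 0) {
      warning("zero variance in ", label, "; its z contribution is 0")
      rep(0, length(x))
    } else (x - mean(x)) / s
  }
  zd <- zcol(metrics$degree, "degree")
  zb <- zcol(metrics$betweenness, "betweenness")
  zc <- zcol(metrics$closeness, "closeness")
  rks <- cbind(rank(-metrics$degree, ties.method = "average"),
               rank(-metrics$betweenness, ties.method = "average"),
               rank(-metrics$closeness, ties.method = "average"))
  metrics$z_degree <- zd; metrics$z_betweenness <- zb; metrics$z_closeness <- zc
  metrics$composite_z <- (zd + zb + zc) / 3
  metrics$composite_rank <- rowMeans(rks)
  metrics
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_s (k_is / k_i)^2` over modules `s`; 0 for nodes whose
#' connections all stay within their own module (or isolated nodes), near
#' 1 for connector hubs with connections spread evenly across modules.
#' Weighted networks use strengths in place of degrees.
#'
#' @param net adjacency matrix.
#' @param membership named module assignment covering the nodes.
#' @return named per-node participation coefficients in [0, 1].
#' @export
participation_coefficient <- function(net, membership) {
  A <- unclass_network(net)
  nm <- node_names(A)
  mem <- membership_vector(membership, nm)
  k <- rowSums(A)
  kis <- t(rowsum(t(A), mem))  # nodes x modules
  P <- ifelse(k > 0, 1 - rowSums((kis / pmax(k, 1))^2), 0)
  stats::setNames(as.numeric(P), nm)
}

# normalize partition/membership input to a named vector over `nodes`
membership_vector <- function(membership, nodes) {
  if (inherits(membership, "network_partition")) membership <- membership$membership
  if (is.null(names(membership))) {
    if (length(membership) != length(nodes))
      stop("membership must be named or align with the node set")
    names(membership) <- nodes
  }
  if (!all(nodes %in% names(membership)))
    stop("membership does not cover all nodes")
  membership[nodes]
}

#' Newman-Girvan modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`, valid for
#' binary and weighted networks.
#'
#' @param net adjacency matrix.
#' @param membership module assignment (named, or a `network_partition`).
#' @return the modularity `Q` in [-1/2, 1].
#' @export
modularity_q <- function(net, membership) {
  A <- unclass_network(net)
  mem <- membership_vector(membership, node_names(A))
  m2 <- sum(A)
  if (m2 == 0) stop("network has no edges")
  k <- rowSums(A)
  same <- outer(mem, mem, "==")
  sum((A - outer(k, k) / m2) * same) / m2
}

new_partition <- function(membership, q, algorithm) {
  structure(list(membership = membership, q = q, algorithm = algorithm,
                 n_modules = length(unique(membership))),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("Partition (%s): %d modules, Q = %.4f\n",
              x$algorithm, x$n_modules, x$q))
  invisible(x)
}

#' Louvain community detection with randomized restarts
#'
#' Runs the Louvain algorithm `n_restarts` times under seeded randomized
#' node orders and keeps the maximum-Q partition (ties broken by first
#' occurrence). Q is recomputed from the modularity formula
#' ([modularity_q]) on the returned membership.
#'
#' @param net adjacency matrix (binary or weighted).
#' @param n_restarts number of randomized restarts (default 10000).
#' @param seed integer seed; results are deterministic given it.
#' @param weighted use edge weights in the modularity objective.
#' @return a `network_partition`.
#' @export
modularity_louvain <- function(net, n_restarts = 10000L, seed = 1L,
                               weighted = FALSE) {
  A <- unclass_network(net)
  if (sum(A) == 0) stop("network has no edges")
  g <- as_graph(A, weighted)
  w <- if (weighted) igraph::E(g)$weight else NULL
  best <- NULL; best_q <- -Inf
  with_seed(seed, {
    for (i in seq_len(n_restarts)) {
      cl <- igraph::cluster_louvain(g, weights = w)
      mem <- igraph::membership(cl)
      q <- modularity_q(A, stats::setNames(as.integer(mem), node_names(A)))
      if (q > best_q + 1e-12) { best_q <- q; best <- mem }
    }
  })
  mem <- stats::setNames(as.integer(best), node_names(A))
  new_partition(mem, best_q, "louvain")
}

#' Girvan-Newman community detection
#'
#' Iterative removal of the highest-edge-betweenness edge; of the resulting
#' dendrogram levels, the one maximizing the modularity formula is
#' returned. Deterministic.
#'
#' @param net binary adjacency matrix.
#' @return a `network_partition`.
#' @export
modularity_girvan_newman <- function(net) {
  A <- unclass_network(net)
  if (sum(A) == 0) stop("network has no edges")
  g <- as_graph(A)
  cl <- igraph::cluster_edge_betweenness(g, weights = NULL)
  nm <- node_names(A)
  best <- NULL; best_q <- -Inf
  for (k in seq_len(nrow(A))) {
    mem <- tryCatch(igraph::cut_at(cl, no = k), error = function(e) NULL)
    if (is.null(mem)) next
    q <- modularity_q(A, stats::setNames(as.integer(mem), nm))
    if (q > best_q + 1e-12) { best_q <- q; best <- mem }
  }
  new_partition(stats::setNames(as.integer(best), nm), best_q, "girvan-newman")
}

#' Largest connected component of a network
#'
#' @param net adjacency matrix.
#' @return the induced adjacency over the largest component's nodes.
#' @export
largest_component <- function(net) {
  A <- unclass_network(net)
  comp <- igraph::components(as_graph(A))
  keep <- which(comp$membership == which.max(comp$csize))
  A[keep, keep, drop = FALSE]
}

# one draw from a graph null model; degree-preserving Maslov-Sneppen
# rewiring by default, Erdos-Renyi (same n, m) as the alternative
null_graph_draw <- function(g, type = c("degree_preserving", "erdos_renyi")) {
  type <- match.arg(type)
  if (type == "degree_preserving")
    igraph::rewire(g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
  else
    igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g))
}

#' Permutation z-score of modularity against a graph null
#'
#' Draws `n_perm` null graphs (degree-preserving rewirings by default, or
#' Erdos-Renyi with matched size), re-partitions each with the same
#' algorithm, and standardizes the observed Q against the null Q
#' distribution: `Z = (Q - mean(Q_rand)) / sd(Q_rand)`.
#'
#' @param net binary adjacency matrix.
#' @param n_perm number of null draws (default 10000).
#' @param null `"degree_preserving"` or `"erdos_renyi"`.
#' @param n_restarts Louvain restarts for the observed partition.
#' @param n_restarts_null Louvain restarts per null graph (default 10; the
#'   null needs the typical attainable Q, not an exhaustive search).
#' @param seed integer seed.
#' @param partition optional precomputed observed `network_partition`.
#' @return list of class `modularity_null`: `q`, `q_rand`, `mean`, `sd`,
#'   `z`, `n_perm`.
#' @export
modularity_zscore <- function(net, n_perm = 10000L,
                              null = c("degree_preserving", "erdos_renyi"),
                              n_restarts = 100L, n_restarts_null = 10L,
                              seed = 1L, partition = NULL) {
  null <- match.arg(null)
  A <- unclass_network(net)
  if (sum(A) / 2 < 2) stop("need at least 2 edges")
  if (n_perm < 2) stop("n_perm must be >= 2 (null SD undefined otherwise)")
  if (is.null(partition))
    partition <- modularity_louvain(A, n_restarts = n_restarts,
                                    seed = substream_seed(seed, "observed"))
  g <- as_graph(A)
  q_rand <- with_seed(substream_seed(seed, "nulls"), {
    vapply(seq_len(n_perm), function(i) {
      gr <- null_graph_draw(g, null)
      Ar <- as.matrix(igraph::as_adjacency_matrix(gr))
      dimnames(Ar) <- dimnames(A)
      modularity_louvain(Ar, n_restarts = n_restarts_null,
                         seed = sample.int(2^31 - 2, 1))$q
    }, numeric(1))
  })
  sdq <- stats::sd(q_rand)
  if (sdq == 0) warning("null modularity SD is 0; z-score undefined")
  structure(list(q = partition$q, q_rand = q_rand, mean = mean(q_rand),
                 sd = sdq, z = (partition$q - mean(q_rand)) / sdq,
                 n_perm = n_perm, null = null, partition = partition),
            class = "modularity_null")
}

#' @export
print.modularity_null <- function(x, ...) {
  cat(sprintf("Modularity vs %s null: Q = %.4f, Q_rand = %.4f +/- %.4f, Z = %.2f (n = %d)\n",
              x$null, x$q, x$mean, x$sd, x$z, x$n_perm))
  invisible(x)
}

#' Small-world indices against a degree-preserving null
#'
#' Computes clustering `C`, global efficiency `G` and characteristic path
#' length `L` on the network and their means over `n_rand` null draws,
#' and the small-world index `sigma = (C / C_rand) / (L / L_rand)`
#' (`sigma > 1` marks the small-world regime). `L` on disconnected null
#' draws uses finite distances only.
#'
#' @param net binary adjacency matrix (must be connected).
#' @param n_rand number of null draws (default 10000).
#' @param null null model type (see [modularity_zscore]).
#' @param seed integer seed.
#' @return list of class `small_world_result`.
#' @export
small_world <- function(net, n_rand = 10000L,
                        null = c("degree_preserving", "erdos_renyi"),
                        seed = 1L) {
  null <- match.arg(null)
  A <- unclass_network(net)
  if (any(is.infinite(distance_matrix(A))))
    stop("small-world analysis requires a connected network")
  C <- clustering_coefficient(A)$C
  G <- global_efficiency(A)
  L <- char_path_length(A)
  g <- as_graph(A)
  draws <- with_seed(substream_seed(seed, "smallworld"), {
    vapply(seq_len(n_rand), function(i) {
      Ar <- as.matrix(igraph::as_adjacency_matrix(null_graph_draw(g, null)))
      c(clustering_coefficient(Ar)$C, global_efficiency(Ar),
        char_path_length(Ar))
    }, numeric(3))
  })
  C_rand <- mean(draws[1, ]); G_rand <- mean(draws[2, ]); L_rand <- mean(draws[3, ])
  sigma <- if (C_rand > 0) (C / C_rand) / (L / L_rand) else NA_real_
  if (is.na(sigma)) warning("null clustering is 0; sigma undefined")
  structure(list(C = C, G = G, L = L, C_rand = C_rand, G_rand = G_rand,
                 L_rand = L_rand, sigma = sigma, n_rand = n_rand),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("Small-world: C = %.3f (rand %.3f), G = %.3f (rand %.3f), L = %.3f (rand %.3f), sigma = %.3f\n",
              x$C, x$C_rand, x$G, x$G_rand, x$L, x$L_rand, x$sigma))
  invisible(x)
}

#' Node-deletion impact on global efficiency
#'
#' For each node, the percentage change in global efficiency when the node
#' and its edges are removed: `100 * (G - G_minus) / G`. Disconnection
#' after removal is allowed (disconnected pairs contribute 0 efficiency).
#'
#' @param net binary adjacency matrix with at least 3 nodes.
#' @return named per-node percentage reductions (negative = removal
#'   improved efficiency).
#' @export
node_deletion_impact <- function(net) {
  A <- unclass_network(net)
  if (nrow(A) < 3) stop("need at least 3 nodes")
  G0 <- global_efficiency(A)
  impacts <- vapply(seq_len(nrow(A)), function(i)
    100 * (G0 - global_efficiency(A[-i, -i, drop = FALSE])) / G0,
    numeric(1))
  stats::setNames(impacts, node_names(A))
}

#' Standardized (z-scored) Rand similarity of two partitions
#'
#' The pair-counting Rand agreement `w` (node pairs co-assigned in both
#' partitions) standardized under the permutation (hypergeometric) null:
#' `z = (w - E[w]) / SD[w]`, with the null moments in closed form
#' (Traud-style standardized Rand coefficient).
#'
#' @param p1,p2 partitions (`network_partition` or named membership
#'   vectors) on the same node set.
#' @return the z-score; `NA` with a warning when the null variance is 0
#'   (e.g. one partition is a single module).
#' @export
zrand_similarity <- function(p1, p2) {
  m1 <- if (inherits(p1, "network_partition")) p1$membership else p1
  m2 <- if (inherits(p2, "network_partition")) p2$membership else p2
  if (!is.null(names(m1)) && !is.null(names(m2))) {
    if (!setequal(names(m1), names(m2))) stop("partitions must share a node set")
    m2 <- m2[names(m1)]
  } else if (length(m1) != length(m2)) stop("partitions must share a node set")
  n <- length(m1)
  M <- n * (n - 1) / 2
  n1 <- table(m1); n2 <- table(m2)
  M1 <- sum(choose(n1, 2)); M2 <- sum(choose(n2, 2))
  co1 <- outer(m1, m1, "==") & upper.tri(matrix(0, n, n))
  co2 <- outer(m2, m2, "==") & upper.tri(matrix(0, n, n))
  w <- sum(co1 & co2)
  C1 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M1 + 4 * sum(n1^3)
  C2 <- n * (n^2 - 3 * n - 2) - 8 * (n + 1) * M2 + 4 * sum(n2^3)
  vw <- M / 16 - (4 * M1 - 2 * M)^2 * (4 * M2 - 2 * M)^2 / (256 * M^2) +
    C1 * C2 / (16 * n * (n - 1) * (n - 2)) +
    ((4 * M1 - 2 * M)^2 - 4 * C1 - 4 * M) *
      ((4 * M2 - 2 * M)^2 - 4 * C2 - 4 * M) /
      (64 * n * (n - 1) * (n - 2) * (n - 3))
  if (vw <= 0) {
    warning("degenerate partition pair: null variance of w is 0")
    return(NA_real_)
  }
  (w - M1 * M2 / M) / sqrt(vw)
}
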