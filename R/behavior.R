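# Validation and behavioral linkage: subject weighted networks masked by
# the group template, weighted small-world metrics, signal-detection
# d-prime from 2AFC trials, and permutation-tested Spearman correlations.

#' Mask a subject's connectivity by the group binary template
#'
#' Subject weights are the absolute correlation values (|r|) wherever the
#' template has an edge, 0 elsewhere, giving a sparse weighted network
#' whose support is contained in the group topology.
#'
#' @param subject a `connectivity_matrix` (Fisher z with the raw `r` in its
#'   attribute) or a plain correlation matrix, covering the template nodes.
#' @param template the group `binary_network`.
#' @return a symmetric non-negative weight matrix of class
#'   `weighted_network`.
#' @export
mask_subject_network <- function(subject, template) {
  A <- unclass_network(template)
  nm <- node_names(A)
  r <- if (inherits(subject, "connectivity_matrix")) attr(subject, "r")
       else as.matrix(subject)
  if (!all(nm %in% node_names(r)))
    stop("subject matrix is missing template node(s): ",
         paste(setdiff(nm, node_names(r)), collapse = ", "))
  W <- abs(r[nm, nm]) * A
  diag(W) <- 0
  structure(W, class = c("weighted_network", "matrix"))
}

#' @export
print.weighted_network <- function(x, ...) {
  W <- unclass(x)
  cat(sprintf("Weighted network: %d nodes, %d edges, mean weight %.3f\n",
              nrow(W), sum(W != 0) / 2,
              if (any(W != 0)) mean(W[upper.tri(W) & W != 0]) else 0))
  invisible(x)
}

#' Weighted small-world metrics of a masked subject network
#'
#' Weighted global efficiency `G_w` (path lengths 1/weight) and weighted
#' clustering `C_w` (geometric-mean triangle form), as used to index each
#' subject's network integration and segregation.
#'
#' @param w a `weighted_network`.
#' @return list with `G_w` and `C_w`.
#' @export
weighted_small_world <- function(w) {
  W <- unclass(w)
  if (nrow(W) < 3) stop("need at least 3 nodes")
  if (all(W == 0)) stop("all-zero network")
  list(G_w = global_efficiency(W, weighted = TRUE),
       C_w = clustering_coefficient(W, weighted = TRUE)$C)
}

#' Signal-detection d-prime from 2AFC odor-discrimination trials
#'
#' Hits are `A` responses on dominantly-A (80/20) trials and false alarms
#' `A` responses on dominantly-B (20/80) trials;
#' `d' = qnorm(hit) - qnorm(fa)`. Perfect rates (0 or 1) are replaced by
#' `0.5/n` and `(n - 0.5)/n` so d-prime stays finite on short blocks.
#' Intermediate mixtures are recorded but excluded from d-prime.
#'
#' @param trials data frame with columns `mixture`, `truth`, `response`
#'   (as produced by [generate_2afc_trials]).
#' @param extreme_a,extreme_b the mixture labels treated as the
#'   dominantly-A and dominantly-B extremes.
#' @return list of class `behavior_summary`: `hit_rate`, `fa_rate`,
#'   `dprime`, and counts `n_hit`, `n_fa`, `n_a_trials`, `n_b_trials`.
#' @export
dprime <- function(trials, extreme_a = "80/20", extreme_b = "20/80") {
  stopifnot(all(c("mixture", "response") %in% names(trials)))
  a <- trials[trials$mixture == extreme_a, , drop = FALSE]
  b <- trials[trials$mixture == extreme_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("both extreme mixtures must be present")
  rate <- function(x, n) {
    r <- x / n
    if (r == 0) 0.5 / n else if (r == 1) (n - 0.5) / n else r
  }
  n_hit <- sum(a$response == "A"); n_fa <- sum(b$response == "A")
  hit <- rate(n_hit, nrow(a)); fa <- rate(n_fa, nrow(b))
  structure(list(hit_rate = hit, fa_rate = fa,
                 dprime = stats::qnorm(hit) - stats::qnorm(fa),
                 n_hit = n_hit, n_fa = n_fa,
                 n_a_trials = nrow(a), n_b_trials = nrow(b)),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("2AFC: hit %.3f (%d/%d), FA %.3f (%d/%d), d' = %.3f\n",
              x$hit_rate, x$n_hit, x$n_a_trials,
              x$fa_rate, x$n_fa, x$n_b_trials, x$dprime))
  invisible(x)
}

#' Permutation-tested Spearman correlation
#'
#' Rank correlation with significance from `n_perm` random permutations of
#' `y`. The default one-tailed test follows the 95th-percentile null
#' criterion: `p` is the exceedance probability of the observed rho under
#' the permutation null (with the +1 continuity correction).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param n_perm number of permutations (default 10000).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param seed integer seed.
#' @return list of class `correlation_test`: `rho`, `p`, `n_perm`, `seed`.
#' @export
spearman_perm <- function(x, y, n_perm = 10000L,
                          alternative = c("greater", "two.sided"),
                          seed = 1L) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho <- stats::cor(rx, ry)
  rxc <- rx - mean(rx)
  ss <- sum(rxc^2)
  perm_rho <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ryp <- ry[sample.int(n)]
      sum(rxc * (ryp - mean(ryp))) / sqrt(ss * sum((ryp - mean(ryp))^2))
    }, numeric(1))
  })
  p <- if (alternative == "greater")
    (1 + sum(perm_rho >= rho)) / (n_perm + 1)
  else
    (1 + sum(abs(perm_rho) >= abs(rho))) / (n_perm + 1)
  structure(list(rho = rho, p = p, n_perm = n_perm, seed = seed,
                 alternative = alternative),
            class = "correlation_test")
}

#' @export
print.correlation_test <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, permutation p = %.4g (%d permutations, %s)\n",
              x$rho, x$p, x$n_perm, x$alternative))
  invisible(x)
}

#' Concordance of two connectivity matrices over an edge set
#'
#' Spearman correlation (permutation-tested) of the unique off-diagonal
#' entries of two matrices, by default restricted to the edges of the
#' group template. The Pearson correlation over the same entries is
#' reported alongside.
#'
#' @param a,b connectivity (or plain numeric) matrices on a shared node
#'   set.
#' @param edge_set optional `binary_network` selecting entries; `NULL`
#'   uses all unique off-diagonal pairs.
#' @param n_perm,seed permutation test parameters.
#' @return a `correlation_test` with an extra `pearson_r` element.
#' @export
matrix_concordance <- function(a, b, edge_set = NULL, n_perm = 10000L,
                               seed = 1L) {
  am <- unclass(a); bm <- unclass(b)
  nm <- node_names(am)
  if (!setequal(nm, node_names(bm))) stop("matrices must share node names")
  bm <- bm[nm, nm]
  sel <- upper.tri(am)
  if (!is.null(edge_set)) {
    E <- unclass_network(edge_set)[nm, nm]
    sel <- sel & (E != 0)
    if (!any(sel)) stop("edge set selects no entries")
  }
  out <- spearman_perm(am[sel], bm[sel], n_perm = n_perm, seed = seed)
  out$pearson_r <- stats::cor(am[sel], bm[sel])
  out$n_entries <- sum(sel)
  out
}

#' Subject-level modularity consistency across a cohort
#'
#' Partitions each subject's weighted network with Louvain, measures the
#' z-Rand similarity of each subject partition to the group partition and
#' between all subject pairs, and compares the observed subject-to-group
#' similarities against a permuted-node-label null with a two-sample
#' t-test.
#'
#' @param subject_networks list of `weighted_network` objects on a shared
#'   node set.
#' @param group_partition the group `network_partition`.
#' @param n_restarts Louvain restarts per subject.
#' @param n_null_per_subject label permutations per subject for the null.
#' @param seed integer seed.
#' @return list: `partitions`, `zrand_to_group`, `zrand_pairwise` (vector),
#'   `mean_to_group`, `mean_pairwise`, `null_mean`, `p_vs_null`,
#'   `module_counts`.
#' @export
cohort_modularity_consistency <- function(subject_networks, group_partition,
                                          n_restarts = 100L,
                                          n_null_per_subject = 20L,
                                          seed = 1L) {
  if (length(subject_networks) < 2) stop("need at least 2 subjects")
  parts <- lapply(seq_along(subject_networks), function(s)
    modularity_louvain(subject_networks[[s]], n_restarts = n_restarts,
                       seed = substream_seed(seed, paste0("subject", s)),
                       weighted = TRUE))
  degenerate <- vapply(parts, function(p) p$n_modules < 2, logical(1))
  if (any(degenerate))
    warning(sum(degenerate), " subject(s) yielded a single-module partition")
  zg <- vapply(parts, function(p)
    suppressWarnings(zrand_similarity(p, group_partition)), numeric(1))
  np <- length(parts)
  zp <- c()
  if (np > 1)
    for (i in seq_len(np - 1)) for (j in (i + 1):np)
      zp <- c(zp, suppressWarnings(zrand_similarity(parts[[i]], parts[[j]])))
  null_z <- with_seed(substream_seed(seed, "labelnull"), {
    unlist(lapply(parts, function(p) {
      vapply(seq_len(n_null_per_subject), function(i) {
        perm <- p$membership[sample.int(length(p$membership))]
        names(perm) <- names(p$membership)
        suppressWarnings(zrand_similarity(perm, group_partition))
      }, numeric(1))
    }))
  })
  tt <- stats::t.test(zg[!is.na(zg)], null_z[!is.na(null_z)],
                      alternative = "greater")
  list(partitions = parts,
       zrand_to_group = zg, zrand_pairwise = zp,
       mean_to_group = mean(zg, na.rm = TRUE),
       mean_pairwise = mean(zp, na.rm = TRUE),
       null_mean = mean(null_z, na.rm = TRUE),
       p_vs_null = tt$p.value,
       module_counts = vapply(parts, function(p) p$n_modules, numeric(1)))
}
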