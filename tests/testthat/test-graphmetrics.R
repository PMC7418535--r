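# Graph metrics against closed forms and brute-force oracles, null-model
# contracts, and partition similarity.

test_that("clustering coefficient: closed-form cases and reduction to binary", {
  expect_equal(clustering_coefficient(complete_graph(3))$C, 1)
  expect_equal(clustering_coefficient(star_graph(5))$C, 0)
  A <- rand_graph(7, 0.5, seed = 101)
  expect_equal(clustering_coefficient(A)$C, oracle_clustering(A)$C,
               tolerance = 1e-12)
  # all-ones weights reduce to the binary value
  expect_equal(clustering_coefficient(A, weighted = TRUE)$C,
               clustering_coefficient(A)$C, tolerance = 1e-12)
  # Onnela form: uniform weight w rescales local clustering by (w/max)^... = 1
  expect_equal(clustering_coefficient(A * 0.4, weighted = TRUE)$C,
               clustering_coefficient(A)$C, tolerance = 1e-12)
})

test_that("global efficiency: closed forms, disconnection, weighted lengths", {
  expect_equal(global_efficiency(complete_graph(6)), 1)
  path3 <- adj_from_edges(3, list(c("a", "b"), c("b", "c")))
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  # disconnected pair contributes zero
  iso <- adj_from_edges(3, list(c("a", "b")))
  expect_equal(global_efficiency(iso), (1 + 0 + 0) / 3, tolerance = 1e-12)
  # doubling all weights doubles weighted efficiency (lengths are 1/w)
  A <- rand_graph(6, 0.6, seed = 5, connected = TRUE)
  expect_equal(global_efficiency(A * 2, weighted = TRUE),
               2 * global_efficiency(A, weighted = TRUE), tolerance = 1e-12)
  expect_error(global_efficiency(-A), "negative")
})

test_that("centralities match closed forms on the 5-node star", {
  A <- star_graph(5)
  m <- centralities(A)
  expect_equal(m$betweenness[1], 1)
  expect_equal(m$closeness[1], 1)
  expect_equal(m$betweenness[2:5], rep(0, 4))
  expect_equal(m$closeness[2], 4 / 7, tolerance = 1e-12)  # distances 1,2,2,2
  expect_equal(m$degree, c(4, 1, 1, 1, 1))
})

test_that("composite hubness aggregates z-scores and ranks as defined", {
  A <- star_graph(6)
  h <- composite_hubness(centralities(A))
  expect_equal(which.min(h$composite_rank), 1)
  expect_equal(h$composite_rank[1], 1)
  expect_equal(mean(h$composite_z), 0, tolerance = 1e-12)
  # identical nodes: all-zero composite with a warning per degenerate metric
  w <- testthat::capture_warnings(
    h0 <- composite_hubness(centralities(complete_graph(5))))
  expect_true(all(grepl("zero variance", w)))
  expect_equal(h0$composite_z, rep(0, 5))
})

test_that("participation coefficient follows 1 - sum((k_is/k_i)^2)", {
  # all edges within own module
  A <- two_cliques(4)
  mem <- stats::setNames(rep(c(1, 2), each = 4), rownames(A))
  expect_equal(unname(participation_coefficient(A, mem)), rep(0, 8))
  # degree 4 split 2/2 across two modules
  A2 <- adj_from_edges(5, list(c("a", "b"), c("a", "c"), c("a", "d"), c("a", "e")))
  mem2 <- c(a = 1, b = 1, c = 1, d = 2, e = 2)
  expect_equal(participation_coefficient(A2, mem2)[["a"]], 0.5)
  # degree 3 split across three modules
  A3 <- adj_from_edges(4, list(c("a", "b"), c("a", "c"), c("a", "d")))
  mem3 <- c(a = 1, b = 1, c = 2, d = 3)
  expect_equal(participation_coefficient(A3, mem3)[["a"]], 1 - 3 * (1 / 9),
               tolerance = 1e-12)
  # isolated node scores zero
  A4 <- adj_from_edges(3, list(c("a", "b")))
  expect_equal(participation_coefficient(A4, c(a = 1, b = 1, c = 2))[["c"]], 0)
})

test_that("Louvain finds the planted split of disconnected cliques with Q = 0.5", {
  A <- two_cliques(4)
  p <- modularity_louvain(A, n_restarts = 20, seed = 1)
  expect_equal(p$n_modules, 2)
  expect_equal(p$q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(p$membership[1:4])), 1)
  expect_equal(length(unique(p$membership[5:8])), 1)
  # complete graph: no partition beats the trivial one (Q = 0)
  pc <- modularity_louvain(complete_graph(6), n_restarts = 20, seed = 2)
  expect_equal(pc$q, 0, tolerance = 1e-12)
  expect_error(modularity_louvain(matrix(0, 3, 3,
                                         dimnames = list(letters[1:3], letters[1:3]))),
               "no edges")
})

test_that("reported Q always equals the independent modularity formula", {
  for (s in 1:5) {
    A <- rand_graph(7, 0.5, seed = 200 + s)
    if (sum(A) == 0) next
    p <- modularity_louvain(A, n_restarts = 10, seed = s)
    expect_equal(p$q, oracle_modularity(A, p$membership), tolerance = 1e-12)
    expect_equal(p$q, igraph::modularity(igraph::graph_from_adjacency_matrix(
      A, mode = "undirected"), p$membership), tolerance = 1e-12)
  }
})

test_that("Louvain restarts are seed-deterministic", {
  A <- rand_graph(16, 0.3, seed = 9)
  p1 <- modularity_louvain(A, n_restarts = 25, seed = 4)
  p2 <- modularity_louvain(A, n_restarts = 25, seed = 4)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$q, p2$q)
})

test_that("Girvan-Newman removes the bridge and agrees with Louvain", {
  A <- two_cliques(4, bridge = TRUE)
  p <- modularity_girvan_newman(A)
  expect_equal(p$n_modules, 2)
  expect_equal(length(unique(p$membership[1:4])), 1)
  expect_equal(p$q, oracle_modularity(A, p$membership), tolerance = 1e-12)
  # tree input terminates and returns the max-Q level
  tree <- adj_from_edges(6, list(c("a", "b"), c("a", "c"), c("b", "d"),
                                 c("b", "e"), c("c", "f")))
  expect_s3_class(modularity_girvan_newman(tree), "network_partition")
  # agreement with Louvain on planted modular structure
  spec <- hub_scenario_spec(seed = 55)
  z <- correlation_matrix(generate_modular_timeseries(spec))
  net <- threshold_proportional(z, 0.4)
  q_l <- modularity_louvain(net, n_restarts = 50, seed = 3)$q
  q_gn <- modularity_girvan_newman(net)$q
  expect_lt(abs(q_l - q_gn), 0.05)
})

test_that("degree-preserving nulls preserve the degree sequence exactly", {
  A <- rand_graph(15, 0.3, seed = 21)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  set.seed(1)
  for (i in 1:20) {
    gr <- olfnet:::null_graph_draw(g, "degree_preserving")
    expect_identical(igraph::degree(gr), igraph::degree(g))
  }
  ger <- olfnet:::null_graph_draw(g, "erdos_renyi")
  expect_equal(igraph::ecount(ger), igraph::ecount(g))
})

test_that("modularity z-score flags planted structure and rejects degenerate input", {
  A <- two_cliques(6, bridge = TRUE)
  mz <- modularity_zscore(A, n_perm = 60, n_restarts = 30,
                          n_restarts_null = 5, seed = 8)
  expect_gt(mz$z, 3)
  expect_equal(mz$q, modularity_louvain(A, 30,
                                        seed = substream_seed(8, "observed"))$q)
  expect_error(modularity_zscore(A, n_perm = 1), "n_perm")
  # deterministic given the seed
  mz2 <- modularity_zscore(A, n_perm = 60, n_restarts = 30,
                           n_restarts_null = 5, seed = 8)
  expect_identical(mz$z, mz2$z)
})

test_that("small-world indices: complete graph gives sigma = 1 exactly", {
  sw <- small_world(complete_graph(8), n_rand = 5, seed = 1)
  expect_equal(sw$C, 1); expect_equal(sw$C_rand, 1)
  expect_equal(sw$L, 1); expect_equal(sw$L_rand, 1)
  expect_equal(sw$G, 1)
  expect_equal(sw$sigma, 1)
  disc <- two_cliques(4)
  expect_error(small_world(disc), "connected")
})

test_that("node deletion impact: complete graph null case and star collapse", {
  expect_equal(unname(node_deletion_impact(complete_graph(6))), rep(0, 6))
  st <- star_graph(6)
  di <- node_deletion_impact(st)
  expect_equal(unname(di[1]), 100)   # removing the center leaves no edges
  expect_lt(max(di[-1]), 100)
})

test_that("hubs planted in the generator top both centrality and deletion impact", {
  spec <- hub_scenario_spec(seed = 77)
  z <- correlation_matrix(generate_modular_timeseries(spec))
  A <- threshold_proportional(z, 0.4)
  h <- composite_hubness(centralities(A))
  top2 <- h$node[order(h$composite_rank)][1:2]
  expect_setequal(top2, c("N01", "N08"))
  di <- sort(node_deletion_impact(A), decreasing = TRUE)
  expect_setequal(names(di)[1:2], c("N01", "N08"))
  # and they are connector hubs by participation
  p <- modularity_louvain(A, n_restarts = 50, seed = 1)
  part <- participation_coefficient(A, p)
  expect_gt(part[["N01"]], 0.3)
  expect_gt(part[["N08"]], 0.3)
})

test_that("z-Rand matches the exhaustive permutation moments on 6 nodes", {
  set.seed(61)
  for (i in 1:10) {
    m1 <- sample(1:3, 6, replace = TRUE)
    m2 <- sample(1:3, 6, replace = TRUE)
    if (length(unique(m1)) == 1 || length(unique(m2)) == 1) next
    zo <- oracle_zrand(m1, m2)
    if (is.na(zo)) next
    expect_equal(suppressWarnings(zrand_similarity(m1, m2)), zo,
                 tolerance = 1e-10)
  }
})

test_that("z-Rand is positive for identical nontrivial partitions, ~0 for random ones", {
  mem <- stats::setNames(rep(1:3, c(8, 7, 7)), sprintf("n%02d", 1:22))
  expect_gt(zrand_similarity(mem, mem), 3)
  set.seed(19)
  zs <- replicate(300, {
    a <- sample(1:3, 22, replace = TRUE); b <- sample(1:3, 22, replace = TRUE)
    suppressWarnings(zrand_similarity(a, b))
  })
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.15)
  # degenerate single-module case is flagged
  expect_warning(z1 <- zrand_similarity(rep(1, 6), c(1, 1, 2, 2, 3, 3)),
                 "degenerate")
  expect_true(is.na(z1))
})

test_that("weighted metrics use 1/weight path lengths and Onnela triangles", {
  W <- adj_from_edges(3, list(c("a", "b"), c("b", "c")))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["b", "c"] <- W["c", "b"] <- 0.25
  # d(a,c) = 1/0.5 + 1/0.25 = 6 -> efficiency mean of 1/2, 1/6, 1/4... pairs:
  # (a,b): 1/2, (b,c): 1/4, (a,c): 1/6
  expect_equal(global_efficiency(W, weighted = TRUE),
               mean(c(1 / 2, 1 / 4, 1 / 6)), tolerance = 1e-12)
  # triangle with weights: Onnela local clustering via geometric mean
  Tri <- complete_graph(3)
  Tri["a", "b"] <- Tri["b", "a"] <- 0.8
  Tri["a", "c"] <- Tri["c", "a"] <- 0.2
  Tri["b", "c"] <- Tri["c", "b"] <- 0.4
  wmax <- 0.8
  gm <- ((0.8 / wmax) * (0.2 / wmax) * (0.4 / wmax))^(1 / 3)
  expect_equal(clustering_coefficient(Tri, weighted = TRUE)$C, gm,
               tolerance = 1e-12)
})
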