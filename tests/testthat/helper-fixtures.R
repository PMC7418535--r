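# Small graph builders and planted-scenario shortcuts shared across tests.

adj_from_edges <- function(n, edges, names = letters[seq_len(n)]) {
  A <- matrix(0, n, n, dimnames = list(names, names))
  for (e in edges) { A[e[1], e[2]] <- 1; A[e[2], e[1]] <- 1 }
  A
}

complete_graph <- function(n, names = letters[seq_len(n)]) {
  A <- matrix(1, n, n, dimnames = list(names, names))
  diag(A) <- 0
  A
}

star_graph <- function(n) {
  adj_from_edges(n, lapply(2:n, function(i) c(1, i)))
}

# two disconnected m-cliques (named a1.., b1..)
two_cliques <- function(m, bridge = FALSE) {
  nm <- c(paste0("a", seq_len(m)), paste0("b", seq_len(m)))
  A <- matrix(0, 2 * m, 2 * m, dimnames = list(nm, nm))
  A[seq_len(m), seq_len(m)] <- 1
  A[m + seq_len(m), m + seq_len(m)] <- 1
  diag(A) <- 0
  if (bridge) { A[1, m + 1] <- 1; A[m + 1, 1] <- 1 }
  A
}

# planted 21-node hub scenario: three 7-node modules, hubs N01 (m1), N08 (m2)
hub_scenario_spec <- function(seed) {
  mods <- stats::setNames(rep(c("m1", "m2", "m3"), each = 7),
                          sprintf("N%02d", 1:21))
  ground_truth_spec(modules = mods, hub_nodes = c("N01", "N08"),
                    isolated_modules = character(0),
                    n_runs = 4, scans_per_run = 1200, seed = seed)
}

# connectivity matrix wrapper around a plain z matrix (for unit tests)
as_connectivity <- function(z, r = tanh(z)) {
  structure(z, class = c("connectivity_matrix", "matrix"), r = r,
            level = "group")
}
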