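# Brute-force oracles, independent of the package's implementation (and of
# igraph): exhaustive path enumeration, direct triangle counting, the
# modularity double sum, and permutation-enumeration z-Rand moments.
# Only usable on small graphs; that is the point.

rand_graph <- function(n, p = 0.5, seed = 1, connected = FALSE) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    dimnames(A) <- list(letters[seq_len(n)], letters[seq_len(n)])
    if (!connected) return(A)
    if (all(is.finite(oracle_distances(A)))) return(A)
  }
}

# Floyd-Warshall all-pairs shortest path lengths
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_efficiency <- function(A) {
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- NA
  inv[is.infinite(D)] <- 0
  mean(inv, na.rm = TRUE)
}

oracle_closeness <- function(A) {
  D <- oracle_distances(A)
  diag(D) <- NA
  apply(D, 1, function(d) {
    d <- d[!is.na(d) & is.finite(d)]
    if (length(d) == 0) 0 else 1 / mean(d)
  })
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    t <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (A[nb[a], nb[b]] > 0) t <- t + 1
    local[i] <- t / (k * (k - 1) / 2)
  }
  list(local = local, C = mean(local))
}

# all simple paths i -> j by depth-first enumeration
all_simple_paths_bf <- function(A, i, j) {
  paths <- list()
  walk <- function(v, seen, path) {
    if (v == j) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (w in which(A[v, ] > 0)) if (!seen[w]) {
      seen2 <- seen; seen2[w] <- TRUE
      walk(w, seen2, c(path, w))
    }
  }
  seen <- rep(FALSE, nrow(A)); seen[i] <- TRUE
  walk(i, seen, i)
  paths
}

# normalized betweenness by exhaustive shortest-path enumeration
oracle_betweenness <- function(A) {
  n <- nrow(A)
  bc <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- all_simple_paths_bf(A, i, j)
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    sp <- paths[lens == min(lens)]
    for (p in sp) for (v in setdiff(p, c(i, j)))
      bc[v] <- bc[v] + 1 / length(sp)
  }
  bc / ((n - 1) * (n - 2) / 2)
}

oracle_modularity <- function(A, mem) {
  n <- nrow(A)
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (mem[i] == mem[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  as.numeric(q) / m2
}

oracle_participation <- function(A, mem) {
  n <- nrow(A)
  P <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(A[i, ])
    if (k == 0) next
    s <- 0
    for (mod in unique(mem)) s <- s + (sum(A[i, mem == mod]) / k)^2
    P[i] <- 1 - s
  }
  P
}

# z-Rand by exhaustive enumeration of all label permutations (n <= 7)
all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_permutations(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

oracle_zrand <- function(m1, m2) {
  n <- length(m1)
  w_of <- function(a, b) {
    w <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (a[i] == a[j] && b[i] == b[j]) w <- w + 1
    w
  }
  w <- w_of(m1, m2)
  ws <- vapply(all_permutations(seq_len(n)),
               function(p) w_of(m1[p], m2), numeric(1))
  mu <- mean(ws)
  sd_pop <- sqrt(mean((ws - mu)^2))
  if (sd_pop == 0) return(NA_real_)
  (w - mu) / sd_pop
}
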