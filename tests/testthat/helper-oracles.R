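# Brute-force oracles, independent of the package's implementation paths:
# exhaustive simple-path enumeration for shortest paths and betweenness,
# direct triangle enumeration for clustering, recursive DFS for connected
# components, and direct formula evaluation for modularity.

# random symmetric weighted graph on n nodes
rand_graph <- function(n, seed, p = 0.4) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  present <- stats::runif(sum(ut)) < p
  w <- stats::runif(sum(ut), 0.1, 1)
  W[ut] <- ifelse(present, w, 0)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

# all simple paths s -> t as lists of (nodes, length); lengths use 1/w
enum_paths <- function(W, s, t) {
  n <- nrow(W)
  L <- 1 / W
  paths <- list()
  rec <- function(v, visited, nodes, len) {
    for (u in seq_len(n)) {
      if (W[v, u] > 0 && !visited[u]) {
        if (u == t) {
          paths[[length(paths) + 1L]] <<- list(nodes = c(nodes, u),
                                               len = len + L[v, u])
        } else {
          visited[u] <- TRUE
          rec(u, visited, c(nodes, u), len + L[v, u])
          visited[u] <- FALSE
        }
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited, s, 0)
  paths
}

# shortest-path distance matrix by exhaustive enumeration
bf_dists <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      ps <- enum_paths(W, s, t)
      if (length(ps)) D[s, t] <- D[t, s] <- min(vapply(ps, `[[`, numeric(1), "len"))
    }
  }
  D
}

bf_global_efficiency <- function(W) {
  n <- nrow(W)
  if (n < 2L) return(0)
  D <- bf_dists(W)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_local_efficiency <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(W[v, ] > 0)
    if (length(nb) >= 2L) out[v] <- bf_global_efficiency(W[nb, nb, drop = FALSE])
  }
  out
}

# betweenness percentage by enumerating all minimal paths per pair
bf_betweenness_pct <- function(W, tol = 1e-9) {
  n <- nrow(W)
  B <- numeric(n)
  for (s in seq_len(n - 1L)) {
    for (t in seq.int(s + 1L, n)) {
      ps <- enum_paths(W, s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      mins <- which(lens <= min(lens) + tol)
      sigma <- length(mins)
      for (k in mins) {
        interior <- setdiff(ps[[k]]$nodes, c(s, t))
        B[interior] <- B[interior] + 1 / sigma
      }
    }
  }
  100 * B / ((n - 1) * (n - 2) / 2)
}

# Onnela weighted clustering by direct triple loop
bf_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(numeric(n))
  Wh <- W / mx
  C <- numeric(n)
  for (v in seq_len(n)) {
    k <- sum(W[v, ] > 0)
    if (k < 2) next
    acc <- 0
    for (u in seq_len(n)) {
      for (w in seq_len(n)) {
        if (u != v && w != v && u != w)
          acc <- acc + (Wh[v, u] * Wh[u, w] * Wh[w, v])^(1 / 3)
      }
    }
    C[v] <- acc / (k * (k - 1))
  }
  C
}

# connected components of an edge list by recursive DFS; returns the sorted
# edge counts of the components
bf_component_sizes <- function(ei, ej) {
  nodes <- sort(unique(c(ei, ej)))
  adj <- lapply(nodes, function(v) integer(0))
  names(adj) <- as.character(nodes)
  for (k in seq_along(ei)) {
    adj[[as.character(ei[k])]] <- c(adj[[as.character(ei[k])]], ej[k])
    adj[[as.character(ej[k])]] <- c(adj[[as.character(ej[k])]], ei[k])
  }
  comp <- stats::setNames(rep(0L, length(nodes)), as.character(nodes))
  cid <- 0L
  dfs <- function(v) {
    comp[[as.character(v)]] <<- cid
    for (u in adj[[as.character(v)]])
      if (comp[[as.character(u)]] == 0L) dfs(u)
  }
  for (v in nodes) {
    if (comp[[as.character(v)]] == 0L) {
      cid <- cid + 1L
      dfs(v)
    }
  }
  edge_comp <- comp[as.character(ei)]
  sort(as.integer(table(edge_comp)), decreasing = TRUE)
}

# direct modularity formula evaluation (duplicate of the definition, written
# as an explicit double loop)
bf_modularity <- function(W, memb, gamma = 1) {
  m2 <- sum(W)
  if (m2 == 0) return(0)
  k <- rowSums(W)
  q <- 0
  n <- nrow(W)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (memb[i] == memb[j]) q <- q + W[i, j] - gamma * k[i] * k[j] / m2
  q / m2
}

# default-condition cohorts shared by the heavier directional tests
make_default_cohorts <- function(seed = 42L, n_subjects = 10L) {
  cfg <- cohort_config(n_subjects = n_subjects, rng_seed = seed)
  conds <- c("normal_cc", "complete_ccd", "partial_ccd", "virtual_callosotomy")
  stats::setNames(lapply(conds, generate_cohort, config = cfg), conds)
}
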