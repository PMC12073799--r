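# Louvain community detection with resolution parameter, consensus
# partitions, participation coefficients and hub classification.

#' Weighted modularity with resolution parameter
#'
#' Direct evaluation of
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[ w_{ij} - \gamma \frac{k_i k_j}{2m}
#'   \right] \delta(c_i, c_j)}
#' for a given node-to-module assignment.
#'
#' @param W Weight matrix (or consensus object).
#' @param membership Integer vector of module ids, one per node.
#' @param gamma Resolution parameter (1 = classic Newman-Girvan).
#' @return Scalar Q.
#' @export
modularity_q <- function(W, membership, gamma = 1) {
  W <- .as_weights(W)
  m2 <- sum(W)              # 2m for undirected W
  if (m2 == 0) return(0)
  k <- rowSums(W)
  same <- outer(membership, membership, `==`)
  sum((W - gamma * outer(k, k) / m2) * same) / m2
}

#' Louvain community detection
#'
#' Greedy modularity maximization at resolution \code{gamma}, with
#' \code{restarts} runs over seed-shuffled node orders; the partition with
#' the best modularity is returned. Deterministic given \code{seed}.
#'
#' @param W Weight matrix (or consensus object).
#' @param gamma Resolution parameter (default 1.2, the value optimized for
#'   modularity on normal-CC consensus networks).
#' @param seed Integer RNG seed.
#' @param restarts Number of restarts (default 20).
#' @return List of class \code{ccd_partition}: \code{membership} (integer
#'   module ids starting at 1, named by node), \code{q}, \code{gamma},
#'   \code{seed}, \code{n_modules}.
#' @export
louvain <- function(W, gamma = 1.2, seed = 1L, restarts = 20L) {
  W <- .as_weights(W)
  n <- nrow(W)
  if (n == 0L) stop("empty graph")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  best <- NULL; best_q <- -Inf
  for (r in seq_len(restarts)) {
    perm <- sample.int(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp, resolution = gamma)
    # vertex i of the input becomes vertex perm[i] of the permuted graph
    memb <- as.integer(igraph::membership(cl))[perm]
    q <- modularity_q(W, memb, gamma)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  memb <- match(best, unique(best))   # contiguous ids, stable order
  structure(list(membership = stats::setNames(memb, rownames(W)),
                 q = best_q, gamma = gamma, seed = seed,
                 n_modules = length(unique(memb))),
            class = "ccd_partition")
}

#' Consensus partition over repeated runs or subjects
#'
#' Builds the node-by-node co-assignment matrix (fraction of input
#' partitions assigning two nodes to the same module) and iteratively applies
#' Louvain to it until all runs agree, yielding a stable consensus grouping
#' that is invariant to module relabeling of the inputs.
#'
#' @param partitions List of \code{ccd_partition} objects or membership
#'   vectors over the same nodes.
#' @param gamma Resolution used on the co-assignment matrix (default 1).
#' @param seed Integer RNG seed.
#' @param max_iter Maximum consensus iterations.
#' @return A \code{ccd_partition}.
#' @export
consensus_partition <- function(partitions, gamma = 1, seed = 1L,
                                max_iter = 20L) {
  membs <- lapply(partitions, function(p)
    if (inherits(p, "ccd_partition")) p$membership else p)
  n <- length(membs[[1L]])
  labels <- names(membs[[1L]])
  co <- matrix(0, n, n)
  for (m in membs) co <- co + outer(m, m, `==`)
  co <- co / length(membs)
  diag(co) <- 0
  dimnames(co) <- list(labels, labels)

  for (it in seq_len(max_iter)) {
    runs <- lapply(seq_len(5L), function(r)
      louvain(co, gamma = gamma, seed = seed + r + it * 101L, restarts = 4L)$membership)
    agree <- all(vapply(runs[-1L], function(m)
      all(outer(m, m, `==`) == outer(runs[[1L]], runs[[1L]], `==`)), logical(1)))
    if (agree) {
      memb <- match(runs[[1L]], unique(runs[[1L]]))
      return(structure(list(membership = stats::setNames(memb, labels),
                            q = NA_real_, gamma = gamma, seed = seed,
                            n_modules = length(unique(memb))),
                       class = "ccd_partition"))
    }
    co2 <- matrix(0, n, n)
    for (m in runs) co2 <- co2 + outer(m, m, `==`)
    co <- co2 / length(runs)
    diag(co) <- 0
  }
  warning("consensus did not stabilize; returning last partition")
  memb <- match(runs[[1L]], unique(runs[[1L]]))
  structure(list(membership = stats::setNames(memb, labels), q = NA_real_,
                 gamma = gamma, seed = seed,
                 n_modules = length(unique(memb))),
            class = "ccd_partition")
}

#' Participation coefficient
#'
#' Guimera-Amaral participation of each node given a module partition:
#' \deqn{P_v = 1 - \sum_m \left( \frac{s_{vm}}{s_v} \right)^2}
#' where \eqn{s_{vm}} is the strength of node v's edges into module m and
#' \eqn{s_v} its total strength. Nodes with zero strength have P = 0.
#'
#' @param W Weight matrix (or consensus object).
#' @param partition A \code{ccd_partition} or membership vector.
#' @return Named numeric vector in [0, 1 - 1/M].
#' @export
participation <- function(W, partition) {
  W <- .as_weights(W)
  memb <- if (inherits(partition, "ccd_partition")) partition$membership else partition
  s <- rowSums(W)
  mods <- sort(unique(memb))
  frac2 <- matrix(0, nrow(W), length(mods))
  for (mi in seq_along(mods)) {
    sm <- rowSums(W[, memb == mods[mi], drop = FALSE])
    frac2[, mi] <- ifelse(s > 0, (sm / s)^2, 0)
  }
  P <- ifelse(s > 0, 1 - rowSums(frac2), 0)
  stats::setNames(P, rownames(W))
}

#' Build a hub table for a network
#'
#' @param W Weight matrix (or consensus object).
#' @param partition A \code{ccd_partition} or membership vector.
#' @return Data frame: node, strength, degree, module, participation.
#' @export
hub_table <- function(W, partition) {
  W <- .as_weights(W)
  memb <- if (inherits(partition, "ccd_partition")) partition$membership else partition
  data.frame(node = rownames(W) %||% as.character(seq_len(nrow(W))),
             strength = unname(rowSums(W)),
             degree = unname(rowSums(W > 0)),
             module = unname(memb),
             participation = unname(participation(W, memb)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify hubs as connector or provincial
#'
#' Nodes at or above the \code{degree_quantile} of strength are hubs;
#' among hubs, participation at or above \code{participation_cut} marks a
#' connector hub (inter-module), below it a provincial hub (within-module).
#'
#' @param tbl Hub table from [hub_table()].
#' @param degree_quantile Strength quantile defining hubs (default 0.8).
#' @param participation_cut Participation split (default 0.5).
#' @return The hub table with an added \code{hub_class} column in
#'   \code{c("connector", "provincial", "non-hub")}.
#' @export
classify_hubs <- function(tbl, degree_quantile = 0.8, participation_cut = 0.5) {
  cut_s <- stats::quantile(tbl$strength, degree_quantile, names = FALSE)
  is_hub <- tbl$strength >= cut_s
  tbl$hub_class <- ifelse(!is_hub, "non-hub",
                          ifelse(tbl$participation >= participation_cut,
                                 "connector", "provincial"))
  tbl
}

#' Correlation between nodal degree and participation
#'
#' Pearson correlation, across nodes, of strength against participation
#' coefficient, with a two-sided p-value. A positive r indicates that
#' high-degree nodes are also inter-module connectors.
#'
#' @param tbl Hub table from [hub_table()].
#' @return List with \code{r} and \code{p} (both NA when either variable has
#'   zero variance).
#' @export
degree_participation_correlation <- function(tbl) {
  x <- tbl$strength; y <- tbl$participation
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Sweep the Louvain resolution parameter
#'
#' Utility for the gamma-optimization step: evaluates the mean best-run
#' modularity over a set of networks for each candidate gamma.
#'
#' @param mats List of weight matrices (e.g. a cohort's subjects).
#' @param gammas Candidate resolutions.
#' @param seed,restarts Passed to [louvain()].
#' @return Data frame: gamma, mean_q.
#' @export
gamma_sweep <- function(mats, gammas = seq(0.8, 1.6, by = 0.1), seed = 1L,
                        restarts = 5L) {
  mq <- vapply(gammas, function(g)
    mean(vapply(mats, function(W) louvain(W, g, seed, restarts)$q, numeric(1))),
    numeric(1))
  data.frame(gamma = gammas, mean_q = mq)
}

#' @export
print.ccd_partition <- function(x, ...) {
  cat("Network partition:", x$n_modules, "modules, gamma =", x$gamma)
  if (!is.na(x$q)) cat(sprintf(", Q = %.4f", x$q))
  cat("\n")
  print(table(module = x$membership))
  invisible(x)
}
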