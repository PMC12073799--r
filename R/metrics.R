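# Weighted graph metrics over proportional sparsity thresholds, AUC
# summarization, and AUC group comparisons.
#
# Conventions for FA-weighted connectomes: path length of an edge is the
# reciprocal of its weight (configurable to -log(w)); global efficiency uses
# the harmonic form (mean of 1/d over pairs) so disconnected graphs stay
# finite; clustering is the Onnela weighted variant; betweenness is expressed
# as the percentage of shortest paths through a node.

#' Analysis configuration
#'
#' Defaults follow the study design this package models: proportional
#' sparsity thresholds 0.05 to 0.13 in steps of 0.01, Louvain resolution
#' gamma = 1.2, NBS with 5000 permutations over primary thresholds 2 to 5,
#' consensus fraction one half, novelty minimum carrier count 2, alpha 0.05.
#'
#' @param sparsity_min,sparsity_max,sparsity_step Sparsity grid.
#' @param gamma Louvain resolution parameter.
#' @param nbs_permutations,nbs_thresholds NBS permutation count and primary
#'   t-statistic thresholds.
#' @param consensus_fraction Minimum fraction of subjects for consensus edges.
#' @param novelty_min_count Minimum case carrier count for a novel edge.
#' @param alpha Significance level.
#' @param path_transform Edge length for shortest paths: \code{"inverse"}
#'   (1/w) or \code{"neglog"} (-log w).
#' @return List of class \code{ccd_analysis_config}.
#' @export
analysis_config <- function(sparsity_min = 0.05, sparsity_max = 0.13,
                            sparsity_step = 0.01, gamma = 1.2,
                            nbs_permutations = 5000L, nbs_thresholds = 2:5,
                            consensus_fraction = 0.5, novelty_min_count = 2L,
                            alpha = 0.05, path_transform = c("inverse", "neglog")) {
  stopifnot(sparsity_min > 0, sparsity_min <= sparsity_max, sparsity_max < 1,
            sparsity_step > 0)
  structure(list(
    sparsity_min = sparsity_min, sparsity_max = sparsity_max,
    sparsity_step = sparsity_step,
    sparsity_grid = seq(sparsity_min, sparsity_max, by = sparsity_step),
    gamma = gamma, nbs_permutations = as.integer(nbs_permutations),
    nbs_thresholds = nbs_thresholds,
    consensus_fraction = consensus_fraction,
    novelty_min_count = as.integer(novelty_min_count), alpha = alpha,
    path_transform = match.arg(path_transform)
  ), class = "ccd_analysis_config")
}

.as_weights <- function(x) {
  if (inherits(x, "ccd_consensus")) x$weights else x
}

.edge_lengths <- function(W, path_transform = "inverse") {
  L <- switch(path_transform,
              inverse = 1 / W,
              neglog = -log(W),
              stop("unknown path transform"))
  L[W <= 0] <- Inf
  diag(L) <- 0
  L
}

# all-pairs shortest path distances by vectorized Floyd-Warshall
.shortest_dists <- function(W, path_transform = "inverse") {
  D <- .edge_lengths(W, path_transform)
  n <- nrow(D)
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, via)
  }
  D
}

#' Proportional sparsity thresholding
#'
#' Keeps the \code{k = round(s * n * (n - 1) / 2)} strongest edges (round
#' half to even) and zeroes the rest, so networks compared at sparsity
#' \code{s} share the same density. Ties at the cutoff weight are broken by
#' stable node-index order. If fewer than \code{k} edges are present the
#' matrix is returned unchanged with a warning.
#'
#' @param W Weight matrix (or consensus object).
#' @param s Sparsity in (0, 1).
#' @return Thresholded weight matrix.
#' @export
threshold_by_sparsity <- function(W, s) {
  W <- .as_weights(W)
  stopifnot(s > 0, s < 1)
  n <- nrow(W)
  k <- round(s * (n * (n - 1) / 2))
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  nz <- sum(w > 0)
  if (k >= nz) {
    if (k > nz) warning("requested sparsity exceeds available edges; keeping all")
    return(W)
  }
  ord <- order(-w, ut[, 1L], ut[, 2L])
  drop <- ord[-seq_len(k)]
  out <- matrix(0, n, n, dimnames = dimnames(W))
  keep <- ord[seq_len(k)]
  out[ut[keep, , drop = FALSE]] <- w[keep]
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Node strength
#'
#' Sum of the weights of the edges incident to each node.
#'
#' @param W Weight matrix (or consensus object).
#' @return Named numeric vector.
#' @export
node_strength <- function(W) {
  W <- .as_weights(W)
  rowSums(W)
}

#' Node betweenness centrality (percentage form)
#'
#' Percentage of all shortest paths between pairs of other nodes that pass
#' through each node, with edge length the reciprocal of weight. Isolated
#' nodes and disconnected pairs contribute zero.
#'
#' @param W Weight matrix (or consensus object).
#' @param path_transform See [analysis_config()].
#' @return Named numeric vector in [0, 100].
#' @export
node_betweenness <- function(W, path_transform = "inverse") {
  W <- .as_weights(W)
  n <- nrow(W)
  if (n < 3L) return(stats::setNames(numeric(n), rownames(W)))
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- if (path_transform == "inverse") 1 / igraph::E(g)$weight
         else -log(igraph::E(g)$weight)
  b <- igraph::betweenness(g, weights = len, directed = FALSE)
  100 * b / ((n - 1) * (n - 2) / 2)
}

#' Weighted clustering coefficient (Onnela)
#'
#' Per-node geometric-mean triangle intensity over normalized weights
#' \eqn{\hat w = w / \max(w)}:
#' \deqn{C_v = \frac{1}{k_v (k_v - 1)} \sum_{u,w} (\hat w_{vu} \hat w_{uw}
#'   \hat w_{wv})^{1/3}}
#' with \eqn{k_v} the binary degree; nodes of degree < 2 have C = 0. On
#' binary graphs this reduces to the usual triangle ratio.
#'
#' @param W Weight matrix (or consensus object).
#' @return Named numeric vector in [0, 1].
#' @export
clustering_coefficient <- function(W) {
  W <- .as_weights(W)
  mx <- max(W)
  n <- nrow(W)
  if (mx == 0) return(stats::setNames(numeric(n), rownames(W)))
  Wh <- (W / mx)^(1 / 3)
  tri <- diag(Wh %*% Wh %*% Wh)
  k <- rowSums(W > 0)
  C <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  stats::setNames(C, rownames(W))
}

#' Global efficiency
#'
#' Harmonic-mean form: the mean over ordered node pairs of the reciprocal
#' shortest-path distance (with 1/Inf = 0 for disconnected pairs), so the
#' measure is finite on disconnected graphs.
#'
#' @param W Weight matrix (or consensus object).
#' @param path_transform See [analysis_config()].
#' @return Scalar in [0, 1] for weights in [0, 1].
#' @export
global_efficiency <- function(W, path_transform = "inverse") {
  W <- .as_weights(W)
  n <- nrow(W)
  if (n < 2L) return(0)
  D <- .shortest_dists(W, path_transform)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Global efficiency of the subgraph induced by each node's neighbors;
#' nodes with fewer than two neighbors have local efficiency 0.
#'
#' @param W Weight matrix (or consensus object).
#' @param path_transform See [analysis_config()].
#' @return Named numeric vector.
#' @export
local_efficiency <- function(W, path_transform = "inverse") {
  W <- .as_weights(W)
  n <- nrow(W)
  out <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(W[v, ] > 0)
    if (length(nb) >= 2L)
      out[v] <- global_efficiency(W[nb, nb, drop = FALSE], path_transform)
  }
  stats::setNames(out, rownames(W))
}

#' Network density
#'
#' Fraction of possible edges present (weight > 0).
#'
#' @param W Weight matrix (or consensus object).
#' @return Scalar in [0, 1].
#' @export
network_density <- function(W) {
  W <- .as_weights(W)
  n <- nrow(W)
  if (n < 2L) return(0)
  sum(W[upper.tri(W)] > 0) / (n * (n - 1) / 2)
}

.METRICS <- c("strength", "betweenness", "clustering",
              "global_efficiency", "local_efficiency", "density")

# network-level summary of one metric on one (already thresholded) matrix
.metric_value <- function(W, metric, path_transform = "inverse") {
  switch(metric,
    strength          = mean(node_strength(W)),
    betweenness       = mean(node_betweenness(W, path_transform)),
    clustering        = mean(clustering_coefficient(W)),
    global_efficiency = global_efficiency(W, path_transform),
    local_efficiency  = mean(local_efficiency(W, path_transform)),
    density           = network_density(W),
    stop("unknown metric: ", metric))
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1L) + y[-1L]) / 2)

#' Metric curve over the sparsity grid, with AUC
#'
#' Evaluates a network metric at each sparsity threshold of the grid and
#' summarizes the curve by its trapezoidal area under the curve.
#'
#' @param W Weight matrix (or consensus object).
#' @param metric One of \code{"strength"}, \code{"betweenness"},
#'   \code{"clustering"}, \code{"global_efficiency"},
#'   \code{"local_efficiency"}, \code{"density"}.
#' @param config An [analysis_config()].
#' @return List of class \code{ccd_metric_curve}: \code{metric},
#'   \code{thresholds}, \code{values}, \code{auc}.
#' @export
metric_curve <- function(W, metric, config = analysis_config()) {
  metric <- match.arg(metric, .METRICS)
  grid <- config$sparsity_grid
  if (length(grid) < 2L) stop("AUC needs a grid of at least two thresholds")
  vals <- vapply(grid, function(s)
    .metric_value(threshold_by_sparsity(W, s), metric, config$path_transform),
    numeric(1))
  structure(list(metric = metric, thresholds = grid, values = vals,
                 auc = .trapz(grid, vals)), class = "ccd_metric_curve")
}

#' Per-subject metric AUCs for a cohort
#'
#' @param cohort A \code{ccd_cohort} or list of weight matrices.
#' @param metric See [metric_curve()].
#' @param config An [analysis_config()].
#' @return Numeric vector of per-subject AUC values.
#' @export
metric_auc <- function(cohort, metric, config = analysis_config()) {
  mats <- if (inherits(cohort, "ccd_cohort")) cohort$subjects else cohort
  vapply(mats, function(W) metric_curve(W, metric, config)$auc, numeric(1))
}

#' Per-subject AUC table for several metrics
#'
#' @param cohort A \code{ccd_cohort} or list of weight matrices.
#' @param metrics Character vector of metric names.
#' @param config An [analysis_config()].
#' @return Data frame, subjects in rows, metrics in columns.
#' @export
auc_table <- function(cohort, metrics = c("strength", "clustering",
                                          "global_efficiency",
                                          "local_efficiency"),
                      config = analysis_config()) {
  out <- lapply(metrics, function(m) metric_auc(cohort, m, config))
  names(out) <- metrics
  as.data.frame(out)
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  adj[order(ord)]
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines transformed skewness and kurtosis z-scores into the K-squared
#' statistic, referred to a chi-squared distribution with 2 degrees of
#' freedom. Requires at least 8 observations.
#'
#' @param x Numeric vector.
#' @return List with \code{statistic} (K2) and \code{p.value}.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8L) stop("D'Agostino-Pearson test requires n >= 8")
  x <- x - mean(x)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  Wsq <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(Wsq)))
  alpha <- sqrt(2 / (Wsq - 1))
  Z1 <- delta * asinh(Y / alpha)

  # kurtosis z (Anscombe-Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(Vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  Z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xs * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Z1^2 + Z2^2
  list(statistic = K2, p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

# two-sample comparison of one measure: normality-gated t / Welch-t / rank test
.two_sample_test <- function(a, b, alpha = 0.05) {
  norm_p <- function(x) {
    if (length(x) >= 8L) dagostino_pearson(x)$p.value
    else stats::shapiro.test(x)$p.value
  }
  normal <- !anyNA(c(a, b)) && stats::sd(a) > 0 && stats::sd(b) > 0 &&
    norm_p(a) >= alpha && norm_p(b) >= alpha
  if (normal) {
    fp <- stats::var.test(a, b)$p.value
    tt <- stats::t.test(a, b, var.equal = fp >= alpha)
    list(test = if (fp >= alpha) "t" else "welch_t",
         statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    list(test = "mann_whitney", statistic = unname(wt$statistic), p = wt$p.value)
  }
}

#' Compare per-subject AUCs between two groups
#'
#' For each measure, tests group A against group B with an unpaired
#' two-tailed test: Student's t when both samples pass the
#' D'Agostino-Pearson normality check (Welch form when an F test finds
#' unequal variances), otherwise a Mann-Whitney U test. Raw p-values are
#' adjusted across measures by the Holm-Sidak step-down procedure.
#'
#' @param aucA,aucB Data frames (or named lists) of per-subject AUC values,
#'   one column per measure; see [auc_table()].
#' @param alpha Significance level for normality/variance gates and the
#'   final call.
#' @return Data frame of class \code{ccd_comparison}: measure, test used,
#'   statistic, raw and adjusted p, significance flag.
#' @export
compare_groups_auc <- function(aucA, aucB, alpha = 0.05) {
  aucA <- as.data.frame(aucA); aucB <- as.data.frame(aucB)
  measures <- intersect(names(aucA), names(aucB))
  if (!length(measures)) stop("no shared measures to compare")
  rows <- lapply(measures, function(m)
    .two_sample_test(aucA[[m]], aucB[[m]], alpha))
  out <- data.frame(
    measure = measures,
    test = vapply(rows, `[[`, character(1), "test"),
    statistic = vapply(rows, `[[`, numeric(1), "statistic"),
    p_raw = vapply(rows, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$p_adj <- holm_sidak(out$p_raw)
  out$significant <- out$p_adj < alpha
  class(out) <- c("ccd_comparison", "data.frame")
  out
}
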