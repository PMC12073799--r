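# Network-based statistic: edge-wise two-sample t statistics, suprathreshold
# connected components, and permutation inference on the maximal component
# size with family-wise error control.

.cohort_mats <- function(x) {
  if (inherits(x, "ccd_cohort")) x$subjects else x
}

# stack a list of symmetric matrices into an edges-by-subjects matrix of
# upper-triangle weights; returns the matrix plus the edge index map
.edge_stack <- function(mats) {
  n <- nrow(mats[[1L]])
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  X <- vapply(mats, function(W) W[ut], numeric(nrow(ut)))
  list(X = X, ei = ut[, 1L], ej = ut[, 2L], n_nodes = n,
       labels = rownames(mats[[1L]]))
}

# pooled-variance two-sample t statistics for many label assignments at once;
# X is edges x subjects, P1 an indicator matrix (subjects x perms) of group-A
# membership with n1 ones per column. Edges with zero variance in both groups
# get t = 0.
.t_matrix <- function(X, X2, St, SSt, P1, n1, n2) {
  S1 <- X %*% P1
  SS1 <- X2 %*% P1
  S2 <- St - S1
  SS2 <- SSt - SS1
  df <- n1 + n2 - 2
  ssw <- (SS1 - S1^2 / n1) + (SS2 - S2^2 / n2)
  ssw[ssw < 0] <- 0
  se <- sqrt(ssw / df * (1 / n1 + 1 / n2))
  tt <- (S1 / n1 - S2 / n2) / se
  tt[se == 0] <- 0
  tt
}

# size (edge count) of the largest connected component of an edge set
.max_component_edges <- function(ei, ej) {
  nodes <- unique(c(ei, ej))
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  a <- match(ei, nodes); b <- match(ej, nodes)
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(a, find, integer(1))
  max(tabulate(match(roots, unique(roots))))
}

#' Edge-wise two-sample t statistics
#'
#' Pooled-variance t statistic per edge for the contrast between two cohorts,
#' with absent edges entering as weight 0. \code{direction = "a_gt_b"} gives
#' positive t where group A exceeds group B; \code{"b_gt_a"} flips the sign.
#' Edges with zero variance in both groups are set to 0 (uninformative).
#'
#' @param cohortA,cohortB \code{ccd_cohort} objects or lists of weight
#'   matrices on a shared parcellation; at least 2 subjects each.
#' @param direction Contrast direction.
#' @return Symmetric matrix of t statistics (zero diagonal).
#' @export
edge_t_stats <- function(cohortA, cohortB, direction = c("a_gt_b", "b_gt_a")) {
  direction <- match.arg(direction)
  A <- .cohort_mats(cohortA); B <- .cohort_mats(cohortB)
  n1 <- length(A); n2 <- length(B)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  if (!identical(dim(A[[1L]]), dim(B[[1L]]))) stop("parcellation mismatch")
  es <- .edge_stack(c(A, B))
  X <- es$X; X2 <- X^2
  P1 <- matrix(0, n1 + n2, 1L); P1[seq_len(n1), 1L] <- 1
  tt <- .t_matrix(X, X2, rowSums(X), rowSums(X2), P1, n1, n2)[, 1L]
  if (direction == "b_gt_a") tt <- -tt
  n <- es$n_nodes
  Tm <- matrix(0, n, n, dimnames = list(es$labels, es$labels))
  Tm[cbind(es$ei, es$ej)] <- tt
  Tm[cbind(es$ej, es$ei)] <- tt
  Tm
}

#' Connected components of the suprathreshold graph
#'
#' Edges with t statistic strictly above the primary threshold form a graph;
#' its connected components (by shared nodes) are the candidate subnetworks.
#' Component size is the number of edges.
#'
#' @param t_matrix Symmetric matrix of edge t statistics.
#' @param t_star Primary threshold.
#' @return List of components, each a list with \code{edges} (data frame
#'   \code{i}, \code{j}, \code{t}) and \code{size}; empty list if no edge is
#'   suprathreshold.
#' @export
suprathreshold_components <- function(t_matrix, t_star) {
  n <- nrow(t_matrix)
  ut <- which(upper.tri(t_matrix) & t_matrix > t_star, arr.ind = TRUE)
  if (nrow(ut) == 0L) return(list())
  g <- igraph::graph_from_edgelist(ut, directed = FALSE)
  comp <- igraph::components(g)$membership
  labs <- rownames(t_matrix)
  split_id <- comp[ut[, 1L]]
  out <- lapply(sort(unique(split_id)), function(cid) {
    sel <- split_id == cid
    ed <- data.frame(i = ut[sel, 1L], j = ut[sel, 2L],
                     t = t_matrix[ut[sel, , drop = FALSE]])
    if (!is.null(labs)) {
      ed$label_i <- labs[ed$i]; ed$label_j <- labs[ed$j]
    }
    list(edges = ed, size = sum(sel))
  })
  out[order(-vapply(out, `[[`, integer(1), "size"))]
}

# null distribution of the maximal suprathreshold component size under
# subject relabeling; vectorized over permutations in chunks
.nbs_null_max <- function(X, ei, ej, n1, n2, t_star, n_perm, seed,
                          chunk = 500L) {
  N <- n1 + n2
  X2 <- X^2
  St <- rowSums(X); SSt <- rowSums(X2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  null_max <- numeric(n_perm)
  done <- 0L
  while (done < n_perm) {
    p <- min(chunk, n_perm - done)
    P1 <- matrix(0, N, p)
    for (c in seq_len(p)) P1[sample.int(N, n1), c] <- 1
    tt <- .t_matrix(X, X2, St, SSt, P1, n1, n2)
    supra <- tt > t_star
    cnt <- colSums(supra)
    for (c in seq_len(p)) {
      null_max[done + c] <- if (cnt[c] <= 1L) cnt[c]
        else .max_component_edges(ei[supra[, c]], ej[supra[, c]])
    }
    done <- done + p
  }
  null_max
}

#' Network-based statistic permutation test
#'
#' Tests for subnetworks whose edge weights differ between two cohorts in the
#' requested direction. Observed suprathreshold components (edge-wise pooled
#' t above \code{t_star}) are compared against the permutation null
#' distribution of the maximal component size under subject relabeling;
#' each component's family-wise-error-corrected p-value is
#' \deqn{p = \frac{1 + \#\{ \mathrm{null\ max} \ge \mathrm{size} \}}{P + 1}.}
#'
#' @param cohortA,cohortB \code{ccd_cohort} objects or lists of weight
#'   matrices; at least 2 subjects per group.
#' @param t_star Primary t threshold.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer RNG seed; results are bit-reproducible given the seed.
#' @param direction Contrast direction, see [edge_t_stats()].
#' @param alpha Significance level for the \code{significant} flags.
#' @return List of class \code{ccd_nbs}: \code{t_star}, \code{components}
#'   (each with edges, size, p, significant), \code{null_max} (the
#'   permutation null), \code{n_perm}, \code{seed}, \code{direction}.
#' @export
nbs_test <- function(cohortA, cohortB, t_star = 3, n_perm = 5000L, seed = 1L,
                     direction = c("a_gt_b", "b_gt_a"), alpha = 0.05) {
  direction <- match.arg(direction)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  A <- .cohort_mats(cohortA); B <- .cohort_mats(cohortB)
  n1 <- length(A); n2 <- length(B)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  Tm <- edge_t_stats(A, B, direction)
  comps <- suprathreshold_components(Tm, t_star)

  es <- .edge_stack(c(A, B))
  X <- if (direction == "b_gt_a") -es$X else es$X
  null_max <- .nbs_null_max(X, es$ei, es$ej, n1, n2, t_star, n_perm, seed)

  for (k in seq_along(comps)) {
    sz <- comps[[k]]$size
    comps[[k]]$p <- (1 + sum(null_max >= sz)) / (n_perm + 1)
    comps[[k]]$significant <- comps[[k]]$p < alpha
  }
  structure(list(t_star = t_star, components = comps, null_max = null_max,
                 n_perm = as.integer(n_perm), seed = seed,
                 direction = direction, alpha = alpha),
            class = "ccd_nbs")
}

#' @export
print.ccd_nbs <- function(x, ...) {
  cat(sprintf("NBS (t* = %g, %d permutations, direction %s)\n",
              x$t_star, x$n_perm, x$direction))
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (k in seq_along(x$components)) {
      cm <- x$components[[k]]
      cat(sprintf("  component %d: %d edges, FWER p = %.4f%s\n", k, cm$size,
                  cm$p, if (cm$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' NBS threshold sweep with per-edge significance counts
#'
#' Runs the NBS at each primary threshold and counts, per edge, at how many
#' thresholds the edge belonged to a family-wise-significant component.
#'
#' @param cohortA,cohortB Cohorts, see [nbs_test()].
#' @param thresholds Primary thresholds (default 2:5).
#' @param n_perm,seed,direction,alpha Passed to [nbs_test()].
#' @return List of class \code{ccd_nbs_sweep}: \code{counts} (symmetric
#'   integer matrix, per-edge number of significant thresholds),
#'   \code{results} (per-threshold \code{ccd_nbs} objects), \code{thresholds}.
#' @export
threshold_sweep <- function(cohortA, cohortB, thresholds = 2:5,
                            n_perm = 5000L, seed = 1L,
                            direction = c("a_gt_b", "b_gt_a"), alpha = 0.05) {
  direction <- match.arg(direction)
  A <- .cohort_mats(cohortA)
  n <- nrow(A[[1L]])
  counts <- matrix(0L, n, n, dimnames = dimnames(A[[1L]]))
  results <- list()
  for (k in seq_along(thresholds)) {
    res <- nbs_test(cohortA, cohortB, t_star = thresholds[k], n_perm = n_perm,
                    seed = seed + k, direction = direction, alpha = alpha)
    results[[k]] <- res
    for (cm in res$components) {
      if (!cm$significant) next
      ij <- cbind(cm$edges$i, cm$edges$j)
      counts[ij] <- counts[ij] + 1L
      counts[ij[, 2:1, drop = FALSE]] <- counts[ij]
    }
  }
  structure(list(counts = counts, results = results, thresholds = thresholds),
            class = "ccd_nbs_sweep")
}

#' Empirical family-wise error rate of the NBS under the null
#'
#' Generates replicate pairs of cohorts from one template distribution (both
#' groups identical in expectation), runs the NBS on each pair, and reports
#' the fraction of replicates that declare any significant component — an
#' empirical check that the permutation procedure controls the family-wise
#' error rate at the nominal level.
#'
#' @param n_replicates Number of replicate null comparisons (default 200).
#' @param n_subjects Subjects per group (default 10).
#' @param t_star Primary threshold (default 3).
#' @param n_perm Permutations per replicate (default 1000).
#' @param seed Integer master seed.
#' @param condition Template condition to sample from (default normal_cc).
#' @param alpha Nominal level.
#' @return List: \code{fwer} (fraction of replicates with any significant
#'   component), \code{n_replicates}, \code{hits} (logical per replicate).
#' @export
nbs_fwer_null <- function(n_replicates = 200L, n_subjects = 10L, t_star = 3,
                          n_perm = 1000L, seed = 1L, condition = "normal_cc",
                          alpha = 0.05) {
  parc <- build_parcellation()
  base_cfg <- cohort_config(n_subjects = n_subjects, rng_seed = 1L)
  template <- build_template(parc, condition, base_cfg)
  hits <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    cfgA <- cohort_config(n_subjects = n_subjects,
                          rng_seed = (seed + 2L * r) %% 1912393L)
    cfgB <- cohort_config(n_subjects = n_subjects,
                          rng_seed = (seed + 2L * r + 1L) %% 1912393L)
    A <- lapply(seq_len(n_subjects), function(s)
      sample_individual(template, cfgA, s))
    B <- lapply(seq_len(n_subjects), function(s)
      sample_individual(template, cfgB, s))
    res <- nbs_test(A, B, t_star = t_star, n_perm = n_perm,
                    seed = seed + 7919L * r, alpha = alpha)
    hits[r] <- any(vapply(res$components, `[[`, logical(1), "significant"))
  }
  list(fwer = mean(hits), n_replicates = n_replicates, hits = hits)
}
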