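# Edge-weight variability, pairwise network similarity split by edge class,
# and the novel/preserved connection discovery rule.

#' Normalized standard deviation of edge weights
#'
#' Per-edge coefficient of variation across subjects: the standard deviation
#' of the edge's weights (absent = 0) divided by its mean weight. Edges
#' absent in every subject are NA.
#'
#' @param cohort A \code{ccd_cohort} or list of weight matrices.
#' @return Symmetric matrix of normalized SDs (NA where always absent,
#'   diagonal NA).
#' @export
edge_normalized_sd <- function(cohort) {
  mats <- .cohort_mats(cohort)
  n <- length(mats)
  S <- Reduce(`+`, mats)
  S2 <- Reduce(`+`, lapply(mats, function(W) W^2))
  mu <- S / n
  v <- (S2 - S^2 / n) / (n - 1)
  v[v < 0] <- 0
  out <- sqrt(v) / mu
  out[mu == 0] <- NA_real_
  diag(out) <- NA_real_
  out
}

.class_mask <- function(parc, n, edge_class) {
  ut <- upper.tri(matrix(0, n, n))
  if (edge_class == "whole") return(ut)
  inter <- outer(parc$hemisphere, parc$hemisphere, `!=`)
  if (edge_class == "inter") ut & inter else ut & !inter
}

#' Pairwise network similarity within a cohort
#'
#' For every pair of subjects, the correlation between their edge-weight
#' vectors over the union of edges present in at least one of the two,
#' restricted to the requested edge class (whole network, interhemispheric
#' or intrahemispheric). Each subject's similarity is the mean of its n - 1
#' pairwise correlations; the cohort summary is the mean and SEM of those
#' per-subject values.
#'
#' @param cohort A \code{ccd_cohort}, or list of weight matrices (then
#'   \code{parc} is required for inter/intra scoping).
#' @param edge_class \code{"whole"}, \code{"inter"} or \code{"intra"}.
#' @param method Correlation type, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @param parc Parcellation, taken from the cohort when available.
#' @return List of class \code{ccd_similarity}: \code{per_subject},
#'   \code{mean}, \code{sem}, \code{edge_class}, \code{n_pairs_skipped}.
#' @export
pairwise_similarity <- function(cohort, edge_class = c("whole", "inter", "intra"),
                                method = c("pearson", "spearman"),
                                parc = NULL) {
  edge_class <- match.arg(edge_class)
  method <- match.arg(method)
  mats <- .cohort_mats(cohort)
  if (is.null(parc) && inherits(cohort, "ccd_cohort")) parc <- cohort$parcellation
  if (is.null(parc) && edge_class != "whole")
    stop("parcellation required to scope inter/intrahemispheric edges")
  n <- length(mats)
  if (n < 3L) stop("similarity requires at least 3 subjects")
  mask <- .class_mask(parc %||% data.frame(), nrow(mats[[1L]]), edge_class)
  vecs <- lapply(mats, function(W) W[mask])

  R <- matrix(NA_real_, n, n)
  skipped <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      va <- vecs[[a]]; vb <- vecs[[b]]
      present <- va > 0 | vb > 0
      if (sum(present) < 3L || stats::sd(va[present]) == 0 ||
          stats::sd(vb[present]) == 0) {
        skipped <- skipped + 1L
        next
      }
      R[a, b] <- R[b, a] <- stats::cor(va[present], vb[present],
                                       method = method)
    }
  }
  per_subject <- rowMeans(R, na.rm = TRUE)
  structure(list(per_subject = per_subject, mean = mean(per_subject),
                 sem = stats::sd(per_subject) / sqrt(n),
                 edge_class = edge_class, method = method,
                 n_pairs_skipped = skipped),
            class = "ccd_similarity")
}

#' @export
print.ccd_similarity <- function(x, ...) {
  cat(sprintf("Pairwise network similarity (%s, %s edges): %.3f +/- %.3f (SEM, n = %d)\n",
              x$method, x$edge_class, x$mean, x$sem, length(x$per_subject)))
  invisible(x)
}

#' Compare pairwise-similarity reports between two cohorts
#'
#' Unpaired two-tailed comparison of the per-subject mean correlations
#' (Student's/Welch t when both samples pass the normality check, otherwise
#' Mann-Whitney U).
#'
#' @param reportA,reportB \code{ccd_similarity} reports.
#' @param alpha Significance level for the normality/variance gates.
#' @return List: \code{test}, \code{statistic}, \code{p}.
#' @export
group_compare_similarity <- function(reportA, reportB, alpha = 0.05) {
  .two_sample_test(reportA$per_subject, reportB$per_subject, alpha)
}

#' Discover novel and preserved connections
#'
#' Novel connections are edges present (weight > 0) in at least
#' \code{min_count} case subjects but in no control subject — the rule that
#' flags low-penetrance tracts such as the sigmoid bundle. Preserved
#' connections are edges present in the consensus connectomes of both
#' cohorts. Evaluated on unthresholded individual connectomes.
#'
#' @param case_cohort,control_cohort \code{ccd_cohort} objects or lists of
#'   weight matrices on a shared parcellation.
#' @param min_count Minimum case carrier count (default 2, i.e. 20\%
#'   penetrance at n = 10).
#' @param consensus_fraction Fraction for the preserved-edge consensus rule.
#' @return List of class \code{ccd_novelty}: \code{novel} (data frame i, j,
#'   labels, case_count, control_count), \code{preserved} (data frame of
#'   consensus-shared edges), counts of each.
#' @export
discover_novel_edges <- function(case_cohort, control_cohort, min_count = 2L,
                                 consensus_fraction = 0.5) {
  cases <- .cohort_mats(case_cohort)
  ctrls <- .cohort_mats(control_cohort)
  if (!identical(dim(cases[[1L]]), dim(ctrls[[1L]]))) stop("parcellation mismatch")
  n <- nrow(cases[[1L]])
  labs <- rownames(cases[[1L]])
  case_n <- Reduce(`+`, lapply(cases, function(W) (W > 0) * 1L))
  ctrl_n <- Reduce(`+`, lapply(ctrls, function(W) (W > 0) * 1L))

  ut <- which(upper.tri(case_n), arr.ind = TRUE)
  novel_sel <- case_n[ut] >= min_count & ctrl_n[ut] == 0L
  novel <- data.frame(i = ut[novel_sel, 1L], j = ut[novel_sel, 2L],
                      case_count = case_n[ut][novel_sel],
                      control_count = ctrl_n[ut][novel_sel])
  cons_case <- build_consensus(cases, consensus_fraction)$weights
  cons_ctrl <- build_consensus(ctrls, consensus_fraction)$weights
  pres_sel <- cons_case[ut] > 0 & cons_ctrl[ut] > 0
  preserved <- data.frame(i = ut[pres_sel, 1L], j = ut[pres_sel, 2L],
                          case_count = case_n[ut][pres_sel],
                          control_count = ctrl_n[ut][pres_sel])
  if (!is.null(labs)) {
    novel$label_i <- labs[novel$i]; novel$label_j <- labs[novel$j]
    preserved$label_i <- labs[preserved$i]; preserved$label_j <- labs[preserved$j]
  }
  ord <- order(-novel$case_count, novel$i, novel$j)
  novel <- novel[ord, , drop = FALSE]
  rownames(novel) <- NULL
  structure(list(novel = novel, preserved = preserved,
                 n_novel = nrow(novel), n_preserved = nrow(preserved),
                 min_count = min_count,
                 n_case = length(cases), n_control = length(ctrls)),
            class = "ccd_novelty")
}

#' @export
print.ccd_novelty <- function(x, ...) {
  cat(sprintf("Novel connections (>= %d cases, 0 controls): %d\n",
              x$min_count, x$n_novel))
  if (x$n_novel > 0) {
    top <- utils::head(x$novel, 10L)
    for (k in seq_len(nrow(top)))
      cat(sprintf("  %s -- %s: present in %d of %d cases\n",
                  top$label_i[k] %||% top$i[k], top$label_j[k] %||% top$j[k],
                  top$case_count[k], x$n_case))
  }
  cat("Preserved connections (both consensus):", x$n_preserved, "\n")
  invisible(x)
}
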