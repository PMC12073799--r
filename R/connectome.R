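# Connectome construction from seed connectivity maps: two-step connection
# retention, FA edge weighting, virtual callosotomy, and group consensus
# connectomes.

#' Construct a seed connectivity map
#'
#' Bundles a seed region's voxelwise streamline-fraction map with the label
#' volume that assigns voxels to regions, and optionally a fractional
#' anisotropy (FA) volume on the same grid.
#'
#' @param seed_region Region id of the seed.
#' @param map Numeric array (any dimension) of streamline-fraction values,
#'   all non-negative.
#' @param labels Integer array of the same shape; voxel region id, 0 = background.
#' @param fa Optional numeric array of the same shape with FA values.
#' @return List of class \code{ccd_seed_map}.
#' @export
seed_map <- function(seed_region, map, labels, fa = NULL) {
  if (!identical(dim(map), dim(labels)))
    stop("label volume shape does not match connectivity map")
  if (any(map < 0)) stop("connectivity map values must be non-negative")
  if (!is.null(fa) && !identical(dim(fa), dim(map)))
    stop("FA volume shape does not match connectivity map")
  structure(list(seed_region = seed_region, map = map, labels = labels,
                 fa = fa), class = "ccd_seed_map")
}

#' Two-step retention test for a putative connection
#'
#' A connection from the seed of \code{map} to \code{target_region} is
#' retained when the ratio between the sum of connectivity values over the
#' target's voxels and the target's voxel count is greater than zero, i.e.
#' when any streamline mass reaches the target.
#'
#' @param map A [seed_map()].
#' @param target_region Region id to test.
#' @return Logical.
#' @export
retain_connection <- function(map, target_region) {
  vox <- map$labels == target_region
  if (!any(vox)) stop("target region has zero volume in the label volume")
  sum(map$map[vox]) / sum(vox) > 0
}

#' FA-based edge weight of a connection
#'
#' Mean FA across voxels whose connectivity value exceeds
#' \code{tract_threshold}, so the edge weight reflects the microstructure of
#' the reconstructed tract rather than the atlas regions themselves.
#'
#' @param map Numeric array of connectivity values (or a [seed_map()]).
#' @param fa_volume Numeric array of FA values, same shape.
#' @param tract_threshold Connectivity cutoff for a voxel to contribute
#'   (default 0.001).
#' @return Mean FA over qualifying voxels, or 0 (absent edge) if none qualify.
#' @export
edge_weight_fa <- function(map, fa_volume, tract_threshold = 0.001) {
  if (inherits(map, "ccd_seed_map")) map <- map$map
  if (!identical(dim(map), dim(fa_volume)))
    stop("FA volume shape does not match connectivity map")
  q <- map > tract_threshold
  if (!any(q)) return(0)
  mean(fa_volume[q])
}

#' Build a connectome from per-region seed connectivity maps
#'
#' Two-step construction: step 1 proposes a candidate pair (i, j) when the
#' retention test passes seeding from i toward j or from j toward i; step 2
#' re-tests the candidate with each map masked to the pair's own voxels and
#' confirms the edge only when both directions pass. Confirmed edges are
#' weighted by mean FA over voxels of the pair-restricted mean map above
#' \code{tract_threshold}. The output is symmetric with zero diagonal.
#'
#' @param maps List of [seed_map()] objects, one per region, named or ordered
#'   by region id \code{1..n}.
#' @param n_regions Number of regions (defaults to \code{length(maps)}).
#' @param tract_threshold Connectivity cutoff for FA weighting.
#' @param labels Optional node labels for the matrix dimnames.
#' @return Symmetric numeric weight matrix.
#' @export
build_connectome <- function(maps, n_regions = length(maps),
                             tract_threshold = 0.001, labels = NULL) {
  if (length(maps) < n_regions) stop("missing seed connectivity map")
  for (r in seq_len(n_regions))
    if (!inherits(maps[[r]], "ccd_seed_map")) stop("missing seed map for region ", r)
  W <- matrix(0, n_regions, n_regions)
  if (!is.null(labels)) dimnames(W) <- list(labels, labels)
  for (i in seq_len(n_regions - 1L)) {
    for (j in seq.int(i + 1L, n_regions)) {
      cand <- retain_connection(maps[[i]], j) || retain_connection(maps[[j]], i)
      if (!cand) next
      pair_vox <- maps[[i]]$labels == i | maps[[i]]$labels == j
      mi <- maps[[i]]$map * pair_vox
      mj <- maps[[j]]$map * pair_vox
      smi <- seed_map(i, mi, maps[[i]]$labels)
      smj <- seed_map(j, mj, maps[[j]]$labels)
      if (!(retain_connection(smi, j) && retain_connection(smj, i))) next
      if (is.null(maps[[i]]$fa)) stop("FA volume required to weight edges")
      w <- edge_weight_fa((mi + mj) / 2, maps[[i]]$fa, tract_threshold)
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

#' Remove callosal edges from a connectome (virtual callosotomy)
#'
#' Zeroes the listed edges and leaves everything else unchanged — the
#' in-silico analogue of a midsagittal exclusion region over the corpus
#' callosum, giving a control network lacking callosal connections but also
#' lacking any compensatory rewiring.
#'
#' @param W Weight matrix.
#' @param cc_edges Data frame (or 2-column matrix) of node index pairs
#'   \code{i, j} to zero; an empty list is the identity.
#' @return The edited weight matrix.
#' @export
virtual_callosotomy <- function(W, cc_edges) {
  if (is.null(cc_edges) || NROW(cc_edges) == 0L) return(W)
  ij <- as.matrix(cc_edges[, 1:2])
  W[ij] <- 0
  W[ij[, 2:1, drop = FALSE]] <- 0
  W
}

#' Group consensus connectome
#'
#' Keeps edges present (weight > 0) in at least \code{min_fraction} of the
#' cohort's subjects (inclusive, i.e. at least \code{ceiling(min_fraction * n)}
#' subjects) and weights each kept edge by the mean FA over the subjects that
#' carry it.
#'
#' @param cohort A \code{ccd_cohort} or a list of weight matrices.
#' @param min_fraction Minimum fraction of subjects carrying an edge
#'   (default 0.5).
#' @return List of class \code{ccd_consensus} with elements \code{weights}
#'   (consensus matrix), \code{support} (per-edge subject counts),
#'   \code{n_subjects} and \code{min_fraction}.
#' @export
build_consensus <- function(cohort, min_fraction = 0.5) {
  mats <- if (inherits(cohort, "ccd_cohort")) cohort$subjects else cohort
  n <- length(mats)
  if (n < 2L) stop("consensus requires at least 2 subjects")
  d <- dim(mats[[1L]])
  for (m in mats) if (!identical(dim(m), d)) stop("parcellation mismatch across subjects")
  support <- Reduce(`+`, lapply(mats, function(W) (W > 0) * 1L))
  total <- Reduce(`+`, mats)
  need <- ceiling(min_fraction * n)
  keep <- support >= need
  weights <- matrix(0, d[1L], d[2L], dimnames = dimnames(mats[[1L]]))
  weights[keep] <- total[keep] / support[keep]
  structure(list(weights = weights, support = support, n_subjects = n,
                 min_fraction = min_fraction), class = "ccd_consensus")
}

#' @export
print.ccd_consensus <- function(x, ...) {
  ut <- upper.tri(x$weights)
  cat("Consensus connectome:", sum(x$weights[ut] > 0), "edges kept",
      sprintf("(support >= %d of %d subjects)\n",
              ceiling(x$min_fraction * x$n_subjects), x$n_subjects))
  invisible(x)
}
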