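# Synthetic cohort generator. A per-condition template network (deterministic)
# defines edge topology: mean FA-like weight, tract tag, presence probability
# and weight-noise SD per edge; individual connectomes are sampled from the
# template with per-subject seeds so that paired conditions (normal vs virtual
# callosotomy) share identical non-callosal draws.
#
# Intrahemispheric topology is a deterministic pseudo-random subset of node
# pairs (dense within lobe groups, sparse between), identical across
# conditions; subject-to-subject variability enters through per-tract-class
# edge consistency (presence) and truncated-normal weight noise. Template
# mean weights carry a deterministic per-edge perturbation (a pure function
# of the node pair) so that edge weights are heterogeneous but identical for
# edges shared between condition templates.

.CONDITIONS <- c("normal_cc", "complete_ccd", "partial_ccd", "virtual_callosotomy")

# homotopic pairs routed through non-callosal commissures (atlas abbreviations)
.AC_REGIONS <- c("Ob", "An", "Pir", "Am")   # anterior commissure
.HC_REGIONS <- c("Hp", "Sub", "Ent")        # hippocampal commissure
.PC_REGIONS <- c("Sc", "Ic", "Pag")         # posterior commissure
# ipsilateral targets of the Probst bundle (frontal pole -> posterior cortex)
.PROBST_TARGETS <- c("V1", "V2l", "V2ml", "A1", "A2", "Pa")

#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable of the generator: cohort size, noise, per-tract-class
#' edge consistency, penetrance of the planted sigmoid bundle, and the edge
#' probability/weight model of the template networks. Consistency values not
#' supplied fall back to condition-specific defaults chosen so that default
#' cohorts reproduce the directional group effects seen in mouse CCD
#' connectomes (lower interhemispheric consistency in partial CCD, lower
#' intrahemispheric consistency in both CCD conditions).
#'
#' @param n_subjects Subjects per cohort (default 10, the study size per
#'   condition); must be at least 2.
#' @param weight_sd Standard deviation of the truncated-normal edge-weight
#'   noise around template means (FA units; default 0.05).
#' @param edge_consistency Named numeric vector of per-tract-class presence
#'   multipliers in (0, 1], names among \code{c("intra", "cc", "ac", "pc",
#'   "hc", "probst", "sigmoid")}; entries override condition defaults.
#' @param sigmoid_penetrance Probability that a partial-CCD subject carries the
#'   primary sigmoid edge (default 0.5, i.e. five of ten mice).
#' @param remnant_fraction Fraction of callosal edges retained, anteriorly
#'   biased, in the partial-CCD callosal remnant (default 0.3).
#' @param rng_seed Integer master seed; per-subject streams are derived from it.
#' @param within_lobe_p,between_lobe_p Fraction of intrahemispheric node pairs
#'   wired in the template within / between lobe groups (defaults 0.8 / 0.3).
#' @param hub_regions Atlas abbreviations of cortical association hubs given
#'   denser between-lobe wiring (default frontal association cortex,
#'   claustrum, secondary motor cortex).
#' @param hub_between_p Between-lobe wiring fraction for pairs involving a
#'   hub region (default 0.45).
#' @param within_lobe_w,between_lobe_w Mean weight of intrahemispheric edges
#'   within / between lobe groups (defaults 0.50 / 0.22); subcortical
#'   within-group edges sit 0.05 below the cortical value.
#' @param cc_w,commissure_w,probst_w,sigmoid_w Mean weights of callosal,
#'   non-callosal commissural, Probst-bundle and sigmoid-bundle edges.
#' @param weight_jitter Half-range of the deterministic per-edge perturbation
#'   of template mean weights (default 0.08).
#' @param ccd_weight_sd_factor Multiplier on \code{weight_sd} for complete-
#'   and partial-CCD templates (default 1.3), emulating the greater
#'   edge-weight variability of CCD connectomes.
#' @param ccd_between_lobe_p Presence probability of between-lobe
#'   intrahemispheric edges in CCD templates (default 0.8, vs 1 in controls):
#'   CCD rerouting makes long-range association wiring less reliable across
#'   subjects.
#' @return A list of class \code{ccd_config}.
#' @export
cohort_config <- function(n_subjects = 10L, weight_sd = 0.05,
                          edge_consistency = NULL,
                          sigmoid_penetrance = 0.5,
                          remnant_fraction = 0.3,
                          rng_seed = 1L,
                          within_lobe_p = 0.8, between_lobe_p = 0.3,
                          hub_regions = c("Fra", "Cl", "M2"),
                          hub_between_p = 0.45,
                          within_lobe_w = 0.50, between_lobe_w = 0.22,
                          cc_w = 0.50, commissure_w = 0.45,
                          probst_w = 0.55, sigmoid_w = 0.45,
                          weight_jitter = 0.08,
                          ccd_weight_sd_factor = 1.3,
                          ccd_between_lobe_p = 0.8) {
  stopifnot(n_subjects >= 2, weight_sd >= 0,
            sigmoid_penetrance > 0, sigmoid_penetrance <= 1,
            remnant_fraction > 0, remnant_fraction <= 1)
  if (!is.null(edge_consistency)) {
    stopifnot(!is.null(names(edge_consistency)),
              all(edge_consistency > 0), all(edge_consistency <= 1))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), weight_sd = weight_sd,
    edge_consistency = edge_consistency,
    sigmoid_penetrance = sigmoid_penetrance,
    remnant_fraction = remnant_fraction,
    rng_seed = as.integer(rng_seed),
    within_lobe_p = within_lobe_p, between_lobe_p = between_lobe_p,
    hub_regions = hub_regions, hub_between_p = hub_between_p,
    within_lobe_w = within_lobe_w, between_lobe_w = between_lobe_w,
    cc_w = cc_w, commissure_w = commissure_w,
    probst_w = probst_w, sigmoid_w = sigmoid_w,
    weight_jitter = weight_jitter,
    ccd_weight_sd_factor = ccd_weight_sd_factor,
    ccd_between_lobe_p = ccd_between_lobe_p
  ), class = "ccd_config")
}

# condition-specific per-tract-class consistency defaults; user-supplied
# entries in config$edge_consistency override
.default_consistency <- function(condition) {
  base <- c(intra = 0.95, cc = 0.95, ac = 0.98, pc = 0.98, hc = 0.98,
            probst = 0.95, sigmoid = 1.00)
  switch(condition,
    normal_cc           = base,
    virtual_callosotomy = base,
    complete_ccd        = base,
    # the callosal remnant of partial CCD is topologically inconsistent
    # across subjects; Probst bundles are smaller and less reliable
    partial_ccd         = replace(base, c("cc", "probst"), c(0.60, 0.85)))
}

.resolve_consistency <- function(condition, config) {
  cons <- .default_consistency(condition)
  if (!is.null(config$edge_consistency)) {
    ov <- config$edge_consistency
    cons[names(ov)] <- ov
  }
  cons
}

.node_idx <- function(parc, abbrev, hemi) {
  which(parc$abbrev == abbrev & parc$hemisphere == hemi)
}

#' Build the ground-truth template network for a callosal condition
#'
#' Constructs the deterministic edge list from which individual connectomes
#' are sampled. All conditions share the same intrahemispheric topology and
#' the same anterior/posterior/hippocampal commissure edges; they differ only
#' in callosal and compensatory edges:
#' \describe{
#'   \item{normal_cc}{homotopic callosal (\code{cc}) edges for cortical pairs.}
#'   \item{complete_ccd}{no \code{cc} edges; bilateral Probst-bundle edges
#'     from the frontal association cortex to ipsilateral posterior (visual,
#'     auditory, parietal association) areas.}
#'   \item{partial_ccd}{an anteriorly biased callosal remnant
#'     (\code{remnant_fraction} of \code{cc} edges, ranked by anteroposterior
#'     position), reduced Probst edges, and asymmetric sigmoid-bundle edges
#'     from the left frontal association cortex to the right hippocampus
#'     (presence probability = \code{sigmoid_penetrance}) and right parietal
#'     association cortex (presence probability 0.2).}
#'   \item{virtual_callosotomy}{the normal template with \code{cc} edges
#'     removed and nothing else changed.}
#' }
#'
#' @param parc Parcellation from [build_parcellation()].
#' @param condition One of \code{"normal_cc"}, \code{"complete_ccd"},
#'   \code{"partial_ccd"}, \code{"virtual_callosotomy"}.
#' @param config A [cohort_config()].
#' @return A list of class \code{ccd_template} with elements
#'   \code{parcellation}, \code{condition}, and \code{edges}, a data frame
#'   with columns \code{i}, \code{j} (node indices, \code{i < j}),
#'   \code{mean_weight}, \code{tract_tag}, \code{presence_prob}.
#' @export
build_template <- function(parc, condition, config = cohort_config()) {
  condition <- match.arg(condition, .CONDITIONS)

  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  et <- character(0); ep <- numeric(0)
  add <- function(i, j, w, tag, p) {
    sw <- pmin(i, j); bw <- pmax(i, j)
    ei <<- c(ei, sw); ej <<- c(ej, bw)
    ew <<- c(ew, rep_len(w, length(sw)))
    et <<- c(et, rep_len(tag, length(sw)))
    ep <<- c(ep, rep_len(p, length(sw)))
  }

  # intrahemispheric wiring: a deterministic pseudo-random subset of node
  # pairs, mirrored across hemispheres and identical in every condition
  for (hemi in c("L", "R")) {
    idx <- which(parc$hemisphere == hemi)
    pr <- utils::combn(idx, 2L)
    same_lobe <- parc$lobe[pr[1L, ]] == parc$lobe[pr[2L, ]]
    # mirror-symmetric selection: hash the within-hemisphere positions
    pos1 <- match(pr[1L, ], idx); pos2 <- match(pr[2L, ], idx)
    u <- .edge_hash(pos1, pos2, salt = 1)
    both_cortical <- parc$is_cortical[pr[1L, ]] & parc$is_cortical[pr[2L, ]]
    # association hubs: denser between-lobe wiring among cortical areas
    is_hub_pair <- both_cortical &
      (parc$abbrev[pr[1L, ]] %in% config$hub_regions |
         parc$abbrev[pr[2L, ]] %in% config$hub_regions)
    p_between <- ifelse(is_hub_pair, config$hub_between_p,
                        config$between_lobe_p)
    # subcortical grey-matter groups are less densely intraconnected than
    # cortical lobes
    p_within <- ifelse(both_cortical, config$within_lobe_p,
                       0.5 * config$within_lobe_p)
    w_within <- ifelse(both_cortical, config$within_lobe_w,
                       config$within_lobe_w - 0.05)
    sel_within <- same_lobe & u < p_within
    sel_between <- !same_lobe & u < p_between
    add(pr[1L, sel_within], pr[2L, sel_within], w_within[sel_within],
        "intra", 1)
    add(pr[1L, sel_between], pr[2L, sel_between], config$between_lobe_w,
        "intra", 1)
  }

  # non-callosal commissures: identical across conditions
  for (ab in .AC_REGIONS) add(.node_idx(parc, ab, "L"), .node_idx(parc, ab, "R"),
                              config$commissure_w, "ac", 1)
  for (ab in .HC_REGIONS) add(.node_idx(parc, ab, "L"), .node_idx(parc, ab, "R"),
                              config$commissure_w, "hc", 1)
  for (ab in .PC_REGIONS) add(.node_idx(parc, ab, "L"), .node_idx(parc, ab, "R"),
                              config$commissure_w - 0.05, "pc", 1)

  # callosal edges: homotopic pairs of cortical areas not routed through
  # another commissure
  cc_ab <- setdiff(parc$abbrev[parc$is_cortical & parc$hemisphere == "L"],
                   c(.AC_REGIONS, .HC_REGIONS, .PC_REGIONS))
  cc_i <- vapply(cc_ab, .node_idx, integer(1), parc = parc, hemi = "L")
  cc_j <- vapply(cc_ab, .node_idx, integer(1), parc = parc, hemi = "R")

  probst_pairs <- function() {
    for (hemi in c("L", "R")) {
      fra <- .node_idx(parc, "Fra", hemi)
      tgt <- vapply(.PROBST_TARGETS, .node_idx, integer(1),
                    parc = parc, hemi = hemi)
      add(rep(fra, length(tgt)), tgt, config$probst_w, "probst", 1)
    }
  }

  # CCD conditions: between-lobe intrahemispheric wiring is less consistent
  # across subjects than in controls
  thin_between_lobe <- function() {
    sel <- et == "intra" & parc$lobe[ei] != parc$lobe[ej]
    ep[sel] <<- ep[sel] * config$ccd_between_lobe_p
  }

  if (condition == "normal_cc") {
    add(cc_i, cc_j, config$cc_w, "cc", 1)
  } else if (condition == "complete_ccd") {
    thin_between_lobe()
    probst_pairs()
  } else if (condition == "partial_ccd") {
    thin_between_lobe()
    # anteriorly biased remnant: rank callosal pairs by anteroposterior
    # position (stable tie-break on node index)
    score <- parc$ap_rank[cc_i]
    ord <- order(score, cc_i)
    keep <- ord[seq_len(ceiling(config$remnant_fraction * length(cc_i)))]
    add(cc_i[keep], cc_j[keep], config$cc_w, "cc", 1)
    probst_pairs()
    # reduced Probst penetrance in partial CCD
    ep[et == "probst"] <- 0.5
    # asymmetric sigmoid bundle: left frontal association -> right hippocampus
    # (primary, penetrance configurable) and -> right parietal association
    # (secondary, lower penetrance)
    add(.node_idx(parc, "Fra", "L"), .node_idx(parc, "Hp", "R"),
        config$sigmoid_w, "sigmoid", config$sigmoid_penetrance)
    add(.node_idx(parc, "Fra", "L"), .node_idx(parc, "Pa", "R"),
        config$sigmoid_w, "sigmoid", 0.2)
  }
  # virtual_callosotomy: normal minus cc, i.e. nothing callosal added

  edges <- data.frame(i = ei, j = ej, mean_weight = ew, tract_tag = et,
                      presence_prob = ep, stringsAsFactors = FALSE)
  # condition-specific edges (e.g. Probst over an existing intrahemispheric
  # pair) override the base topology: keep the last definition of each pair
  edges <- edges[!duplicated(edges[, c("i", "j")], fromLast = TRUE), ]
  rownames(edges) <- NULL
  # heterogeneous mean weights: deterministic per-edge perturbation, a pure
  # function of the node pair so shared edges agree across condition templates
  jit <- (2 * .edge_hash(edges$i, edges$j, salt = 2) - 1) * config$weight_jitter
  edges$mean_weight <- pmin(pmax(edges$mean_weight + jit, 0.05), 0.95)
  sd_factor <- if (condition %in% c("complete_ccd", "partial_ccd"))
    config$ccd_weight_sd_factor else 1
  edges$weight_sd <- config$weight_sd * sd_factor
  stopifnot(all(edges$i < edges$j), !anyDuplicated(edges[, c("i", "j")]))
  structure(list(parcellation = parc, condition = condition, edges = edges),
            class = "ccd_template")
}

# deterministic hash of a node pair to (0, 1); stable across platforms at
# double precision, used for template topology selection and weight jitter
.edge_hash <- function(i, j, salt = 1) {
  x <- sin(i * 12.9898 + j * 78.233 + salt * 37.719) * 43758.5453
  x - floor(x)
}

# deterministic per-subject seed below 2^31
.subject_seed <- function(rng_seed, subject_index) {
  as.integer((as.numeric(rng_seed) %% 1912393L) * 1117L + subject_index)
}

# inverse-CDF truncated normal on (0, 1), vectorized over mean and sd;
# sd = 0 degenerates to the mean
.rtrunc01 <- function(u, mean, sd) {
  k <- max(length(u), length(mean), length(sd))
  u <- rep_len(u, k); mean <- rep_len(mean, k); sd <- rep_len(sd, k)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    lo <- stats::pnorm(0, mean[pos], sd[pos])
    hi <- stats::pnorm(1, mean[pos], sd[pos])
    out[pos] <- stats::qnorm(lo + u[pos] * (hi - lo), mean[pos], sd[pos])
  }
  out
}

#' Sample one subject connectome from a template
#'
#' Each template edge is retained independently with probability
#' \code{presence_prob * edge_consistency[tract_tag]}; a retained edge's
#' weight is drawn from a normal distribution about the template mean with
#' the template's per-edge standard deviation, truncated to (0, 1). The draw
#' is a pure function of \code{(rng_seed, subject_index)}.
#'
#' @param template From [build_template()].
#' @param config A [cohort_config()].
#' @param subject_index 1-based subject number within the cohort.
#' @return A symmetric, zero-diagonal numeric weight matrix with node labels
#'   as dimnames.
#' @export
sample_individual <- function(template, config, subject_index) {
  parc <- template$parcellation
  cons <- .resolve_consistency(template$condition, config)
  ed <- template$edges
  seed <- .subject_seed(config$rng_seed, subject_index)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  u_keep <- stats::runif(nrow(ed))
  u_w <- stats::runif(nrow(ed))

  p_keep <- ed$presence_prob * unname(cons[ed$tract_tag])
  keep <- u_keep < p_keep
  sd_e <- if (is.null(ed$weight_sd)) config$weight_sd else ed$weight_sd
  w <- .rtrunc01(u_w, ed$mean_weight, sd_e)

  n <- nrow(parc)
  W <- matrix(0, n, n, dimnames = list(parc$label, parc$label))
  W[cbind(ed$i[keep], ed$j[keep])] <- w[keep]
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

#' Generate a cohort of synthetic connectomes for one callosal condition
#'
#' Samples \code{config$n_subjects} connectomes from the condition template.
#' The virtual-callosotomy cohort is derived from the normal template with the
#' same seeds and the callosal edges zeroed afterwards, so that its
#' intrahemispheric (and non-callosal commissural) entries are identical to
#' the paired normal cohort — the in-silico control of a midsagittal callosal
#' exclusion without compensatory rewiring.
#'
#' @param condition Callosal condition (see [build_template()]).
#' @param config A [cohort_config()].
#' @param parc Optional parcellation; built if missing.
#' @return A list of class \code{ccd_cohort}: \code{condition},
#'   \code{parcellation}, \code{template}, \code{config}, \code{subjects}
#'   (list of weight matrices), \code{subject_seeds}, and \code{metadata}
#'   (for partial CCD: integer vector \code{sigmoid_carriers} of subjects
#'   carrying the primary sigmoid edge).
#' @export
generate_cohort <- function(condition, config = cohort_config(), parc = NULL) {
  condition <- match.arg(condition, .CONDITIONS)
  if (is.null(parc)) parc <- build_parcellation()
  stopifnot(config$n_subjects >= 2)

  sample_cond <- if (condition == "virtual_callosotomy") "normal_cc" else condition
  template <- build_template(parc, sample_cond, config)
  seeds <- vapply(seq_len(config$n_subjects), .subject_seed,
                  integer(1), rng_seed = config$rng_seed)
  subjects <- lapply(seq_len(config$n_subjects), function(s)
    sample_individual(template, config, s))

  if (condition == "virtual_callosotomy") {
    cc <- template$edges[template$edges$tract_tag == "cc", c("i", "j")]
    subjects <- lapply(subjects, virtual_callosotomy, cc_edges = cc)
    template$condition <- "virtual_callosotomy"
  }

  meta <- list()
  if (condition == "partial_ccd") {
    iFra <- .node_idx(parc, "Fra", "L"); jHp <- .node_idx(parc, "Hp", "R")
    meta$sigmoid_carriers <- which(vapply(subjects, function(W)
      W[iFra, jHp] > 0, logical(1)))
    meta$sigmoid_edge <- c(parc$label[iFra], parc$label[jHp])
  }

  structure(list(condition = condition, parcellation = parc,
                 template = template, config = config, subjects = subjects,
                 subject_seeds = seeds, metadata = meta),
            class = "ccd_cohort")
}

#' @export
print.ccd_cohort <- function(x, ...) {
  cat("Synthetic connectome cohort:", x$condition, "\n")
  cat("  subjects:", length(x$subjects),
      " nodes:", nrow(x$parcellation),
      " master seed:", x$config$rng_seed, "\n")
  dens <- vapply(x$subjects, function(W) mean(W[upper.tri(W)] > 0), numeric(1))
  cat(sprintf("  mean edge density: %.3f\n", mean(dens)))
  if (length(x$metadata$sigmoid_carriers))
    cat("  sigmoid-bundle carriers:",
        paste(x$metadata$sigmoid_carriers, collapse = ", "), "\n")
  invisible(x)
}
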