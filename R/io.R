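# File interchange: labeled CSV weight matrices, node table TSV, GraphML
# export, cohort directories with JSON metadata, and the end-to-end pipeline.

#' Write a connectome as a labeled CSV matrix
#'
#' @param W Weight matrix (or consensus object) with node labels as dimnames.
#' @param path Output file.
#' @export
write_connectome <- function(W, path) {
  W <- .as_weights(W)
  utils::write.csv(as.data.frame(W), path, row.names = TRUE)
  invisible(path)
}

#' Read a connectome from a labeled CSV matrix
#'
#' Validates shape and content: the matrix must be square, non-negative,
#' symmetric within \code{tol} (then symmetrized exactly as the mean of the
#' two triangles) with a zero diagonal, and its labels must match the node
#' table when one is given.
#'
#' @param path CSV file with a header row and row labels in the first column.
#' @param node_table Optional parcellation/node table; labels must match its
#'   \code{label} column in order.
#' @param tol Asymmetry tolerance (default 1e-9).
#' @return Numeric weight matrix.
#' @export
read_connectome <- function(path, node_table = NULL, tol = 1e-9) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  W <- as.matrix(df)
  if (nrow(W) != ncol(W))
    stop("connectome matrix is not square: ", nrow(W), " x ", ncol(W))
  if (!identical(rownames(W), colnames(W)))
    stop("row and column labels disagree")
  if (!is.null(node_table) && !identical(rownames(W), node_table$label))
    stop("matrix labels do not match the node table")
  if (any(W < 0)) stop("negative weights are not allowed")
  if (max(abs(W - t(W))) > tol)
    stop("matrix asymmetric beyond tolerance ", tol)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

#' Write the node table as TSV
#'
#' @param parc Parcellation from [build_parcellation()].
#' @param path Output file.
#' @export
write_node_table <- function(parc, path) {
  utils::write.table(as.data.frame(parc), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a node table TSV
#'
#' @param path File written by [write_node_table()].
#' @return A \code{ccd_parcellation} data frame.
#' @export
read_node_table <- function(path) {
  parc <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(parc) <- c("ccd_parcellation", "data.frame")
  parc
}

#' Export a connectome to GraphML
#'
#' Writes a GraphML graph with edge weights and, when available, node
#' attributes: hemisphere, lobe, module assignment, degree, strength and
#' participation coefficient.
#'
#' @param W Weight matrix (or consensus object).
#' @param path Output file.
#' @param parc Optional parcellation for node attributes.
#' @param partition Optional \code{ccd_partition}; adds module and
#'   participation attributes.
#' @export
write_graphml <- function(W, path, parc = NULL, partition = NULL) {
  W <- .as_weights(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(nrow(W)))
  if (!is.null(parc)) {
    igraph::V(g)$hemisphere <- parc$hemisphere
    igraph::V(g)$lobe <- parc$lobe
  }
  igraph::V(g)$degree <- unname(rowSums(W > 0))
  igraph::V(g)$strength <- unname(rowSums(W))
  if (!is.null(partition)) {
    memb <- if (inherits(partition, "ccd_partition")) partition$membership else partition
    igraph::V(g)$module <- as.integer(unname(memb))
    igraph::V(g)$participation <- unname(participation(W, memb))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a cohort to a directory
#'
#' Emits one CSV weight matrix per subject, the node table TSV, and a JSON
#' metadata file recording the condition, seeds, template edge list with
#' tract tags, and generator config.
#'
#' @param cohort A \code{ccd_cohort}.
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_along(cohort$subjects))
    write_connectome(cohort$subjects[[s]],
                     file.path(dir, sprintf("subject_%02d.csv", s)))
  write_node_table(cohort$parcellation, file.path(dir, "nodes.tsv"))
  meta <- list(condition = cohort$condition,
               n_subjects = length(cohort$subjects),
               rng_seed = cohort$config$rng_seed,
               subject_seeds = cohort$subject_seeds,
               metadata = cohort$metadata,
               template_edges = cohort$template$edges)
  jsonlite::write_json(meta, file.path(dir, "cohort.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A \code{ccd_cohort} (template carries the stored edge list only).
#' @export
read_cohort <- function(dir) {
  parc <- read_node_table(file.path(dir, "nodes.tsv"))
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^subject_\\d+\\.csv$",
                           full.names = TRUE))
  subjects <- lapply(files, read_connectome, node_table = parc)
  template <- list(parcellation = parc, condition = meta$condition,
                   edges = as.data.frame(meta$template_edges))
  class(template) <- "ccd_template"
  structure(list(condition = meta$condition, parcellation = parc,
                 template = template, config = NULL, subjects = subjects,
                 subject_seeds = meta$subject_seeds,
                 metadata = meta$metadata %||% list()),
            class = "ccd_cohort")
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Orchestrates the whole workflow: cohort simulation for the four callosal
#' conditions, consensus connectomes, metric AUC tables and group
#' comparisons, community detection and hub classification on the consensus
#' networks, the NBS threshold sweep for each requested contrast, pairwise
#' similarity by edge class, and novel-edge discovery for the CCD conditions
#' against normal controls. All artifacts plus a run manifest (config
#' snapshot, seed, package version, output hashes) are written under
#' \code{out_dir}.
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every stochastic stage.
#' @param config An [analysis_config()].
#' @param cohort_cfg A [cohort_config()] template; its \code{rng_seed} is
#'   replaced by \code{seed}.
#' @param contrasts List of NBS contrasts, each
#'   \code{list(a = condition, b = condition, direction)}.
#' @param verbose Log stage boundaries.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1L, config = analysis_config(),
                         cohort_cfg = cohort_config(),
                         contrasts = list(
                           list(a = "complete_ccd", b = "normal_cc",
                                direction = "b_gt_a"),
                           list(a = "partial_ccd", b = "normal_cc",
                                direction = "b_gt_a")),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[ccdnet] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_cfg$rng_seed <- as.integer(seed)
  parc <- build_parcellation()

  say("simulating cohorts")
  conds <- .CONDITIONS
  cohorts <- lapply(conds, generate_cohort, config = cohort_cfg, parc = parc)
  names(cohorts) <- conds
  for (cn in conds) write_cohort(cohorts[[cn]], file.path(out_dir, cn))

  say("consensus connectomes")
  consensus <- lapply(cohorts, build_consensus,
                      min_fraction = config$consensus_fraction)
  for (cn in conds)
    write_connectome(consensus[[cn]],
                     file.path(out_dir, paste0("consensus_", cn, ".csv")))

  say("metric AUC tables")
  aucs <- lapply(cohorts, auc_table, config = config)
  for (cn in conds)
    utils::write.table(aucs[[cn]], file.path(out_dir, paste0("auc_", cn, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  say("group comparisons of AUCs")
  comparisons <- list()
  for (cn in setdiff(conds, "normal_cc"))
    comparisons[[paste0(cn, "_vs_normal_cc")]] <-
      compare_groups_auc(aucs[[cn]], aucs$normal_cc, alpha = config$alpha)

  say("community structure and hubs")
  hubs <- list(); partitions <- list()
  for (cn in conds) {
    part <- louvain(consensus[[cn]], gamma = config$gamma, seed = seed)
    tbl <- classify_hubs(hub_table(consensus[[cn]], part))
    partitions[[cn]] <- part
    hubs[[cn]] <- c(degree_participation_correlation(tbl),
                    q = part$q, n_modules = part$n_modules)
    utils::write.table(tbl, file.path(out_dir, paste0("hubs_", cn, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_graphml(consensus[[cn]],
                  file.path(out_dir, paste0("consensus_", cn, ".graphml")),
                  parc = parc, partition = part)
  }

  say("NBS threshold sweeps")
  nbs <- list()
  for (ct in contrasts) {
    key <- paste0(ct$a, "_", ct$direction, "_", ct$b)
    sw <- threshold_sweep(cohorts[[ct$a]], cohorts[[ct$b]],
                          thresholds = config$nbs_thresholds,
                          n_perm = config$nbs_permutations,
                          seed = seed, direction = ct$direction,
                          alpha = config$alpha)
    utils::write.csv(as.data.frame(sw$counts),
                     file.path(out_dir, paste0("nbs_counts_", key, ".csv")))
    nbs[[key]] <- lapply(sw$results, function(r)
      list(t_star = r$t_star,
           components = lapply(r$components, function(cm)
             cm[c("size", "p", "significant")])))
  }

  say("pairwise similarity")
  similarity <- list()
  for (cn in conds)
    for (cl in c("whole", "inter", "intra")) {
      rep <- pairwise_similarity(cohorts[[cn]], cl)
      similarity[[paste0(cn, "_", cl)]] <-
        list(mean = rep$mean, sem = rep$sem)
    }

  say("novel-edge discovery")
  novelty <- list()
  for (cn in c("complete_ccd", "partial_ccd")) {
    nv <- discover_novel_edges(cohorts[[cn]], cohorts$normal_cc,
                               min_count = config$novelty_min_count,
                               consensus_fraction = config$consensus_fraction)
    utils::write.table(nv$novel,
                       file.path(out_dir, paste0("novel_", cn, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    novelty[[cn]] <- list(n_novel = nv$n_novel, n_preserved = nv$n_preserved)
  }

  say("writing manifest")
  report <- list(comparisons = comparisons, hubs = hubs, nbs = nbs,
                 similarity = similarity, novelty = novelty)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  rel <- list.files(out_dir, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ccdnet")),
    seed = seed,
    analysis_config = unclass(config),
    cohort_config = unclass(cohort_cfg),
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(file.path(out_dir, rel)))), rel))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Load an analysis configuration from YAML
#'
#' Reads a YAML file whose keys match the arguments of [analysis_config()]
#' and/or [cohort_config()].
#'
#' @param path YAML file.
#' @return List with elements \code{analysis} and \code{cohort}.
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  an <- y[intersect(names(y), names(formals(analysis_config)))]
  co <- y[intersect(names(y), names(formals(cohort_config)))]
  list(analysis = do.call(analysis_config, an),
       cohort = do.call(cohort_config, co))
}
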