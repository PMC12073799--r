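# 38-area adult mouse brain atlas table, mirrored into left and right
# hemispheres for a 76-node parcellation. Order is fixed (atlas order) and is
# the canonical node order used by every matrix in the package: all left
# hemisphere nodes first, then all right, atlas order within hemisphere.

.atlas_areas <- function() {
  # name, abbreviation, lobe group, cortical flag, anteroposterior rank
  # (1 = most anterior; used to bias callosal-remnant selection anteriorly)
  tab <- list(
    list("Subiculum",                          "Sub",  "hippocampal", TRUE,  30),
    list("Entorhinal cortex",                  "Ent",  "hippocampal", TRUE,  28),
    list("Dorsolateral orbital cortex",        "Dlo",  "frontal",     TRUE,   2),
    list("Frontal association cortex",         "Fra",  "frontal",     TRUE,   1),
    list("Lateral orbital cortex",             "Lo",   "frontal",     TRUE,   3),
    list("Primary motor cortex",               "M1",   "frontal",     TRUE,   6),
    list("Secondary motor cortex",             "M2",   "frontal",     TRUE,   5),
    list("Ventromedial orbital cortex",        "Vmo",  "frontal",     TRUE,   4),
    list("Parietal association cortex",        "Pa",   "parietal",    TRUE,  16),
    list("Primary somatosensory cortex",       "S1",   "parietal",    TRUE,  14),
    list("Secondary somatosensory cortex",     "S2",   "parietal",    TRUE,  15),
    list("Primary auditory cortex",            "A1",   "temporal",    TRUE,  22),
    list("Secondary auditory cortex",          "A2",   "temporal",    TRUE,  23),
    list("Temporal association area",          "Ta",   "temporal",    TRUE,  24),
    list("Primary visual cortex",              "V1",   "occipital",   TRUE,  25),
    list("Secondary visual cortex lateral",    "V2l",  "occipital",   TRUE,  26),
    list("Secondary visual cortex mediolateral","V2ml","occipital",   TRUE,  27),
    list("Anterior cingulate",                 "Ac",   "frontal",     TRUE,   7),
    list("Retrosplenial area",                 "Rs",   "occipital",   TRUE,  21),
    list("Insular cortex",                     "In",   "lateral",     TRUE,  12),
    list("Ectorhinal cortex",                  "Ect",  "temporal",    TRUE,  29),
    list("Perirhinal cortex",                  "Pr",   "temporal",    TRUE,  31),
    list("Claustrum",                          "Cl",   "lateral",     TRUE,  11),
    list("Endopiriform nucleus",               "End",  "lateral",     TRUE,  13),
    list("Piriform nucleus",                   "Pir",  "lateral",     TRUE,  10),
    list("Amygdala",                           "Am",   "hippocampal", TRUE,  26),
    list("Hippocampus",                        "Hp",   "hippocampal", TRUE,  23),
    list("Caudate putamen",                    "Cp",   "subcortical", FALSE, 17),
    list("Lateral globus pallidus",            "Lgp",  "subcortical", FALSE, 18),
    list("Olfactory bulb",                     "Ob",   "subcortical", FALSE,  8),
    list("Accumbens nucleus",                  "An",   "subcortical", FALSE,  9),
    list("Hypothalamus",                       "Hyp",  "subcortical", FALSE, 20),
    list("Septum",                             "Sep",  "subcortical", FALSE, 19),
    list("Thalamus",                           "Thal", "subcortical", FALSE, 22),
    list("Superior colliculus",                "Sc",   "midbrain",    FALSE, 32),
    list("Inferior colliculus",                "Ic",   "midbrain",    FALSE, 33),
    list("Periaqueductal grey",                "Pag",  "midbrain",    FALSE, 34),
    list("Cerebellum",                         "Cb",   "cerebellum",  FALSE, 38)
  )
  data.frame(
    name        = vapply(tab, `[[`, character(1), 1L),
    abbrev      = vapply(tab, `[[`, character(1), 2L),
    lobe        = vapply(tab, `[[`, character(1), 3L),
    is_cortical = vapply(tab, `[[`, logical(1), 4L),
    ap_rank     = vapply(tab, function(x) as.numeric(x[[5L]]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Build the 76-region bilateral mouse brain parcellation
#'
#' Mirrors the packaged 38-area adult mouse brain atlas table into left and
#' right hemispheres, giving the 76-node parcellation on which all connectomes
#' in this package are defined. Node order is canonical: the 38 left-hemisphere
#' regions in atlas order, followed by their right-hemisphere homotopes in the
#' same order, so node \code{i} (left) always has homotopic partner
#' \code{i + 38} (right).
#'
#' @return A data frame of class \code{ccd_parcellation} with one row per node
#'   and columns \code{region_id} (1-76), \code{name}, \code{abbrev} (atlas
#'   abbreviation), \code{label} (abbreviation plus hemisphere suffix, e.g.
#'   \code{"Fra_L"}), \code{hemisphere} (\code{"L"} or \code{"R"}),
#'   \code{lobe} (lobe-group label), \code{is_cortical}, and \code{ap_rank}
#'   (ordinal anteroposterior position, 1 = most anterior).
#' @examples
#' parc <- build_parcellation()
#' nrow(parc)                    # 76
#' table(parc$hemisphere)        # 38 L, 38 R
#' @export
build_parcellation <- function() {
  areas <- .atlas_areas()
  n <- nrow(areas)
  parc <- rbind(areas, areas)
  parc$hemisphere <- rep(c("L", "R"), each = n)
  parc$region_id <- seq_len(2L * n)
  parc$label <- paste(parc$abbrev, parc$hemisphere, sep = "_")
  rownames(parc) <- NULL
  parc <- parc[, c("region_id", "name", "abbrev", "label", "hemisphere",
                   "lobe", "is_cortical", "ap_rank")]
  class(parc) <- c("ccd_parcellation", "data.frame")
  parc
}

#' Index of the homotopic partner of each node
#'
#' @param parc A parcellation from [build_parcellation()].
#' @return Integer vector \code{p} with \code{p[i]} the row index of node
#'   \code{i}'s homotopic partner in the opposite hemisphere.
#' @export
homotopic_partner <- function(parc) {
  n2 <- nrow(parc) %/% 2L
  c(seq_len(n2) + n2, seq_len(n2))
}

#' Classify an edge as interhemispheric or intrahemispheric
#'
#' @param parc A parcellation from [build_parcellation()].
#' @param i,j Node indices (or labels) of the edge endpoints; must differ.
#' @return \code{"interhemispheric"} if the endpoints lie in different
#'   hemispheres, otherwise \code{"intrahemispheric"}.
#' @export
classify_edge <- function(parc, i, j) {
  if (is.character(i)) i <- match(i, parc$label)
  if (is.character(j)) j <- match(j, parc$label)
  if (any(is.na(i)) || any(is.na(j))) stop("unknown node label")
  if (any(i == j)) stop("self-edges cannot be classified")
  ifelse(parc$hemisphere[i] != parc$hemisphere[j],
         "interhemispheric", "intrahemispheric")
}

#' @export
print.ccd_parcellation <- function(x, ...) {
  cat("Bilateral mouse brain parcellation:", nrow(x), "regions (",
      sum(x$hemisphere == "L"), "per hemisphere )\n")
  cat("Lobe groups:", paste(unique(x$lobe), collapse = ", "), "\n")
  invisible(x)
}
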