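#' Maximal single-species clades of a species-labeled gene tree
#'
#' A maximal single-species clade is a clade (possibly a single leaf)
#' whose leaves all belong to one species and whose parent clade contains
#' another species. Every leaf belongs to exactly one such clade; these
#' clades are the shared substrate of the duplication and HGT callers.
#'
#' @param tree Rooted [ape::phylo]; leaves are gene ids.
#' @param species_map Named character vector gene id -> species id
#'   covering every leaf (see [read_species_map()]).
#' @return Data frame with columns `species_id`, `node` (internal node or
#'   tip index), `size`, and a list-column `leaf_ids`.
#' @export
maximal_species_clades <- function(tree, species_map) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("gene ids must be unique")
  sp <- tip_species(tree, species_map)
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  # species of each node if its clade is single-species, else NA
  mono <- rep(NA_character_, n)
  mono[seq_len(ntip)] <- sp
  eo <- ape::reorder.phylo(tree, "postorder")
  kids <- split(eo$edge[, 2L], eo$edge[, 1L])
  for (p in unique(eo$edge[, 1L])) {
    s <- unique(mono[kids[[as.character(p)]]])
    if (length(s) == 1L && !is.na(s)) mono[p] <- s
  }
  parent <- node_parents(tree)
  maximal <- !is.na(mono) & (is.na(parent) | is.na(mono[pmax(parent, 1L)]))
  # pmax guard only feeds the subscript; root (parent NA) is maximal if mono
  idx <- which(maximal)
  tipsets <- node_tip_sets(tree)
  data.frame(
    species_id = mono[idx],
    node = idx,
    size = vapply(tipsets[idx], length, 1L),
    leaf_ids = I(lapply(tipsets[idx], function(s) tree$tip.label[s])),
    stringsAsFactors = FALSE
  )
}

#' Call gene-duplication events from a species-labeled gene tree
#'
#' Duplication events are called where genes of one species form a
#' monophyletic group: each maximal single-species clade of two or more
#' genes is duplication-derived. Two tallies are offered, because a clade
#' of n genes can be read either as n-1 duplication events (one per
#' internal bifurcation; `mode = "node_count"`, the default) or as a
#' single expansion event (`mode = "per_clade"`).
#'
#' @inheritParams maximal_species_clades
#' @param mode `"node_count"` or `"per_clade"`.
#' @return Data frame with columns `species_id`, `size`, `n_events`, and
#'   list-column `leaf_ids`; one row per qualifying clade.
#' @export
call_duplications <- function(tree, species_map, mode = c("node_count", "per_clade")) {
  mode <- match.arg(mode)
  cl <- maximal_species_clades(tree, species_map)
  cl <- cl[cl$size >= 2L, , drop = FALSE]
  cl$n_events <- if (mode == "node_count") cl$size - 1L else rep(1L, nrow(cl))
  rownames(cl) <- NULL
  cl[, c("species_id", "size", "n_events", "leaf_ids")]
}

#' Call directed horizontal-gene-transfer events from a gene tree
#'
#' An HGT event is inferred when the gene diversity of one species falls
#' within that of another: a maximal single-species clade (the putative
#' recipient) whose successive enclosing clades add only genes of one
#' single other species (the putative donor). `context_depth` sets how
#' many consecutive enclosing clades must be donor-pure; the default of 2
#' reads "falls within" as two-sided nesting rather than mere sisterhood,
#' and raising it makes calls strictly more conservative.
#'
#' @inheritParams maximal_species_clades
#' @param context_depth Integer >= 1; number of consecutive enclosing
#'   clades that must each add genes of the same single donor species.
#' @param min_support Suppress events whose defining nodes (the recipient
#'   clade node and its `context_depth` ancestors) carry a support value
#'   below this threshold; 0 (default) disables the filter. Nodes without
#'   a numeric support label are never suppressed.
#' @param min_recipient_size Minimum recipient clade size (default 1; set
#'   2 to require that the transferred gene has duplicated in the
#'   recipient).
#' @return Data frame with columns `donor_species`, `recipient_species`,
#'   `context_depth`, `size`, and list-column `recipient_leaf_ids`.
#' @export
call_hgt <- function(tree, species_map, context_depth = 2L, min_support = 0,
                     min_recipient_size = 1L) {
  if (context_depth < 1L) stop("context_depth must be >= 1")
  cl <- maximal_species_clades(tree, species_map)
  parent <- node_parents(tree)
  tipsets <- node_tip_sets(tree)
  sp <- tip_species(tree, species_map)
  sup <- node_supports(tree)
  ntip <- length(tree$tip.label)

  res <- list()
  for (i in seq_len(nrow(cl))) {
    if (cl$size[i] < min_recipient_size) next
    a <- cl$species_id[i]
    node <- cl$node[i]
    prev <- tipsets[[node]]
    donor <- NA_character_
    ok <- TRUE
    path_nodes <- node
    for (d in seq_len(context_depth)) {
      p <- parent[node]
      if (is.na(p)) { ok <- FALSE; break }
      added <- setdiff(tipsets[[p]], prev)
      s <- unique(sp[added])
      if (length(s) != 1L || s == a || (!is.na(donor) && s != donor)) {
        ok <- FALSE; break
      }
      donor <- s
      prev <- tipsets[[p]]
      node <- p
      path_nodes <- c(path_nodes, p)
    }
    if (!ok) next
    if (min_support > 0) {
      s <- sup[path_nodes[path_nodes > ntip]]
      if (any(!is.na(s) & s < min_support)) next
    }
    res[[length(res) + 1L]] <- data.frame(
      donor_species = donor, recipient_species = a,
      context_depth = as.integer(context_depth), size = cl$size[i],
      recipient_leaf_ids = I(cl$leaf_ids[i]),
      stringsAsFactors = FALSE
    )
  }
  if (!length(res))
    return(data.frame(donor_species = character(), recipient_species = character(),
                      context_depth = integer(), size = integer(),
                      recipient_leaf_ids = I(list()), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Tabulate HGT events as a donor-by-recipient matrix
#'
#' @param events Data frame from [call_hgt()] (columns `donor_species`,
#'   `recipient_species`).
#' @param species Ordered character vector of species ids for the matrix
#'   dimensions; every event species must appear in it.
#' @return Square integer matrix; entry `[donor, recipient]` counts
#'   events, diagonal zero.
#' @export
hgt_matrix <- function(events, species) {
  species <- as.character(species)
  unknown <- setdiff(c(events$donor_species, events$recipient_species), species)
  if (length(unknown))
    stop("unknown species in events: ", paste(unknown, collapse = ", "))
  m <- matrix(0L, length(species), length(species),
              dimnames = list(donor = species, recipient = species))
  for (i in seq_len(nrow(events)))
    m[events$donor_species[i], events$recipient_species[i]] <-
      m[events$donor_species[i], events$recipient_species[i]] + 1L
  m
}
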