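# Internal tree helpers shared by the phylogenetic screen and event callers.

# Tip-index sets for every node (tips and internals), postorder accumulation.
node_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# parent[node] for every node index; NA at the root.
node_parents <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

# Numeric support value per node index (NA where absent/unparseable).
node_supports <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  sup <- rep(NA_real_, n)
  if (!is.null(tree$node.label)) {
    v <- suppressWarnings(as.numeric(tree$node.label))
    sup[(ntip + 1L):n] <- v
  }
  sup
}

# Species id per tip, checking the map covers the tree.
tip_species <- function(tree, species_map) {
  sp <- species_map[tree$tip.label]
  if (anyNA(sp) || any(!nzchar(sp)))
    stop("unlabeled leaf (no species for): ",
         paste(utils::head(tree$tip.label[is.na(sp) | !nzchar(sp)], 5),
               collapse = ", "))
  unname(sp)
}
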