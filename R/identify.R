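#' Merge HMM and BLAST candidate sets
#'
#' NLR candidates are typically collected twice — once by an NB-ARC
#' profile-HMM search and once by BLASTP against reference NLR proteins —
#' and the two hit lists are merged with redundant identifiers removed.
#'
#' @param hmm_ids,blast_ids Character vectors of protein ids.
#' @return Character vector: the union, each id once, HMM ids first.
#' @export
merge_candidates <- function(hmm_ids, blast_ids) {
  unique(c(as.character(hmm_ids), as.character(blast_ids)))
}

#' Classify NLR domain architectures into TNL/CNL/RNL/NL
#'
#' Applies the standard N-terminal-domain classification of plant NLRs:
#' proteins lacking the NB-ARC nucleotide-binding domain are not NLRs;
#' among NB-ARC proteins, a TIR domain gives TNL, an RPW8 domain gives
#' RNL, an Rx_N domain (the four-helix bundle annotated in place of the
#' coiled-coil motif) gives CNL, and proteins with none of the three are
#' NL. LRR presence is recorded upstream but does not affect the class:
#' NL covers both NBS-only and NBS-LRR architectures.
#'
#' When a protein carries more than one N-terminal domain the precedence
#' TIR > RPW8 > Rx_N applies, keeping the partition total and
#' deterministic; such dual-domain proteins can be flagged with
#' [architecture_table()].
#'
#' @param has_nbarc,has_tir,has_rpw8,has_rxn Logical vectors (recycled to
#'   a common length) indicating domain presence.
#' @return Character vector over `{"TNL","CNL","RNL","NL","NOT_NLR"}`.
#' @examples
#' classify_architecture(TRUE, TRUE, FALSE, FALSE)   # "TNL"
#' classify_architecture(TRUE, FALSE, FALSE, FALSE)  # "NL"
#' classify_architecture(FALSE, FALSE, FALSE, TRUE)  # "NOT_NLR"
#' @export
classify_architecture <- function(has_nbarc, has_tir = FALSE, has_rpw8 = FALSE,
                                  has_rxn = FALSE) {
  n <- max(length(has_nbarc), length(has_tir), length(has_rpw8), length(has_rxn))
  has_nbarc <- rep_len(as.logical(has_nbarc), n)
  has_tir <- rep_len(as.logical(has_tir), n)
  has_rpw8 <- rep_len(as.logical(has_rpw8), n)
  has_rxn <- rep_len(as.logical(has_rxn), n)
  out <- rep("NL", n)
  out[has_rxn] <- "CNL"
  out[has_rpw8] <- "RNL"
  out[has_tir] <- "TNL"
  out[!has_nbarc] <- "NOT_NLR"
  out
}

#' Summarise domain hits into per-protein architectures
#'
#' Collapses a domain-hit table (see [read_domain_table()]) into one row
#' per protein with domain-presence booleans, the assigned NLR class, and
#' a flag for proteins carrying more than one N-terminal domain type
#' (TIR/RPW8/Rx_N), for which the fixed precedence TIR > RPW8 > Rx_N
#' decided the class.
#'
#' Domain names are matched case-insensitively; `"NB-ARC"`/`"NBS"`,
#' `"TIR"`, `"RPW8"`, `"Rx_N"`/`"RX-N"`, and `"LRR"` (any name containing
#' "LRR") are recognised.
#'
#' @param hits Data frame with columns `protein_id` and `domain_name`.
#' @param protein_ids Optional character vector of proteins to report on
#'   (proteins without hits get all-FALSE rows); defaults to the proteins
#'   present in `hits`.
#' @return Data frame with columns `protein_id`, `has_nbarc`, `has_tir`,
#'   `has_rpw8`, `has_rxn`, `has_lrr`, `class`, `dual_domain`.
#' @export
architecture_table <- function(hits, protein_ids = NULL) {
  stopifnot(is.data.frame(hits), all(c("protein_id", "domain_name") %in% names(hits)))
  if (is.null(protein_ids)) protein_ids <- unique(hits$protein_id)
  dom <- toupper(gsub("[^A-Za-z0-9]", "", hits$domain_name))
  kind <- rep(NA_character_, length(dom))
  kind[dom %in% c("NBARC", "NBS")] <- "nbarc"
  kind[dom == "TIR"] <- "tir"
  kind[dom == "RPW8"] <- "rpw8"
  kind[dom %in% c("RXN", "RX")] <- "rxn"
  kind[grepl("LRR", dom)] <- "lrr"
  has <- function(k) protein_ids %in% hits$protein_id[!is.na(kind) & kind == k]
  out <- data.frame(
    protein_id = protein_ids,
    has_nbarc = has("nbarc"), has_tir = has("tir"), has_rpw8 = has("rpw8"),
    has_rxn = has("rxn"), has_lrr = has("lrr"),
    stringsAsFactors = FALSE
  )
  out$class <- classify_architecture(out$has_nbarc, out$has_tir, out$has_rpw8,
                                     out$has_rxn)
  out$dual_domain <- (out$has_tir + out$has_rpw8 + out$has_rxn) > 1L
  out
}

#' Screen candidates by phylogenetic placement among plant R proteins
#'
#' Given a rooted reference tree whose leaves are candidate proteins plus
#' reference sequences labeled `plant_R`, `non_plant` or `outgroup`, a
#' candidate is retained when it clusters with plant R proteins rather
#' than with non-plant NB-ARC homologs. In the default strict mode the
#' rule is: find the smallest clade containing the candidate and at least
#' one reference leaf (`plant_R` or `non_plant`); retain the candidate iff
#' that clade contains no `non_plant` reference. In permissive mode a
#' candidate is retained if any enclosing clade up to the root consists
#' purely of candidates and `plant_R` references (with at least one
#' `plant_R`).
#'
#' @param tree Rooted [ape::phylo] with every leaf labeled in `labels`.
#' @param labels Data frame with columns `leaf_id` and `label`
#'   (`candidate`, `plant_R`, `non_plant` or `outgroup`), or a named
#'   character vector of labels.
#' @param mode `"strict"` (default) or `"permissive"`.
#' @return Character vector of retained candidate leaf ids.
#' @export
filter_by_phylogeny <- function(tree, labels, mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(labels)) {
    stopifnot(all(c("leaf_id", "label") %in% names(labels)))
    lab <- stats::setNames(as.character(labels$label), labels$leaf_id)
  } else {
    lab <- labels
  }
  tips <- tree$tip.label
  missing <- setdiff(tips, names(lab))
  if (length(missing))
    stop("missing label for leaf: ", paste(utils::head(missing, 5), collapse = ", "))
  lab <- lab[tips]
  bad <- !lab %in% c("candidate", "plant_R", "non_plant", "outgroup")
  if (any(bad)) stop("unknown label: ", paste(unique(lab[bad]), collapse = ", "))
  is_ref <- lab %in% c("plant_R", "non_plant")
  if (!any(is_ref)) stop("tree contains no reference leaves (plant_R/non_plant)")

  tipsets <- node_tip_sets(tree)
  parent <- node_parents(tree)
  ntip <- length(tips)
  cand_idx <- which(lab == "candidate")
  keep <- logical(length(cand_idx))
  for (i in seq_along(cand_idx)) {
    node <- cand_idx[i]
    repeat {
      node <- parent[node]
      if (is.na(node)) break
      members <- tipsets[[node]]
      mlab <- lab[members]
      if (mode == "strict") {
        if (any(mlab %in% c("plant_R", "non_plant"))) {
          keep[i] <- !any(mlab == "non_plant")
          break
        }
      } else {
        if (any(mlab == "plant_R") &&
            all(mlab %in% c("candidate", "plant_R"))) {
          keep[i] <- TRUE
          break
        }
        if (node == ntip + 1L && !keep[i]) break
      }
    }
  }
  tips[cand_idx[keep]]
}

#' Keep the longest isoform per locus
#'
#' Gene models frequently include several alternatively spliced isoforms
#' of one locus; NLR tallies count loci, so one representative protein is
#' kept per locus: the longest, with ties broken by the lexicographically
#' smallest protein id.
#'
#' @param records Data frame with columns `protein_id`, `locus_id`,
#'   `length` (amino-acid length; `locus_id` may equal `protein_id` when
#'   the locus is unknown).
#' @return Character vector of retained protein ids (one per locus, in
#'   order of first locus appearance).
#' @export
drop_redundant_isoforms <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "locus_id", "length") %in% names(records)))
  if (any(records$length < 0)) stop("negative protein length")
  loci <- unique(records$locus_id)
  vapply(loci, function(l) {
    r <- records[records$locus_id == l, , drop = FALSE]
    r <- r[order(-r$length, r$protein_id), , drop = FALSE]
    r$protein_id[1L]
  }, "", USE.NAMES = FALSE)
}
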