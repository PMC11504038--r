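# Shared fixture builders: all fixtures are generated in code at test time.

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A generic domain TSV with given e-values, one NB-ARC row per value.
generic_domain_tsv <- function(evalues, proteins = paste0("p", seq_along(evalues))) {
  write_tmp(c(
    "protein_id\tdomain_name\tenv_start\tenv_end\te_value",
    sprintf("%s\tNB-ARC\t10\t300\t%g", proteins, evalues)
  ), ".tsv")
}

# Minimal hmmscan --domtblout content: 2 comment lines + data rows with
# 22 whitespace fields followed by a free-text description.
hmmscan_domtbl <- function(rows) {
  row_line <- function(domain, protein, ievalue, from, to) {
    paste(domain, "PF00000.1", "200", protein, "-", "900",
          "1e-40", "120.0", "0.1", "1", "1",
          "1e-42", ievalue, "118.0", "0.1",
          "5", "190", "10", "300", from, to, "0.95",
          "some description text")
  }
  write_tmp(c(
    "#                     --- full sequence ---",
    "# target name  accession  tlen query ...",
    vapply(rows, function(r) do.call(row_line, r), "")
  ))
}

blast_tab <- function(queries, subjects, evalues) {
  write_tmp(sprintf(
    "%s\t%s\t95.0\t100\t5\t0\t1\t100\t1\t100\t%g\t200",
    queries, subjects, evalues
  ), ".tsv")
}

# Gene tree + species map from a newick string whose tips are like "a1":
# species is the leading letters.
labeled_tree <- function(newick) {
  tree <- ape::read.tree(text = newick)
  species <- sub("[0-9]+$", "", tree$tip.label)
  list(tree = tree, map = stats::setNames(species, tree$tip.label))
}

# Null alignment for MaxChi calibration: two unrelated descendants of A
# (no recombination) plus A itself as comparison context.
null_maxchi_alignment <- function(len = 300L, divergence = 0.3) {
  bases <- c("A", "C", "G", "T")
  mut <- function(s) {
    h <- stats::runif(length(s)) < divergence
    s[h] <- vapply(s[h], function(b) sample(setdiff(bases, b), 1L), "")
    s
  }
  A <- sample(bases, len, replace = TRUE)
  rbind(A = A, B = mut(A), D = mut(A))
}

# Duplications on the root-to-tip species-tree path of `species`, read
# from a simulator event log (branch labels are tip labels or "anc<node>").
path_dup_count <- function(truth, species) {
  tr <- truth$config$species_tree
  ntip <- length(tr$tip.label)
  parent <- rep(NA_integer_, ntip + tr$Nnode)
  parent[tr$edge[, 2L]] <- tr$edge[, 1L]
  node <- which(tr$tip.label == species)
  labels <- character()
  while (!is.na(parent[node])) {
    labels <- c(labels, if (node <= ntip) tr$tip.label[node] else paste0("anc", node))
    node <- parent[node]
  }
  ev <- truth$event_log
  sum(ev$type == "duplication" & ev$branch %in% labels)
}
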