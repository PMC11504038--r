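#' Default species tree: an ultrametric ladder
#'
#' A caterpillar (ladder) species tree with equally spaced divergences
#' and equal root-to-tip depth, echoing a small clade of closely related
#' genomes. Ten leaves with unit depth is the default study condition.
#'
#' @param n_species Number of leaves (>= 2).
#' @param depth Root-to-tip distance.
#' @param prefix Tip-label prefix; tips are `sp1 ... spN`.
#' @return An [ape::phylo] ultrametric rooted tree.
#' @export
default_species_tree <- function(n_species = 10L, depth = 1, prefix = "sp") {
  stopifnot(n_species >= 2L, depth > 0)
  step <- depth / (n_species - 1L)
  tips <- paste0(prefix, seq_len(n_species))
  # innermost cherry first, then wrap outward
  node_time <- function(k) (k - 1L) * step  # k-th split from the root
  nwk <- sprintf("(%s:%.10g,%s:%.10g)", tips[n_species - 1L], step, tips[n_species], step)
  if (n_species > 2L) {
    for (k in (n_species - 2L):1L) {
      tip_len <- depth - node_time(k)
      nwk <- sprintf("(%s:%.10g,%s:%.10g)", tips[k], tip_len, nwk, step)
    }
  }
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Simulation configuration for the gene-family generator
#'
#' @param species_tree Rooted [ape::phylo] with branch lengths; leaves
#'   are species.
#' @param dup_rate,loss_rate,transfer_rate Per-gene per-unit-branch-length
#'   rates (>= 0) of duplication, loss, and horizontal transfer.
#' @param domain_gain_rates,domain_loss_rates Named numeric vectors with
#'   entries `TIR`, `RPW8`, `Rx_N`, `LRR`: gain/loss rates of each
#'   N-terminal domain (and LRR) along gene-tree branches.
#' @param n_root_genes Number of independent gene lineages at the root.
#' @param seed Integer seed; the same configuration always yields the
#'   same family.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(species_tree = default_species_tree(),
                       dup_rate = 0.3, loss_rate = 0, transfer_rate = 0,
                       domain_gain_rates = c(TIR = 0.1, RPW8 = 0.1, Rx_N = 0.1, LRR = 0.5),
                       domain_loss_rates = c(TIR = 0.3, RPW8 = 0.3, Rx_N = 0.3, LRR = 0.1),
                       n_root_genes = 1L, seed = 1L) {
  stopifnot(inherits(species_tree, "phylo"),
            !is.null(species_tree$edge.length),
            length(species_tree$tip.label) >= 2L,
            dup_rate >= 0, loss_rate >= 0, transfer_rate >= 0,
            n_root_genes >= 1L)
  doms <- c("TIR", "RPW8", "Rx_N", "LRR")
  stopifnot(all(doms %in% names(domain_gain_rates)),
            all(doms %in% names(domain_loss_rates)),
            all(domain_gain_rates >= 0), all(domain_loss_rates >= 0))
  structure(list(species_tree = species_tree, dup_rate = dup_rate,
                 loss_rate = loss_rate, transfer_rate = transfer_rate,
                 domain_gain_rates = domain_gain_rates[doms],
                 domain_loss_rates = domain_loss_rates[doms],
                 n_root_genes = as.integer(n_root_genes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a gene family by a birth-death-transfer process
#'
#' Gene lineages evolve along the branches of the species tree. Each
#' lineage duplicates at rate `dup_rate`, dies at rate `loss_rate`, and
#' at rate `transfer_rate` sends a copy to a uniformly chosen
#' contemporaneous branch of another part of the species tree (the donor
#' lineage continues). At every speciation a lineage copies into both
#' daughter branches. The returned gene tree is pruned to lineages with
#' extant descendants (internal nodes with a single surviving child are
#' collapsed), so with all rates zero and one root gene it is
#' topologically identical to the species tree.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `gene_family_truth`: `gene_tree` ([ape::phylo],
#'   or `NULL` when fewer than two genes survive), `species_map` (named
#'   character vector gene id -> species id over all extant genes),
#'   `event_log` (data frame: `type` in duplication/loss/transfer,
#'   `branch`, `time`, `terminal_branch`, `donor`, `recipient`,
#'   `survived`, list-column `recipient_leaves`), `n_extant`, `config`.
#' @examples
#' fam <- simulate_gene_family(sim_config(dup_rate = 0, seed = 42))
#' fam$n_extant   # one gene per species
#' @export
simulate_gene_family <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tr <- cfg$species_tree
  ntip <- length(tr$tip.label)
  times <- ape::node.depth.edgelength(tr)  # distance from root per node
  edge <- data.frame(
    parent = tr$edge[, 1L], child = tr$edge[, 2L],
    t0 = times[tr$edge[, 1L]], t1 = times[tr$edge[, 2L]]
  )
  edge$is_tip <- edge$child <= ntip
  edge$label <- ifelse(edge$is_tip, tr$tip.label[pmin(edge$child, ntip)],
                       paste0("anc", edge$child))
  lam <- cfg$dup_rate; mu <- cfg$loss_rate; tau <- cfg$transfer_rate
  total <- lam + mu + tau

  st <- new.env(parent = emptyenv())
  st$log <- list()
  st$counts <- stats::setNames(integer(ntip), tr$tip.label)
  st$map <- character()

  collect_leaves <- function(node) {
    if (is.null(node)) return(character())
    if (!is.null(node$label)) return(node$label)
    unlist(lapply(node$children, collect_leaves), use.names = FALSE)
  }
  combine2 <- function(te, a, b) {
    kids <- Filter(Negate(is.null), list(a, b))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    list(time = te, children = kids)
  }
  log_event <- function(...) st$log[[length(st$log) + 1L]] <- list(...)

  sim_from <- function(k, t) {
    t1 <- edge$t1[k]
    repeat {
      w <- if (total > 0) stats::rexp(1L, total) else Inf
      te <- t + w
      if (te >= t1) break
      u <- stats::runif(1L) * total
      if (u < lam) {                      # duplication
        log_event(type = "duplication", branch = edge$label[k], time = te,
                  terminal_branch = edge$is_tip[k], donor = NA_character_,
                  recipient = NA_character_, survived = NA,
                  recipient_leaves = character())
        return(combine2(te, sim_from(k, te), sim_from(k, te)))
      } else if (u < lam + mu) {          # loss
        log_event(type = "loss", branch = edge$label[k], time = te,
                  terminal_branch = edge$is_tip[k], donor = NA_character_,
                  recipient = NA_character_, survived = NA,
                  recipient_leaves = character())
        return(NULL)
      } else {                            # transfer
        cand <- which(edge$t0 < te & te < edge$t1)
        cand <- cand[cand != k]
        if (length(cand) == 0L) { t <- te; next }
        r <- if (length(cand) == 1L) cand else sample(cand, 1L)
        rec <- sim_from(r, te)
        log_event(type = "transfer", branch = edge$label[k], time = te,
                  terminal_branch = edge$is_tip[r], donor = edge$label[k],
                  recipient = edge$label[r], survived = !is.null(rec),
                  recipient_leaves = collect_leaves(rec))
        cont <- sim_from(k, te)
        return(combine2(te, cont, rec))
      }
    }
    if (edge$is_tip[k]) {
      spn <- edge$label[k]
      st$counts[spn] <- st$counts[spn] + 1L
      id <- paste0(spn, "_g", st$counts[spn])
      st$map[id] <- spn
      return(list(time = t1, label = id))
    }
    ce <- which(edge$parent == edge$child[k])
    kids <- Filter(Negate(is.null), lapply(ce, sim_from, t = t1))
    if (length(kids) == 0L) return(NULL)
    if (length(kids) == 1L) return(kids[[1L]])
    list(time = t1, children = kids)
  }

  root <- ntip + 1L
  root_edges <- which(edge$parent == root)
  root_genes <- list()
  for (g in seq_len(cfg$n_root_genes)) {
    kids <- Filter(Negate(is.null), lapply(root_edges, sim_from, t = 0))
    sub <- if (length(kids) == 0L) NULL
           else if (length(kids) == 1L) kids[[1L]]
           else list(time = 0, children = kids)
    if (!is.null(sub)) root_genes[[length(root_genes) + 1L]] <- sub
  }

  fmt <- function(x) sprintf("%.10g", max(x, 0))
  nwk <- function(node, ptime) {
    if (!is.null(node$label))
      return(paste0(node$label, ":", fmt(node$time - ptime)))
    paste0("(", paste(vapply(node$children, nwk, "", ptime = node$time),
                      collapse = ","),
           "):", fmt(node$time - ptime))
  }
  n_extant <- length(st$map)
  gene_tree <- NULL
  if (n_extant >= 2L) {
    top <- if (length(root_genes) == 1L) root_genes[[1L]]
           else list(time = 0, children = root_genes)
    if (!is.null(top$label)) {
      gene_tree <- NULL  # single leaf; cannot form a phylo
    } else {
      inner <- paste(vapply(top$children, nwk, "", ptime = top$time),
                     collapse = ",")
      gene_tree <- ape::read.tree(text = paste0("(", inner, ");"))
    }
  }

  ev <- if (length(st$log)) {
    data.frame(
      type = vapply(st$log, `[[`, "", "type"),
      branch = vapply(st$log, `[[`, "", "branch"),
      time = vapply(st$log, `[[`, 0, "time"),
      terminal_branch = vapply(st$log, `[[`, TRUE, "terminal_branch"),
      donor = vapply(st$log, `[[`, "", "donor"),
      recipient = vapply(st$log, `[[`, "", "recipient"),
      survived = vapply(st$log, `[[`, TRUE, "survived"),
      recipient_leaves = I(lapply(st$log, `[[`, "recipient_leaves")),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(type = character(), branch = character(), time = numeric(),
               terminal_branch = logical(), donor = character(),
               recipient = character(), survived = logical(),
               recipient_leaves = I(list()), stringsAsFactors = FALSE)
  }

  structure(list(gene_tree = gene_tree, species_map = st$map,
                 event_log = ev, n_extant = n_extant, config = cfg),
            class = "gene_family_truth")
}

#' @export
print.gene_family_truth <- function(x, ...) {
  cat(sprintf("Simulated gene family: %d extant genes in %d species; %d logged events\n",
              x$n_extant, length(unique(x$species_map)), nrow(x$event_log)))
  invisible(x)
}

#' Evolve binary domain states along a simulated gene tree
#'
#' Each of the TIR, RPW8, Rx_N and LRR domains evolves as an independent
#' two-state (present/absent) Markov chain along the gene-tree branches,
#' with the gain and loss rates of the configuration. The root state is
#' NL — NB-ARC plus LRR, no N-terminal domain — reflecting the inference
#' that TNL, RNL and CNL receptors arose from NL ancestors by acquiring
#' TIR, RPW8 and CC(Rx_N) domains. NB-ARC is always present (losing it
#' would remove the gene from the family).
#'
#' @param truth A `gene_family_truth` from [simulate_gene_family()] with
#'   a non-empty gene tree.
#' @param cfg The [sim_config()] used (for rates and seed).
#' @return `truth` with `$domain_states` set: a data frame per extant
#'   gene with `gene_id`, presence booleans (`has_nbarc`, `has_tir`,
#'   `has_rpw8`, `has_rxn`, `has_lrr`) and the true `class` implied by
#'   the classification rule.
#' @export
evolve_domain_states <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "gene_family_truth"))
  tree <- truth$gene_tree
  if (is.null(tree)) stop("gene tree is empty; nothing to evolve domains on")
  set.seed(cfg$seed + 7919L)  # distinct, reproducible stream per family
  doms <- c("TIR", "RPW8", "Rx_N", "LRR")
  g <- cfg$domain_gain_rates[doms]
  l <- cfg$domain_loss_rates[doms]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(FALSE, nnode, 4L, dimnames = list(NULL, doms))
  states[ntip + 1L, "LRR"] <- TRUE  # NL root state
  eo <- ape::reorder.phylo(tree, "cladewise")  # preorder: parents first
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]; ch <- eo$edge[k, 2L]
    t <- eo$edge.length[k]
    for (j in seq_along(doms)) {
      r <- g[j] + l[j]
      if (r == 0) { states[ch, j] <- states[p, j]; next }
      pi1 <- g[j] / r
      p1 <- pi1 + ((states[p, j]) - pi1) * exp(-r * t)
      states[ch, j] <- stats::runif(1L) < p1
    }
  }
  ds <- data.frame(
    gene_id = tree$tip.label,
    has_nbarc = TRUE,
    has_tir = states[seq_len(ntip), "TIR"],
    has_rpw8 = states[seq_len(ntip), "RPW8"],
    has_rxn = states[seq_len(ntip), "Rx_N"],
    has_lrr = states[seq_len(ntip), "LRR"],
    stringsAsFactors = FALSE
  )
  ds$class <- classify_architecture(ds$has_nbarc, ds$has_tir, ds$has_rpw8, ds$has_rxn)
  truth$domain_states <- ds
  truth
}

#' Simulate an alignment containing one planted recombinant
#'
#' Parent sequence A is drawn i.i.d. over ACGT; parent B (and any extra
#' background sequences) differ from A independently at each site with
#' probability `divergence`. The recombinant C takes its first
#' `round(breakpoint_frac * length)` sites from A and the rest from B.
#'
#' @param n_background Number of background (parent-pool) sequences
#'   (>= 2); the first two are the parents `A` and `B`.
#' @param length Alignment length in sites.
#' @param divergence Per-site difference probability in (0,1).
#' @param breakpoint_frac Breakpoint position as a fraction of `length`.
#' @param seed Integer seed.
#' @return List with `alignment` (character matrix; rows `A`, `B`,
#'   optional `bg3..bgN`, and `C`) and `breakpoint` (last alignment
#'   column taken from A).
#' @export
simulate_recombinant_alignment <- function(n_background = 2L, length = 1000L,
                                           divergence = 0.3,
                                           breakpoint_frac = 0.5, seed = 1L) {
  stopifnot(n_background >= 2L, length >= 2L,
            divergence > 0, divergence < 1,
            breakpoint_frac > 0, breakpoint_frac < 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  mutate <- function(s) {
    hit <- stats::runif(length(s)) < divergence
    if (any(hit))
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L), "")
    s
  }
  A <- sample(bases, length, replace = TRUE)
  B <- mutate(A)
  rows <- list(A = A, B = B)
  if (n_background > 2L)
    for (i in 3L:n_background) rows[[paste0("bg", i)]] <- mutate(A)
  k <- round(breakpoint_frac * length)
  rows$C <- c(A[seq_len(k)], B[(k + 1L):length])
  aln <- do.call(rbind, rows)
  list(alignment = aln, breakpoint = as.integer(k))
}
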