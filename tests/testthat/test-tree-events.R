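test_that("maximal single-species clades partition the leaves", {
  lt <- labeled_tree("((a1,a2),(b1,(b2,b3)));")
  cl <- maximal_species_clades(lt$tree, lt$map)
  expect_setequal(cl$species_id, c("a", "b"))
  expect_setequal(cl$leaf_ids[[which(cl$species_id == "a")]], c("a1", "a2"))
  expect_setequal(cl$leaf_ids[[which(cl$species_id == "b")]], c("b1", "b2", "b3"))
  expect_setequal(unlist(cl$leaf_ids), lt$tree$tip.label)  # partition

  all_diff <- labeled_tree("((a1,b1),(c1,d1));")
  cl2 <- maximal_species_clades(all_diff$tree, all_diff$map)
  expect_equal(nrow(cl2), 4L)
  expect_true(all(cl2$size == 1L))

  mono <- labeled_tree("((a1,a2),(a3,a4));")
  cl3 <- maximal_species_clades(mono$tree, mono$map)
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$size, 4L)
})

test_that("duplication calling counts same-species monophyletic groups", {
  lt <- labeled_tree("((a1,a2),(b1,(b2,b3)));")
  nc <- call_duplications(lt$tree, lt$map, mode = "node_count")
  expect_equal(sum(nc$n_events[nc$species_id == "a"]), 1L)
  expect_equal(sum(nc$n_events[nc$species_id == "b"]), 2L)
  expect_equal(sum(nc$n_events), 3L)

  pc <- call_duplications(lt$tree, lt$map, mode = "per_clade")
  expect_equal(sum(pc$n_events), 2L)

  cherry <- labeled_tree("(a1,b1);")
  expect_equal(nrow(call_duplications(cherry$tree, cherry$map)), 0L)
})

test_that("node_count duplications equal the sum of clade sizes minus one", {
  set.seed(3)
  for (i in 1:20) {
    tree <- ape::rtree(12)
    tree$tip.label <- paste0(sample(c("a", "b", "c"), 12, replace = TRUE), 1:12)
    map <- stats::setNames(sub("[0-9]+$", "", tree$tip.label), tree$tip.label)
    cl <- maximal_species_clades(tree, map)
    d <- call_duplications(tree, map, "node_count")
    expect_equal(sum(d$n_events), sum(pmax(cl$size - 1L, 0L)))
  }
})

test_that("HGT calling requires donor-pure nesting context", {
  # diversity of a falls within b on two consecutive levels -> one event
  lt <- labeled_tree("(b1,((a1,a2),(b2,b3)));")
  ev <- call_hgt(lt$tree, lt$map, context_depth = 2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$donor_species, "b")
  expect_equal(ev$recipient_species, "a")
  expect_setequal(ev$recipient_leaf_ids[[1]], c("a1", "a2"))

  # species-concordant tree: no nesting, no events
  conc <- labeled_tree("((a1,a2),(b1,b2));")
  expect_equal(nrow(call_hgt(conc$tree, conc$map)), 0L)

  # mixed context (b then c) is not a transfer signal
  mixed <- labeled_tree("(c1,((a1,a2),(b2,b3)));")
  expect_equal(nrow(call_hgt(mixed$tree, mixed$map, context_depth = 2)), 0L)
})

test_that("HGT calling is monotone in context depth and respects support/size flags", {
  lt <- labeled_tree("(b1,((a1,a2),(b2,b3)));")
  n_events <- vapply(1:4, function(d)
    nrow(call_hgt(lt$tree, lt$map, context_depth = d)), 1L)
  expect_true(all(diff(n_events) <= 0))

  set.seed(8)
  for (i in 1:10) {
    tree <- ape::rtree(14)
    tree$tip.label <- paste0(sample(c("a", "b", "c", "d"), 14, TRUE), 1:14)
    map <- stats::setNames(sub("[0-9]+$", "", tree$tip.label), tree$tip.label)
    n <- vapply(1:3, function(d) nrow(call_hgt(tree, map, context_depth = d)), 1L)
    expect_true(all(diff(n) <= 0))
  }

  # support filter: low support on defining nodes suppresses the call
  sup_tree <- ape::read.tree(text = "(b1,((a1,a2)40,(b2,b3)90)50);")
  map <- stats::setNames(sub("[0-9]+$", "", sup_tree$tip.label), sup_tree$tip.label)
  expect_equal(nrow(call_hgt(sup_tree, map, min_support = 0)), 1L)
  expect_equal(nrow(call_hgt(sup_tree, map, min_support = 60)), 0L)

  # recipient-size flag: singleton recipients can be excluded
  single <- labeled_tree("(b1,(a1,(b2,b3)));")
  expect_equal(nrow(call_hgt(single$tree, single$map, context_depth = 2)), 1L)
  expect_equal(nrow(call_hgt(single$tree, single$map, context_depth = 2,
                             min_recipient_size = 2)), 0L)
})

test_that("species-monophyletic trees yield no HGT events", {
  set.seed(21)
  sub_newick <- function(sp) {
    t <- ape::rtree(sample(2:4, 1))
    t$tip.label <- paste0(sp, seq_along(t$tip.label))
    sub(";$", "", ape::write.tree(t))
  }
  for (i in 1:20) {
    # join per-species subtrees at the root: every species monophyletic
    tree <- ape::read.tree(text = sprintf("(%s,(%s,%s));", sub_newick("a"),
                                          sub_newick("b"), sub_newick("c")))
    map <- stats::setNames(sub("[0-9]+$", "", tree$tip.label), tree$tip.label)
    expect_equal(nrow(call_hgt(tree, map, context_depth = 2)), 0L)
  }
})

test_that("HGT matrix counts directed events with zero diagonal", {
  species <- c("A", "B", "C")
  empty <- hgt_matrix(data.frame(donor_species = character(),
                                 recipient_species = character()), species)
  expect_true(all(empty == 0L))

  ev <- data.frame(donor_species = c("B", "B", "B", "A"),
                   recipient_species = c("A", "A", "A", "B"))
  m <- hgt_matrix(ev, species)
  expect_equal(m["B", "A"], 3L)
  expect_equal(m["A", "B"], 1L)
  expect_equal(sum(m), nrow(ev))
  expect_true(all(diag(m) == 0L))

  # row/col sums match an independent tally
  expect_equal(rowSums(m), vapply(species, function(s)
    sum(ev$donor_species == s), 1, USE.NAMES = TRUE), ignore_attr = TRUE)
  expect_equal(colSums(m), vapply(species, function(s)
    sum(ev$recipient_species == s), 1, USE.NAMES = TRUE), ignore_attr = TRUE)

  expect_error(hgt_matrix(data.frame(donor_species = "Z", recipient_species = "A"),
                          species), "unknown species")
})
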