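test_that("identical sequences carry no recombination signal", {
  aln <- rbind(A = rep(c("A", "C", "G", "T"), 25),
               B = rep(c("A", "C", "G", "T"), 25))
  r <- maxchi_test(aln, c("A", "B"), half_window = 5, n_permutations = 50)
  expect_equal(r$p_value, 1)
  expect_true(is.na(r$breakpoint_site))
  expect_equal(r$max_chi2, 0)
})

test_that("a fully separated window gives the closed-form 2x2 chi-square", {
  # 20 polymorphic sites: pair (C,A) matches on the first 10, mismatches on
  # the last 10; with half_window 10 the only partition point is the centre
  # and the 2x2 table (10,0 / 0,10) has chi-square exactly 20.
  A <- rep("A", 20)
  B <- rep("C", 20)           # every column polymorphic
  C <- c(rep("A", 10), rep("C", 10))
  aln <- rbind(A = A, B = B, C = C)
  r <- maxchi_test(aln, c("C", "A"), half_window = 10, n_permutations = 10,
                   seed = 1)
  expect_equal(r$max_chi2, 20)
  expect_equal(r$breakpoint_site, 10L)
})

test_that("too few usable sites yields p = 1 and no breakpoint", {
  aln <- rbind(A = c("A", "C", "G", "T", "A", "C"),
               B = c("A", "G", "G", "T", "A", "C"),
               C = c("A", "G", "-", "N", "A", "C"))
  r <- maxchi_test(aln, c("C", "A"), half_window = 3, n_permutations = 20)
  expect_equal(r$p_value, 1)
  expect_true(is.na(r$breakpoint_site))
})

test_that("gap and N sites are excluded pairwise, not alignment-wide", {
  sim <- simulate_recombinant_alignment(length = 400, divergence = 0.3,
                                        breakpoint_frac = 0.5, seed = 77)
  aln <- sim$alignment
  aln["B", 1:10] <- "-"   # gaps in B must not reduce the (C,A) comparison
  r_full <- maxchi_test(sim$alignment, c("C", "A"), half_window = 10,
                        n_permutations = 100, seed = 5)
  r_gapb <- maxchi_test(aln, c("C", "A"), half_window = 10,
                        n_permutations = 100, seed = 5)
  # B's gapped columns are dropped only if they stop being polymorphic;
  # the (C,A) usable-site count must not fall below the full count minus 10
  expect_gte(r_gapb$n_sites, r_full$n_sites - 10L)
  aln["A", 11:60] <- "N"  # N in the tested pair removes those sites
  r_gapa <- maxchi_test(aln, c("C", "A"), half_window = 10,
                        n_permutations = 100, seed = 5)
  expect_lt(r_gapa$n_sites, r_gapb$n_sites)
})

test_that("planted recombinants are detected at the right breakpoint", {
  sim <- simulate_recombinant_alignment(n_background = 2, length = 1000,
                                        divergence = 0.3, breakpoint_frac = 0.5,
                                        seed = 101)
  r <- maxchi_test(sim$alignment, c("C", "A"), half_window = 25,
                   n_permutations = 1000, seed = 11)
  expect_lt(r$p_value, 0.01)
  # breakpoint accuracy measured in polymorphic sites of the (C,A) scan
  diff_sites <- which(sim$alignment["C", ] != sim$alignment["A", ])
  off_by <- sum(diff_sites > min(r$breakpoint_position, sim$breakpoint) &
                diff_sites <= max(r$breakpoint_position, sim$breakpoint))
  expect_lte(off_by, 3L)
})

test_that("permutation p-values are reproducible under a fixed seed", {
  sim <- simulate_recombinant_alignment(length = 300, seed = 5)
  r1 <- maxchi_test(sim$alignment, c("C", "B"), n_permutations = 200, seed = 42)
  r2 <- maxchi_test(sim$alignment, c("C", "B"), n_permutations = 200, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$max_chi2, r2$max_chi2)
})

test_that("maxchi errors on unknown sequence ids", {
  sim <- simulate_recombinant_alignment(length = 200, seed = 2)
  expect_error(maxchi_test(sim$alignment, c("C", "nope")), "not in alignment")
})

test_that("consensus rule: at least four methods below threshold", {
  tab <- data.frame(event_id = c("e1", "e2", "e3"),
                    RDP = c(1e-7, 1e-7, 1), GENECONV = c(1e-8, 1e-8, 1),
                    Chimaera = c(1e-9, 1e-9, 1), MaxChi = c(1e-7, 0.5, 1),
                    BootScan = c(0.5, 0.5, 1), SiScan = c(0.5, 0.5, 1),
                    `3Seq` = c(0.5, 0.5, 1), check.names = FALSE)
  calls <- consensus_call(tab)
  expect_equal(calls$n_supporting, c(4L, 3L, 0L))
  expect_equal(calls$significant, c(TRUE, FALSE, FALSE))
})

test_that("consensus threshold is a strict inequality and handles NAs", {
  tab <- data.frame(event_id = "e", RDP = 1e-6, GENECONV = 1e-6,
                    Chimaera = 1e-6, MaxChi = 1e-6, BootScan = NA,
                    SiScan = NA, `3Seq` = NA, check.names = FALSE)
  expect_equal(consensus_call(tab)$n_supporting, 0L)  # p == alpha not counted
  tab$RDP <- 0.99e-6
  expect_equal(consensus_call(tab)$n_supporting, 1L)  # missing = non-supporting
  tab$RDP <- 1.5
  expect_error(consensus_call(tab), "\\[0,1\\]")
})

test_that("consensus agrees with brute-force counting over all 2^7 patterns", {
  methods <- recomb_methods()
  for (mask in 0:(2^7 - 1)) {
    below <- as.logical(bitwAnd(mask, 2^(0:6)))
    p <- ifelse(below, 1e-8, 0.5)
    tab <- as.data.frame(as.list(stats::setNames(p, methods)),
                         check.names = FALSE)
    tab$event_id <- "e"
    call <- consensus_call(tab, min_methods = 4, alpha = 1e-6)
    expect_equal(call$n_supporting, sum(below))          # brute-force count
    expect_equal(call$significant, sum(below) >= 4)
  }
})

test_that("consensus is monotone: lowering a p-value never loses significance", {
  set.seed(19)
  methods <- recomb_methods()
  for (i in 1:50) {
    p <- stats::runif(7)
    tab <- as.data.frame(as.list(stats::setNames(p, methods)), check.names = FALSE)
    tab$event_id <- "e"
    before <- consensus_call(tab, min_methods = 2, alpha = 0.2)
    j <- sample(7, 1)
    tab[[methods[j]]] <- tab[[methods[j]]] / 10
    after <- consensus_call(tab, min_methods = 2, alpha = 0.2)
    expect_gte(after$n_supporting, before$n_supporting)
    if (before$significant) expect_true(after$significant)
  }
})
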