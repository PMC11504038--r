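#' Maximum chi-square sliding-window recombination test for one pair
#'
#' A pairwise variant of the classical maximum chi-square (MaxChi)
#' recombination test. The scan is restricted to the polymorphic sites of
#' the alignment (columns with at least two distinct bases among all
#' sequences — the classical variable-site restriction); sites where
#' either member of the tested pair carries a gap or `N` are additionally
#' excluded pairwise. Each remaining comparison site is scored as a match
#' or mismatch between the two sequences; both states are informative.
#' Note that a two-sequence alignment has no polymorphic match sites, so
#' a pair should be tested inside the alignment that provides its
#' comparison context (parents plus candidate recombinant).
#'
#' A partition point slides
#' along the comparison sites and, at each point, a 2x2 chi-square
#' statistic (no continuity correction) contrasts the match/mismatch
#' counts in the `half_window` sites to its left against the
#' `half_window` sites to its right. A recombination breakpoint produces
#' a sharp excess of mismatches on one side. Significance is assessed by
#' permuting the site order (which is exchangeable under the
#' no-recombination null) with the add-one estimator
#' `p = (1 + #\{permutation max >= observed max\}) / (n_permutations + 1)`.
#'
#' @param aln Character matrix alignment (see [read_alignment()]).
#' @param pair Character vector of two sequence ids present in `aln`.
#' @param half_window Sites on each side of the partition point
#'   (>= 2; default 25).
#' @param n_permutations Number of site-order permutations (default 1000).
#' @param seed Integer seed making the permutation p-value reproducible.
#' @return A list of class `maxchi_result`: `pair`, `max_chi2`,
#'   `breakpoint_site` (1-based index into the comparison-site list, `NA`
#'   if fewer than `2*half_window` usable sites), `breakpoint_position`
#'   (alignment column of that site), `p_value`, `n_permutations`,
#'   `seed`, `n_sites`.
#' @export
maxchi_test <- function(aln, pair, half_window = 25L, n_permutations = 1000L,
                        seed = 1L) {
  stopifnot(is.matrix(aln), half_window >= 2L, n_permutations >= 1L)
  missing_ids <- setdiff(pair, rownames(aln))
  if (length(missing_ids))
    stop("sequence id not in alignment: ", paste(missing_ids, collapse = ", "))
  s1 <- aln[pair[1L], ]; s2 <- aln[pair[2L], ]
  poly <- apply(aln, 2L, function(col) {
    b <- unique(col[!col %in% c("-", "N")])
    length(b) >= 2L
  })
  usable <- poly & !(s1 %in% c("-", "N")) & !(s2 %in% c("-", "N"))
  sites <- which(usable)
  x <- s1[sites] == s2[sites]
  m <- length(x)
  hw <- as.integer(half_window)
  base <- list(pair = pair, max_chi2 = 0, breakpoint_site = NA_integer_,
               breakpoint_position = NA_integer_, p_value = 1,
               n_permutations = as.integer(n_permutations),
               seed = as.integer(seed), n_sites = m)
  class(base) <- "maxchi_result"
  if (m < 2L * hw || all(x) || !any(x)) return(base)

  obs <- maxchi_scan(x, hw)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- maxchi_scan(x[sample.int(m)], hw)
    if (perm$max >= obs$max) exceed <- exceed + 1L
  }
  base$max_chi2 <- obs$max
  base$breakpoint_site <- obs$argmax
  base$breakpoint_position <- sites[obs$argmax]
  base$p_value <- (1 + exceed) / (n_permutations + 1)
  base
}

# Vectorised scan over all partition points: x is the logical match
# vector over comparison sites; returns max 2x2 chi-square and argmax
# (partition after site argmax).
maxchi_scan <- function(x, hw) {
  m <- length(x)
  cs <- c(0L, cumsum(x))
  t <- hw:(m - hw)                       # partition after site t
  a <- cs[t + 1L] - cs[t - hw + 1L]      # left matches
  b <- hw - a                            # left mismatches
  c_ <- cs[t + hw + 1L] - cs[t + 1L]     # right matches
  d <- hw - c_                           # right mismatches
  n <- 2L * hw
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  k <- which.max(chi)
  list(max = chi[k], argmax = t[k])
}

#' @export
print.maxchi_result <- function(x, ...) {
  cat(sprintf("MaxChi pair (%s, %s): max chi-square = %.3f, p = %.4g (%d permutations)\n",
              x$pair[1L], x$pair[2L], x$max_chi2, x$p_value, x$n_permutations))
  if (!is.na(x$breakpoint_site))
    cat(sprintf("  breakpoint after comparison site %d (alignment column %d) of %d sites\n",
                x$breakpoint_site, x$breakpoint_position, x$n_sites))
  invisible(x)
}

#' Scan all sequence pairs of an alignment for recombination
#'
#' Convenience wrapper running [maxchi_test()] over every unordered pair.
#'
#' @inheritParams maxchi_test
#' @return Data frame with one row per pair: `id1`, `id2`, `max_chi2`,
#'   `breakpoint_site`, `breakpoint_position`, `p_value`.
#' @export
maxchi_scan_pairs <- function(aln, half_window = 25L, n_permutations = 1000L,
                              seed = 1L) {
  ids <- rownames(aln)
  pairs <- utils::combn(ids, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    r <- maxchi_test(aln, pairs[, k], half_window, n_permutations,
                     seed = seed + k - 1L)
    data.frame(id1 = r$pair[1L], id2 = r$pair[2L], max_chi2 = r$max_chi2,
               breakpoint_site = r$breakpoint_site,
               breakpoint_position = r$breakpoint_position,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Standard method names of the seven recombination detectors
#' @export
recomb_methods <- function() {
  c("RDP", "GENECONV", "Chimaera", "MaxChi", "BootScan", "SiScan", "3Seq")
}

#' Multi-method consensus rule for recombination events
#'
#' A candidate recombination event is deemed significant only when enough
#' independent detection methods support it: with the defaults, at least
#' four of the seven methods (RDP, GENECONV, Chimaera, MaxChi, BootScan,
#' SiScan, 3Seq) at p strictly below 1e-6. Missing method p-values count
#' as non-supporting.
#'
#' @param table Data frame with a column `event_id` and one column per
#'   method (any subset of [recomb_methods()], matched by name; `3Seq`
#'   may be written `X3Seq` as R's `read.csv` mangles it); `NA` = missing.
#' @param min_methods Minimum number of supporting methods (1-7).
#' @param alpha Significance threshold; support requires `p < alpha`
#'   (strict inequality).
#' @return Data frame with columns `event_id`, `n_supporting`,
#'   `significant`.
#' @examples
#' tab <- data.frame(event_id = "e1", RDP = 1e-7, GENECONV = 1e-8,
#'                   Chimaera = 1e-9, MaxChi = 1e-7, BootScan = 0.5,
#'                   SiScan = 0.5, `3Seq` = 0.5, check.names = FALSE)
#' consensus_call(tab)  # 4 supporting methods -> significant
#' @export
consensus_call <- function(table, min_methods = 4L, alpha = 1e-6) {
  stopifnot(is.data.frame(table), "event_id" %in% names(table))
  if (min_methods < 1L || min_methods > 7L) stop("min_methods must be in 1..7")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  nm <- names(table)
  nm[nm == "X3Seq"] <- "3Seq"
  names(table) <- nm
  methods <- intersect(recomb_methods(), nm)
  if (!length(methods)) stop("no recognised method columns in table")
  p <- as.matrix(table[, methods, drop = FALSE])
  storage.mode(p) <- "double"
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  n_sup <- rowSums(p < alpha, na.rm = TRUE)
  data.frame(event_id = as.character(table$event_id),
             n_supporting = as.integer(n_sup),
             significant = n_sup >= min_methods,
             stringsAsFactors = FALSE)
}
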