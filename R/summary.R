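#' Per-species NLR class counts
#'
#' Tallies classified NLR proteins into the per-species table of TNL,
#' CNL, RNL and NL counts. Rows classified `NOT_NLR` are an error: the
#' input is expected to be pre-filtered to true NLRs.
#'
#' @param assignments Data frame with columns `protein_id`, `species_id`,
#'   `class` (values in TNL/CNL/RNL/NL).
#' @return Data frame with one row per species: `species_id`, `n_tnl`,
#'   `n_cnl`, `n_rnl`, `n_nl`, `n_total`; the grand total of `n_total`
#'   equals the number of input rows.
#' @export
counts_table <- function(assignments) {
  stopifnot(is.data.frame(assignments),
            all(c("protein_id", "species_id", "class") %in% names(assignments)))
  if (nrow(assignments) == 0L)
    return(data.frame(species_id = character(), n_tnl = integer(),
                      n_cnl = integer(), n_rnl = integer(), n_nl = integer(),
                      n_total = integer(), stringsAsFactors = FALSE))
  if (any(assignments$class == "NOT_NLR"))
    stop("assignments contain NOT_NLR rows; filter to NLRs first")
  bad <- setdiff(unique(assignments$class), c("TNL", "CNL", "RNL", "NL"))
  if (length(bad)) stop("unknown class: ", paste(bad, collapse = ", "))
  species <- unique(assignments$species_id)
  cnt <- function(s, cl) sum(assignments$species_id == s & assignments$class == cl)
  out <- data.frame(
    species_id = species,
    n_tnl = vapply(species, cnt, 1L, cl = "TNL", USE.NAMES = FALSE),
    n_cnl = vapply(species, cnt, 1L, cl = "CNL", USE.NAMES = FALSE),
    n_rnl = vapply(species, cnt, 1L, cl = "RNL", USE.NAMES = FALSE),
    n_nl = vapply(species, cnt, 1L, cl = "NL", USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  out$n_total <- out$n_tnl + out$n_cnl + out$n_rnl + out$n_nl
  out
}

#' Correlate per-species gene counts with event frequencies
#'
#' Computes the correlation between per-species NLR gene counts and
#' per-species event counts (HGT, recombination or duplication events).
#' Pearson is the default; the two-sided p-value uses the t-distribution
#' transform `t = r * sqrt((n-2) / (1-r^2))` with `n - 2` degrees of
#' freedom. Spearman applies the same transform to the rank correlation.
#'
#' @param counts,events Numeric vectors of equal length (>= 3 species),
#'   paired by position, or named vectors paired by species name when
#'   both are named.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame (one row): `x_name`, `y_name`, `r`, `p_value`,
#'   `n`, `method`.
#' @examples
#' correlate_counts_events(c(56, 107, 178, 405), c(6, 20, 40, 116))
#' @export
correlate_counts_events <- function(counts, events,
                                    method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.null(names(counts)) && !is.null(names(events))) {
    common <- intersect(names(counts), names(events))
    if (length(common) < length(counts) || length(common) < length(events))
      stop("length mismatch: species names do not pair up")
    counts <- counts[common]; events <- events[common]
  }
  if (length(counts) != length(events)) stop("length mismatch")
  n <- length(counts)
  if (n < 3L) stop("need at least 3 paired species")
  x <- as.numeric(counts); y <- as.numeric(events)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant vector")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    .Machine$double.xmin
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  data.frame(x_name = "n_genes", y_name = "n_events", r = r, p_value = p,
             n = n, method = method, stringsAsFactors = FALSE)
}
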