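#' M7-versus-M8 likelihood-ratio test for positive selection
#'
#' The standard site-model test of positive selection compares the beta
#' (M7) and beta-plus-omega (M8) codon models: the statistic is twice the
#' log-likelihood difference, `2 * (lnL_M8 - lnL_M7)`, referred to a
#' chi-square distribution with 2 degrees of freedom, for which the
#' upper-tail probability has the closed form `exp(-stat / 2)`. Negative
#' statistics (optimiser noise: M8 nests M7, so the true difference is
#' non-negative) are clamped to zero.
#'
#' @param lnl_m7,lnl_m8 Numeric vectors of log-likelihoods (recycled to a
#'   common length); must be finite.
#' @return Data frame with columns `lrt_stat` and `p_value`.
#' @examples
#' lrt_m7m8(-1000, -995)  # stat 10, p = exp(-5)
#' @export
lrt_m7m8 <- function(lnl_m7, lnl_m8) {
  if (any(!is.finite(lnl_m7)) || any(!is.finite(lnl_m8)))
    stop("log-likelihoods must be finite")
  stat <- pmax(0, 2 * (lnl_m8 - lnl_m7))
  data.frame(lrt_stat = stat, p_value = exp(-stat / 2))
}

#' Classify gene groups by positive-selection evidence
#'
#' Combines the M7/M8 likelihood-ratio test with Bayes-empirical-Bayes
#' (BEB) site evidence: a group is called positive when its LRT p-value
#' falls below `alpha` and it has at least one BEB site at posterior
#' probability `>= min_posterior`. The conventional defaults are
#' `alpha = 0.05` and `min_posterior = 0.95`.
#'
#' @param likelihoods Data frame with columns `group_id`, `lnl_m7`,
#'   `lnl_m8`.
#' @param beb_sites Data frame with columns `group_id`, `site_index`
#'   (1-based codon position) and `posterior` in `[0,1]`; may be empty.
#' @param alpha LRT significance threshold in (0,1).
#' @param min_posterior Minimum BEB posterior for a site to count.
#' @return Data frame with one row per group: `group_id`, `lrt_stat`,
#'   `p_value`, `n_beb_sites`, `verdict` (`"positive"`/`"negative"`);
#'   attribute `"summary"` holds the `"k/n"` positive-group tally.
#' @export
classify_selection_groups <- function(likelihoods, beb_sites,
                                      alpha = 0.05, min_posterior = 0.95) {
  stopifnot(is.data.frame(likelihoods),
            all(c("group_id", "lnl_m7", "lnl_m8") %in% names(likelihoods)))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (min_posterior < 0 || min_posterior > 1) stop("min_posterior must be in [0,1]")
  if (is.null(beb_sites) || nrow(beb_sites) == 0L) {
    beb_sites <- data.frame(group_id = character(), site_index = integer(),
                            posterior = numeric())
  }
  stopifnot(all(c("group_id", "posterior") %in% names(beb_sites)))
  if (any(beb_sites$posterior < 0 | beb_sites$posterior > 1))
    stop("BEB posteriors must lie in [0,1]")
  unknown <- setdiff(beb_sites$group_id, likelihoods$group_id)
  if (length(unknown))
    stop("BEB site references unknown group: ", paste(unknown, collapse = ", "))

  lrt <- lrt_m7m8(likelihoods$lnl_m7, likelihoods$lnl_m8)
  strong <- beb_sites[beb_sites$posterior >= min_posterior, , drop = FALSE]
  n_beb <- vapply(likelihoods$group_id,
                  function(g) sum(strong$group_id == g), 1L, USE.NAMES = FALSE)
  out <- data.frame(
    group_id = as.character(likelihoods$group_id),
    lrt_stat = lrt$lrt_stat, p_value = lrt$p_value,
    n_beb_sites = n_beb,
    verdict = ifelse(lrt$p_value < alpha & n_beb >= 1L, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  attr(out, "summary") <- sprintf("%d/%d", sum(out$verdict == "positive"), nrow(out))
  out
}
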