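#' Score called HGT events against simulator ground truth
#'
#' A called event matches a true (surviving) transfer when the recipient
#' species agrees — the called recipient species must occur among the
#' species of the transfer's extant descendant genes — and at least half
#' of the called recipient clade's leaves descend from the transferred
#' copy. Precision is the fraction of called events with a match; recall
#' is the fraction of surviving true transfers matched by at least one
#' call.
#'
#' @param called Data frame from [call_hgt()].
#' @param truth A `gene_family_truth` from [simulate_gene_family()].
#' @return List with `precision`, `recall`, `n_called`, `n_true`
#'   (`precision`/`recall` are `NA` when the respective denominator is 0).
#' @export
hgt_recovery <- function(called, truth) {
  stopifnot(inherits(truth, "gene_family_truth"))
  ev <- truth$event_log
  tru <- ev[ev$type == "transfer" & ev$survived, , drop = FALSE]
  n_called <- nrow(called)
  n_true <- nrow(tru)
  if (n_called == 0L && n_true == 0L)
    return(list(precision = NA_real_, recall = NA_real_, n_called = 0L, n_true = 0L))
  sp_of <- function(leaves) unique(unname(truth$species_map[leaves]))
  matched_called <- logical(n_called)
  matched_true <- logical(n_true)
  for (i in seq_len(n_called)) {
    cl <- called$recipient_leaf_ids[[i]]
    for (j in seq_len(n_true)) {
      tl <- tru$recipient_leaves[[j]]
      if (!(called$recipient_species[i] %in% sp_of(tl))) next
      if (length(intersect(cl, tl)) / length(cl) >= 0.5) {
        matched_called[i] <- TRUE
        matched_true[j] <- TRUE
      }
    }
  }
  list(precision = if (n_called) mean(matched_called) else NA_real_,
       recall = if (n_true) mean(matched_true) else NA_real_,
       n_called = n_called, n_true = n_true)
}
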