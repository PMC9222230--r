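#' Precision and recall of a selection against planted truth
#'
#' @param selected_ids character vector of selected probe ids.
#' @param truth truth data.frame from [generate_dataset()] (`probe_id`,
#'   `is_deg`).
#' @return named numeric vector: `precision`, `recall`, `n_selected`,
#'   `fdr` (empirical, = 1 - precision; 0 when nothing is selected).
#' @export
selection_performance <- function(selected_ids, truth) {
  pos <- truth$probe_id[truth$is_deg]
  tp <- length(intersect(selected_ids, pos))
  n_sel <- length(unique(selected_ids))
  precision <- if (n_sel == 0L) NA_real_ else tp / n_sel
  c(precision = precision,
    recall = tp / length(pos),
    n_selected = n_sel,
    fdr = if (n_sel == 0L) 0 else 1 - tp / n_sel)
}

#' Recall attainable at a matched empirical FDR
#'
#' Ranks probes by increasing p-value and finds the largest prefix whose
#' empirical false discovery proportion (against the planted truth) does
#' not exceed `fdr`; returns the recall of that prefix.  Used to compare
#' selectors at the same achieved error level rather than at their
#' nominal thresholds.
#'
#' @param p_values per-probe p-values, in the order of `truth$probe_id`.
#' @param truth truth data.frame (`probe_id`, `is_deg`).
#' @param fdr target empirical FDR.
#' @return named numeric vector: `recall`, `n_selected`, `fdr_achieved`.
#' @export
recall_at_matched_fdr <- function(p_values, truth, fdr) {
  stopifnot(length(p_values) == nrow(truth))
  ord <- order(p_values)
  is_pos <- truth$is_deg[ord]
  fdp <- cumsum(!is_pos) / seq_along(is_pos)
  k <- suppressWarnings(max(which(fdp <= fdr)))
  if (!is.finite(k)) {
    return(c(recall = 0, n_selected = 0, fdr_achieved = 0))
  }
  c(recall = sum(is_pos[seq_len(k)]) / sum(truth$is_deg),
    n_selected = k,
    fdr_achieved = fdp[k])
}
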