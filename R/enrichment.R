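#' Select proteins for overrepresentation analysis
#'
#' Two selection modes mirror the two ways a differential proteome can feed
#' an enrichment analysis: proteins detected in only one sample, or
#' proteins whose peptide-backed fold change passes a threshold.
#'
#' @param mode `"unique_to_sample"` or `"fold_change"`.
#' @param gw_ids,mw_ids Protein ids detected in each sample
#'   (`unique_to_sample` mode).
#' @param sample Which sample's unique proteins to return (default `"GW"`).
#' @param fold_changes Named numeric vector of protein log2 fold changes
#'   (`fold_change` mode).
#' @param fc_threshold Fold-change threshold on the natural scale
#'   (default 2; selection uses `>=`).
#' @param direction `"up"`, `"down"` or `"both"` relative to GW.
#' @return Character vector of selected protein ids (possibly empty, with a
#'   warning).
#' @export
select_proteins <- function(mode = c("unique_to_sample", "fold_change"),
                            gw_ids = NULL, mw_ids = NULL, sample = "GW",
                            fold_changes = NULL, fc_threshold = 2,
                            direction = c("up", "down", "both")) {
  mode <- match.arg(mode)
  direction <- match.arg(direction)
  sel <- if (mode == "unique_to_sample") {
    if (is.null(gw_ids) || is.null(mw_ids)) {
      stop("unique_to_sample mode needs gw_ids and mw_ids", call. = FALSE)
    }
    if (sample == "GW") setdiff(gw_ids, mw_ids) else setdiff(mw_ids, gw_ids)
  } else {
    if (is.null(fold_changes)) {
      stop("fold_change mode needs named fold_changes", call. = FALSE)
    }
    thr <- log2(fc_threshold)
    keep <- switch(direction,
      up = fold_changes >= thr,
      down = fold_changes <= -thr,
      both = abs(fold_changes) >= thr
    )
    names(fold_changes)[keep & !is.na(keep)]
  }
  if (length(sel) == 0) warning("empty protein selection", call. = FALSE)
  sel
}

#' Hypergeometric term overrepresentation
#'
#' Upper-tail hypergeometric test per annotation term: the probability of
#' observing at least `k` annotated proteins among `n` selected, given `K`
#' annotated in a background of `N`, with Benjamini-Hochberg adjustment
#' across the tested terms. Results are sorted by q then p.
#'
#' @param selected Character vector of selected protein ids (must be a
#'   subset of `background`).
#' @param background Character vector of background protein ids.
#' @param annotations `data.frame` with columns `protein_id`, `term_id`
#'   and optionally `term_name`. Annotations outside the background are
#'   ignored.
#' @return `data.frame`: `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`.
#' @export
hypergeom_enrich <- function(selected, background, annotations) {
  selected <- unique(selected)
  background <- unique(background)
  outside <- setdiff(selected, background)
  if (length(outside) > 0) {
    stop("selected protein(s) not in background: ",
         paste(outside, collapse = ", "), call. = FALSE)
  }
  annotations <- annotations[annotations$protein_id %in% background, ,
                             drop = FALSE]
  if (is.null(annotations$term_name)) annotations$term_name <- ""
  N <- length(background)
  n <- length(selected)
  terms <- unique(annotations$term_id)
  res <- lapply(terms, function(tm) {
    ann_ids <- unique(annotations$protein_id[annotations$term_id == tm])
    K <- length(ann_ids)
    k <- length(intersect(ann_ids, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm,
               term_name = annotations$term_name[
                 match(tm, annotations$term_id)],
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  }
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$q_value, res$p_value), , drop = FALSE]
}
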