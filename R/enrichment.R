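#' Hypergeometric gene-set over-representation
#'
#' For each term: with a universe of N transcripts of which K belong to the
#' term, and a query of n transcripts of which k overlap the term, the
#' p-value is the upper hypergeometric tail P(X >= k). The enrichment score
#' is -log10(p); p-values are BH-adjusted across all tested terms.
#'
#' Query ids outside the universe are dropped with a warning; term members
#' are intersected with the universe. Terms with k = 0 are reported with
#' p = 1.
#'
#' @param query character vector of transcript ids (e.g. a DE list).
#' @param gene_sets named list of `list(term_name, members)` as returned by
#'   [read_gmt()].
#' @param universe character vector of all testable transcript ids.
#' @return data.frame `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, `enrichment_score`, one row per term in input order.
#' @export
hypergeometric_enrich <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop_config("enrichment universe is empty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query id(s) outside the universe dropped, e.g. ",
            outside[1])
    query <- intersect(query, universe)
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(id) {
    members <- intersect(gene_sets[[id]]$members, universe)
    K <- length(members)
    k <- length(intersect(members, query))
    p <- if (k == 0) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_name = gene_sets[[id]]$term_name,
               k = k, K = K, n = n, N = N, p_value = p)
  })
  res <- do.call(rbind, rows) %||%
    data.frame(term_id = character(0), term_name = character(0),
               k = integer(0), K = integer(0), n = integer(0), N = integer(0),
               p_value = numeric(0))
  res$fdr <- bh_fdr(res$p_value)
  res$enrichment_score <- -log10(res$p_value)
  rownames(res) <- NULL
  res
}

#' Top enriched terms
#'
#' Descending by enrichment score (i.e. ascending p), ties broken by
#' smaller FDR then lexicographic term id.
#'
#' @param results data.frame from [hypergeometric_enrich()].
#' @param k number of terms to return (capped at the available count),
#'   default 10.
#' @return the top rows in rank order.
#' @export
top_terms <- function(results, k = 10) {
  ord <- order(-results$enrichment_score, results$fdr, results$term_id)
  res <- results[ord[seq_len(min(k, nrow(results)))], , drop = FALSE]
  rownames(res) <- NULL
  res
}
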