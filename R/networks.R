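#' Co-expression network configuration
#'
#' The retention rule of the study's co-expression analysis:
#' |PCC| >= 0.968 with p < 0.05.
#'
#' @param pcc_threshold absolute Pearson correlation threshold in (0,1],
#'   default 0.968.
#' @param p_threshold p-value threshold in (0,1), default 0.05.
#' @param min_site_type minimum seed-site specificity for site-backed edges
#'   (`"any"`, `"7mer"`, `"8mer"`, ...), default `"any"`.
#' @return list of class `coexpr_config`.
#' @export
coexpr_config <- function(pcc_threshold = 0.968, p_threshold = 0.05,
                          min_site_type = "any") {
  if (!is.numeric(pcc_threshold) || pcc_threshold <= 0 || pcc_threshold > 1) {
    stop_config("pcc_threshold must be in (0,1]")
  }
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop_config("p_threshold must be in (0,1)")
  }
  site_rank(min_site_type)  # validates
  structure(list(pcc_threshold = pcc_threshold, p_threshold = p_threshold,
                 min_site_type = min_site_type),
            class = "coexpr_config")
}

#' Two-sided p-value for a Pearson correlation
#'
#' `t = r * sqrt(n-2) / sqrt(1-r^2)` referred to the t distribution on
#' n-2 degrees of freedom; `|r| = 1` returns p = 0.
#'
#' @param r correlation coefficient(s).
#' @param n sample size (>= 3).
#' @return two-sided p-value(s).
#' @export
pcc_pvalue <- function(r, n) {
  if (any(n < 3)) stop_config("correlation p-value needs n >= 3")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  p
}

#' Pearson correlation with p-value between two sample vectors
#'
#' @param x,y numeric vectors of equal length n >= 3, non-constant.
#' @return `list(pcc, p_value, exact_fit)`; `exact_fit` flags |r| = 1,
#'   reported with p = 0.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  if (length(x) < 3L) stop_config("correlation needs n >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop_config("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_config("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  # clamp numerical excursions beyond +-1
  r <- max(-1, min(1, r))
  list(pcc = r, p_value = pcc_pvalue(r, length(x)), exact_fit = abs(r) == 1)
}

## Correlation matrix between rows of A and rows of B (log2 profiles),
## with the t-transform p-values. Constant rows yield NA correlations.
cor_matrix_with_p <- function(A, B) {
  n <- ncol(A)
  r <- suppressWarnings(stats::cor(t(A), t(B)))
  r[r > 1] <- 1
  r[r < -1] <- -1
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  ok <- is.finite(r)
  p[ok] <- pcc_pvalue(r[ok], n)
  list(r = r, p = p, n = n)
}

edge_frame <- function() {
  data.frame(node_a = character(0), node_b = character(0),
             class_a = character(0), class_b = character(0),
             pcc = numeric(0), p_value = numeric(0), sign = character(0))
}

## Shared retention logic: |r| >= thr, p < thr, optional sign constraint.
retain_edges <- function(ids_a, ids_b, class_a, class_b, cm, config,
                         require_negative = FALSE) {
  r <- cm$r[ids_a, ids_b, drop = FALSE]
  p <- cm$p[ids_a, ids_b, drop = FALSE]
  mask <- is.finite(r) & abs(r) >= config$pcc_threshold & p < config$p_threshold
  if (require_negative) mask <- mask & r < 0
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(edge_frame())
  canonical_edges(data.frame(
    node_a = ids_a[idx[, 1]], node_b = ids_b[idx[, 2]],
    class_a = class_a, class_b = class_b,
    pcc = r[idx], p_value = p[idx],
    sign = ifelse(r[idx] > 0, "positive", "negative")))
}

#' Coding/non-coding (CNC) co-expression network
#'
#' Pearson correlation between every (mRNA, lncRNA) pair of deregulated
#' transcripts, computed on log2 profiles pooled across all samples (cases
#' and controls); pairs with |PCC| >= threshold and p < threshold are
#' retained as signed edges.
#'
#' @param em_mrna,em_lnc expression matrices sharing the same samples.
#' @param de_mrna_ids,de_lnc_ids deregulated transcript ids to correlate;
#'   ids absent from the matrices are dropped with a warning.
#' @param config a [coexpr_config()].
#' @return edge data.frame (`node_a` = mRNA, `node_b` = lncRNA) in canonical
#'   order.
#' @export
build_cnc_network <- function(em_mrna, em_lnc, de_mrna_ids, de_lnc_ids,
                              config = coexpr_config()) {
  stopifnot(identical(colnames(em_mrna$values), colnames(em_lnc$values)))
  keep_m <- de_mrna_ids %in% rownames(em_mrna$values)
  keep_l <- de_lnc_ids %in% rownames(em_lnc$values)
  if (!all(keep_m) || !all(keep_l)) {
    warning(sum(!keep_m) + sum(!keep_l),
            " transcript(s) absent from expression matrices were skipped")
  }
  ids_m <- de_mrna_ids[keep_m]
  ids_l <- de_lnc_ids[keep_l]
  if (!length(ids_m) || !length(ids_l)) return(edge_frame())
  cm <- cor_matrix_with_p(em_log2(em_subset(em_mrna, ids_m)),
                          em_log2(em_subset(em_lnc, ids_l)))
  retain_edges(ids_m, ids_l, "mRNA", "lncRNA", cm, config)
}

## direction lookup from a DE table restricted to filter-passing records
de_direction <- function(de) {
  de <- de[de$passes_filter, , drop = FALSE]
  setNames(de$direction, de$transcript_id)
}

#' Negatively-correlated miRNA target network
#'
#' An edge (miRNA, mRNA) is retained iff the pair has at least one canonical
#' seed site, the pooled-sample Pearson correlation is negative with
#' |PCC| >= threshold and p < threshold, and the two members are
#' deregulated in opposite directions (miRNA up with target down, or the
#' mirror). All retained edges carry `sign = "negative"`.
#'
#' @param em_mirna miRNA count matrix (log2(count+1) profiles are used).
#' @param em_mrna mRNA expression matrix on the same samples.
#' @param de_mirna,de_mrna DE tables from [differential_expression()]; only
#'   filter-passing records are considered.
#' @param sites site table from [scan_all_sites()] covering the candidate
#'   (miRNA, mRNA) pairs.
#' @param config a [coexpr_config()]; `min_site_type` sets the minimum site
#'   specificity.
#' @return edge data.frame (`node_a` = miRNA, `node_b` = mRNA) with an
#'   `n_sites` column.
#' @export
build_mirna_target_network <- function(em_mirna, em_mrna, de_mirna, de_mrna,
                                       sites, config = coexpr_config()) {
  stopifnot(identical(colnames(em_mirna$values), colnames(em_mrna$values)))
  dir_mir <- de_direction(de_mirna)
  dir_mrna <- de_direction(de_mrna)
  rank <- site_rank(config$min_site_type)
  sites <- sites[SITE_SPECIFICITY[sites$site_type] >= rank, , drop = FALSE]
  sites <- sites[sites$mirna_id %in% names(dir_mir) &
                   sites$target_id %in% names(dir_mrna), , drop = FALSE]
  if (!nrow(sites)) return(cbind(edge_frame(), n_sites = integer(0)))
  pairs <- unique(sites[, c("mirna_id", "target_id")])
  ids_m <- intersect(unique(pairs$mirna_id), rownames(em_mirna$values))
  ids_t <- intersect(unique(pairs$target_id), rownames(em_mrna$values))
  if (!length(ids_m) || !length(ids_t)) return(cbind(edge_frame(), n_sites = integer(0)))
  cm <- cor_matrix_with_p(em_log2(em_subset(em_mirna, ids_m), pseudo_count = 1),
                          em_log2(em_subset(em_mrna, ids_t)))
  out <- list()
  for (k in seq_len(nrow(pairs))) {
    m <- pairs$mirna_id[k]
    t <- pairs$target_id[k]
    if (!(m %in% ids_m) || !(t %in% ids_t)) next
    r <- cm$r[m, t]
    p <- cm$p[m, t]
    if (!is.finite(r) || r >= 0) next
    if (abs(r) < config$pcc_threshold || !(p < config$p_threshold)) next
    if (dir_mir[[m]] == dir_mrna[[t]]) next  # anti-directional DE required
    out[[length(out) + 1L]] <- data.frame(
      node_a = m, node_b = t, class_a = "miRNA", class_b = "mRNA",
      pcc = r, p_value = p, sign = "negative",
      n_sites = sum(sites$mirna_id == m & sites$target_id == t))
  }
  if (!length(out)) return(cbind(edge_frame(), n_sites = integer(0)))
  canonical_edges(do.call(rbind, out))
}

#' circRNA-miRNA-mRNA ceRNA triplet network
#'
#' A triplet (circRNA, miRNA, mRNA) is emitted iff the miRNA has canonical
#' seed sites on both the circRNA (scanned with circular topology, so sites
#' may span the backsplice junction) and the mRNA, and both miRNA-involving
#' correlation edges (circ-miR and miR-mRNA) pass the negative-correlation
#' retention rule of [build_mirna_target_network()]. The circ-mRNA
#' correlation is annotated but not gated. All members must be
#' filter-passing DE transcripts.
#'
#' @param em_circ,em_mirna,em_mrna expression matrices on the same samples.
#' @param de_circ,de_mirna,de_mrna DE tables; only filter-passing records
#'   enter the candidate sets.
#' @param circ_seqs,mrna_seqs,mirna_seqs sequence record lists; circRNA
#'   records must be circular. A DE circRNA or mRNA with no sequence is
#'   skipped (counted in attribute `n_missing_seq`).
#' @param config a [coexpr_config()].
#' @return data.frame of triplets with site counts, the three pairwise
#'   correlations and member directions, deduplicated and in canonical
#'   (circ, miRNA, mRNA) order.
#' @export
build_cerna_network <- function(em_circ, em_mirna, em_mrna,
                                de_circ, de_mirna, de_mrna,
                                circ_seqs, mrna_seqs, mirna_seqs,
                                config = coexpr_config()) {
  dir_circ <- de_direction(de_circ)
  dir_mir <- de_direction(de_mirna)
  dir_mrna <- de_direction(de_mrna)
  seq_ids <- function(seqs) vapply(seqs, `[[`, character(1), "id")
  mir_recs <- mirna_seqs[seq_ids(mirna_seqs) %in% names(dir_mir)]
  circ_recs <- circ_seqs[seq_ids(circ_seqs) %in% names(dir_circ)]
  mrna_recs <- mrna_seqs[seq_ids(mrna_seqs) %in% names(dir_mrna)]
  n_missing_seq <- (length(dir_circ) - length(circ_recs)) +
    (length(dir_mrna) - length(mrna_recs))
  for (r in circ_recs) {
    if (!identical(r$topology, "circular")) {
      stop_config("circRNA sequence ", r$id, " is not circular")
    }
  }
  empty <- data.frame(circ_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), n_sites_circ = integer(0),
                      n_sites_mrna = integer(0),
                      r_circ_mir = numeric(0), p_circ_mir = numeric(0),
                      r_mir_mrna = numeric(0), p_mir_mrna = numeric(0),
                      r_circ_mrna = numeric(0),
                      dir_circ = character(0), dir_mir = character(0),
                      dir_mrna = character(0))
  if (!length(mir_recs) || !length(circ_recs) || !length(mrna_recs)) {
    attr(empty, "n_missing_seq") <- n_missing_seq
    return(empty)
  }
  rank <- site_rank(config$min_site_type)
  keep_rank <- function(s) s[SITE_SPECIFICITY[s$site_type] >= rank, , drop = FALSE]
  sites_circ <- keep_rank(scan_all_sites(mir_recs, circ_recs))
  sites_mrna <- keep_rank(scan_all_sites(mir_recs, mrna_recs))

  ids_c <- intersect(unique(sites_circ$target_id), rownames(em_circ$values))
  ids_m <- intersect(unique(c(sites_circ$mirna_id, sites_mrna$mirna_id)),
                     rownames(em_mirna$values))
  ids_t <- intersect(unique(sites_mrna$target_id), rownames(em_mrna$values))
  if (!length(ids_c) || !length(ids_m) || !length(ids_t)) {
    attr(empty, "n_missing_seq") <- n_missing_seq
    return(empty)
  }
  log_mir <- em_log2(em_subset(em_mirna, ids_m), pseudo_count = 1)
  log_circ <- em_log2(em_subset(em_circ, ids_c))
  log_mrna <- em_log2(em_subset(em_mrna, ids_t))
  cm_cm <- cor_matrix_with_p(log_circ, log_mir)
  cm_mt <- cor_matrix_with_p(log_mir, log_mrna)
  cm_ct <- cor_matrix_with_p(log_circ, log_mrna)

  passes_neg <- function(r, p, dir1, dir2) {
    is.finite(r) && r < 0 && abs(r) >= config$pcc_threshold &&
      p < config$p_threshold && dir1 != dir2
  }
  out <- list()
  for (m in ids_m) {
    circs <- unique(sites_circ$target_id[sites_circ$mirna_id == m])
    mrnas <- unique(sites_mrna$target_id[sites_mrna$mirna_id == m])
    circs <- intersect(circs, ids_c)
    mrnas <- intersect(mrnas, ids_t)
    for (cc in circs) {
      if (!passes_neg(cm_cm$r[cc, m], cm_cm$p[cc, m], dir_circ[[cc]], dir_mir[[m]])) next
      for (tt in mrnas) {
        if (!passes_neg(cm_mt$r[m, tt], cm_mt$p[m, tt], dir_mir[[m]], dir_mrna[[tt]])) next
        out[[length(out) + 1L]] <- data.frame(
          circ_id = cc, mirna_id = m, mrna_id = tt,
          n_sites_circ = sum(sites_circ$mirna_id == m & sites_circ$target_id == cc),
          n_sites_mrna = sum(sites_mrna$mirna_id == m & sites_mrna$target_id == tt),
          r_circ_mir = cm_cm$r[cc, m], p_circ_mir = cm_cm$p[cc, m],
          r_mir_mrna = cm_mt$r[m, tt], p_mir_mrna = cm_mt$p[m, tt],
          r_circ_mrna = cm_ct$r[cc, tt],
          dir_circ = dir_circ[[cc]], dir_mir = dir_mir[[m]],
          dir_mrna = dir_mrna[[tt]])
      }
    }
  }
  if (!length(out)) {
    attr(empty, "n_missing_seq") <- n_missing_seq
    return(empty)
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$circ_id, res$mirna_id, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_missing_seq") <- n_missing_seq
  res
}

#' Node-attribute table for a ceRNA network
#'
#' The attribute scheme used to render ceRNA networks: transcript class,
#' regulation direction, |log2 fold change| and p-value per node.
#'
#' @param triplets triplet table from [build_cerna_network()].
#' @param de_circ,de_mirna,de_mrna the DE tables of the three classes.
#' @return data.frame `id`, `class`, `direction`, `abs_log2fc`, `p_value`.
#' @export
cerna_node_attributes <- function(triplets, de_circ, de_mirna, de_mrna) {
  pick <- function(ids, de, class) {
    de <- de[match(ids, de$transcript_id), , drop = FALSE]
    data.frame(id = ids, class = class, direction = de$direction,
               abs_log2fc = abs(de$log2fc), p_value = de$p_value)
  }
  res <- rbind(pick(unique(triplets$circ_id), de_circ, "circRNA"),
               pick(unique(triplets$mirna_id), de_mirna, "miRNA"),
               pick(unique(triplets$mrna_id), de_mrna, "mRNA"))
  res <- res[order(res$id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Expand ceRNA triplets to their pairwise edges
#'
#' @param triplets triplet table from [build_cerna_network()].
#' @return edge data.frame with the circ-miR and miR-mRNA edges.
#' @export
cerna_edges <- function(triplets) {
  if (!nrow(triplets)) return(edge_frame())
  e1 <- data.frame(node_a = triplets$circ_id, node_b = triplets$mirna_id,
                   class_a = "circRNA", class_b = "miRNA",
                   pcc = triplets$r_circ_mir, p_value = triplets$p_circ_mir,
                   sign = "negative")
  e2 <- data.frame(node_a = triplets$mirna_id, node_b = triplets$mrna_id,
                   class_a = "miRNA", class_b = "mRNA",
                   pcc = triplets$r_mir_mrna, p_value = triplets$p_mir_mrna,
                   sign = "negative")
  canonical_edges(unique(rbind(e1, e2)))
}

#' Summary statistics of a network
#'
#' @param x an edge data.frame (`node_a`/`node_b`) or a ceRNA triplet table
#'   (expanded to pairwise edges first).
#' @return `list(n_nodes, n_edges, degree, sign_counts)`; `degree` is a
#'   data.frame sorted by decreasing degree with id tie-break.
#' @export
network_summary <- function(x) {
  if (all(c("circ_id", "mirna_id", "mrna_id") %in% colnames(x))) {
    x <- cerna_edges(x)
  }
  nodes <- sort(unique(c(x$node_a, x$node_b)))
  if (length(nodes)) {
    deg <- table(factor(c(x$node_a, x$node_b), levels = nodes))
    degree <- data.frame(id = names(deg), degree = as.integer(deg))
    degree <- degree[order(-degree$degree, degree$id), , drop = FALSE]
    rownames(degree) <- NULL
  } else {
    degree <- data.frame(id = character(0), degree = integer(0))
  }
  sign_counts <- c(positive = sum(x$sign == "positive"),
                   negative = sum(x$sign == "negative"))
  list(n_nodes = length(nodes), n_edges = nrow(x),
       degree = degree, sign_counts = sign_counts)
}
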