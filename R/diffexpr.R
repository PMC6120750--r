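#' Differential-expression configuration
#'
#' Thresholds of the study's printed filter: fold change > 2 and p < 0.05,
#' both strict. The t statistic is computed on log2 values; for count
#' matrices (miRNA-seq) a pseudo-count is added before the log.
#'
#' @param fc_threshold linear fold-change threshold (> 1), default 2.
#' @param p_threshold raw p-value threshold in (0,1), default 0.05.
#' @param log_transform compute the test on log2 values (default TRUE).
#' @param pseudo_count added to counts before log2 (used only when
#'   `counts = TRUE` in [differential_expression()]), default 1.
#' @return a list of class `de_config`.
#' @export
de_config <- function(fc_threshold = 2, p_threshold = 0.05,
                      log_transform = TRUE, pseudo_count = 1) {
  if (!is.numeric(fc_threshold) || fc_threshold <= 1) {
    stop_config("fc_threshold must be > 1")
  }
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold >= 1) {
    stop_config("p_threshold must be in (0,1)")
  }
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 log_transform = isTRUE(log_transform),
                 pseudo_count = pseudo_count),
            class = "de_config")
}

#' Quantile normalization across samples
#'
#' Forces every sample column to the same distribution: each rank is
#' replaced by the across-sample mean of that rank's order statistics, with
#' ties within a column receiving the mean of the tied ranks' target values.
#' The grand sum of the matrix is preserved. Delegates to
#' `limma::normalizeQuantiles(ties = TRUE)`, the same procedure array
#' pipelines apply before fold-change calculations.
#'
#' @param x numeric matrix (transcripts x samples) or an `expr_matrix`.
#' @return object of the same kind with normalized values.
#' @export
quantile_normalize <- function(x) {
  em <- NULL
  if (inherits(x, "expr_matrix")) {
    em <- x
    x <- em$values
  }
  if (!is.matrix(x) || !is.numeric(x)) stop_format("x must be a numeric matrix")
  if (ncol(x) < 2L) {
    stop_config("quantile normalization needs >= 2 samples")
  }
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  if (!is.null(em)) {
    em$values <- out
    return(em)
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment via [stats::p.adjust()]; exposed as the single FDR
#' routine used by every stage of the pipeline.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values (same length/order).
#' @export
bh_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Two-group differential expression
#'
#' Per transcript: linear-scale group means and fold change
#' (case / control), two-sided equal-variance Student's t test on log2
#' values, BH FDR over all transcripts in the call, and the strict
#' `fold change > fc_threshold & p < p_threshold` filter. Degenerate rows
#' (zero variance in both groups) get p = 1 when the group means are equal,
#' and the smallest representable positive p (flagged in the `degenerate`
#' column) when they differ.
#'
#' @param em an [expression_matrix()] (linear scale). Both groups need
#'   >= 2 samples.
#' @param config a [de_config()].
#' @param counts treat values as counts: log2(value + pseudo_count).
#' @return data.frame with columns `transcript_id`, `mean_case`,
#'   `mean_control`, `fold_change`, `log2fc`, `p_value`, `fdr`, `direction`,
#'   `passes_filter`, `degenerate`, in input transcript order.
#' @export
differential_expression <- function(em, config = de_config(), counts = FALSE) {
  stopifnot(inherits(em, "expr_matrix"))
  case <- names(em$groups)[em$groups == "case"]
  ctrl <- names(em$groups)[em$groups == "control"]
  n1 <- length(case)
  n2 <- length(ctrl)
  if (n1 < 2L || n2 < 2L) {
    stop_config("both groups need >= 2 samples for the t test (case=", n1,
                ", control=", n2, ")")
  }
  v <- em$values
  mean_case <- rowMeans(v[, case, drop = FALSE])
  mean_control <- rowMeans(v[, ctrl, drop = FALSE])
  fold_change <- mean_case / mean_control
  log2fc <- log2(fold_change)

  y <- if (config$log_transform) {
    em_log2(em, pseudo_count = if (counts) config$pseudo_count else 0)
  } else {
    v
  }
  y1 <- y[, case, drop = FALSE]
  y2 <- y[, ctrl, drop = FALSE]
  m1 <- rowMeans(y1)
  m2 <- rowMeans(y2)
  ss1 <- rowSums((y1 - m1)^2)
  ss2 <- rowSums((y2 - m2)^2)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tstat), df)

  degenerate <- rep(FALSE, nrow(v))
  zero_var <- sp2 == 0
  if (any(zero_var)) {
    eq <- zero_var & (m1 == m2)
    p[eq] <- 1
    uneq <- zero_var & (m1 != m2)
    p[uneq] <- .Machine$double.xmin
    degenerate[uneq] <- TRUE
  }

  direction <- ifelse(fold_change > 1, "up",
                      ifelse(fold_change < 1, "down", "unchanged"))
  res <- data.frame(
    transcript_id = rownames(v),
    mean_case = mean_case,
    mean_control = mean_control,
    fold_change = fold_change,
    log2fc = log2fc,
    p_value = p,
    fdr = bh_fdr(p),
    direction = direction,
    passes_filter = (p < config$p_threshold) &
      (pmax(fold_change, 1 / fold_change) > config$fc_threshold),
    degenerate = degenerate,
    row.names = NULL
  )
  res
}

#' Write a differential-expression table
#'
#' Serializes the standard nine-column DE report.
#'
#' @param de data.frame from [differential_expression()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_tsv <- function(de, path) {
  cols <- c("transcript_id", "mean_case", "mean_control", "fold_change",
            "log2fc", "p_value", "fdr", "direction", "passes_filter")
  write_table_tsv(de[, cols], path)
}

#' Hierarchical clustering order of transcripts
#'
#' Agglomerative average-linkage clustering of transcript expression
#' profiles under the correlation distance 1 - PCC across samples — the
#' ordering used for expression heat maps of the significantly
#' differentially expressed transcripts. Rows are pre-sorted by id so the
#' leaf order is deterministic under ties.
#'
#' @param x numeric matrix (transcripts x samples) or `expr_matrix` (log2 is
#'   taken for an `expr_matrix` with no zero handling — pass a matrix for
#'   custom transforms); >= 2 rows.
#' @return `list(order, tree)`: ids in leaf order and the `hclust` tree.
#' @export
hierarchical_order <- function(x) {
  if (inherits(x, "expr_matrix")) x <- em_log2(x, pseudo_count = 1e-9)
  if (!is.matrix(x) || nrow(x) < 2L) {
    stop_config("hierarchical_order needs a matrix with >= 2 rows")
  }
  x <- x[order(rownames(x)), , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(x)))
  d <- 1 - cc
  if (any(is.na(d))) {
    warning("constant row(s): undefined correlation set to distance 1")
    d[is.na(d)] <- 1
  }
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(order = rownames(x)[hc$order], tree = hc)
}

#' Relative qPCR expression by the 2^-ddCt method
#'
#' Expression of a target gene normalized to a reference gene and the
#' control condition:
#' `ddCt = (Ct_target_case - Ct_ref_case) - (Ct_target_control - Ct_ref_control)`
#' and the returned linear ratio is `2^-ddCt`.
#'
#' @param ct_target_case,ct_ref_case,ct_target_control,ct_ref_control
#'   threshold-cycle values (finite, vectorized).
#' @return linear relative-expression ratio(s).
#' @export
relative_expression_ddct <- function(ct_target_case, ct_ref_case,
                                     ct_target_control, ct_ref_control) {
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_control - ct_ref_control)
  2^(-ddct)
}
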