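#' Expression matrix with a two-group sample design
#'
#' Lightweight container for a transcripts x samples table of linear-scale
#' intensities or counts, the case/control group of every sample, and the
#' transcript class (mRNA, lncRNA, circRNA or miRNA). All downstream stages
#' (normalization, differential expression, correlation networks) consume
#' this object.
#'
#' @param values numeric matrix, rows = transcripts (rownames required),
#'   columns = samples (colnames required). Linear scale, finite, >= 0.
#' @param groups named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @param transcript_class either a single class recycled to all transcripts
#'   or a named character vector over the rownames. One of
#'   `"mRNA"`, `"lncRNA"`, `"circRNA"`, `"miRNA"`.
#' @return an object of class `expr_matrix` with fields `values`, `groups`
#'   and `transcript_class`.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
#' g <- setNames(rep(c("case", "control"), each = 2), colnames(m))
#' em <- expression_matrix(m, g, "mRNA")
#' @export
expression_matrix <- function(values, groups, transcript_class) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_format("values must be a numeric matrix")
  }
  tid <- rownames(values)
  sid <- colnames(values)
  if (is.null(tid) || is.null(sid)) {
    stop_format("values must carry transcript rownames and sample colnames")
  }
  if (anyDuplicated(tid)) {
    stop_format("duplicate transcript id: ", tid[duplicated(tid)][1])
  }
  if (anyDuplicated(sid)) {
    stop_format("duplicate sample id: ", sid[duplicated(sid)][1])
  }
  if (!all(is.finite(values))) {
    stop_format("expression values must all be finite (missing values are not supported)")
  }
  if (any(values < 0)) {
    stop_format("expression values must be >= 0 on the linear scale")
  }
  missing_g <- setdiff(sid, names(groups))
  if (length(missing_g)) {
    stop_config("sample missing from group map: ", missing_g[1])
  }
  groups <- groups[sid]
  if (!all(groups %in% c("case", "control"))) {
    stop_config("groups must be 'case' or 'control'")
  }
  if (!all(c("case", "control") %in% groups)) {
    stop_config("both groups must be non-empty")
  }
  if (length(transcript_class) == 1L && is.null(names(transcript_class))) {
    transcript_class <- setNames(rep(transcript_class, length(tid)), tid)
  }
  missing_c <- setdiff(tid, names(transcript_class))
  if (length(missing_c)) {
    stop_config("transcript missing from class map: ", missing_c[1])
  }
  transcript_class <- transcript_class[tid]
  if (!all(transcript_class %in% TRANSCRIPT_CLASSES)) {
    stop_config("transcript_class must be one of ",
                paste(TRANSCRIPT_CLASSES, collapse = ", "))
  }
  structure(list(values = values,
                 groups = setNames(as.character(groups), sid),
                 transcript_class = transcript_class),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d transcripts x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  cls <- table(x$transcript_class)
  cat("classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix to a set of transcripts
#'
#' @param em an `expr_matrix`.
#' @param transcript_ids ids to keep (order preserved); ids absent from the
#'   matrix are dropped with a warning.
#' @return an `expr_matrix` over the retained transcripts.
#' @export
em_subset <- function(em, transcript_ids) {
  keep <- transcript_ids %in% rownames(em$values)
  if (!all(keep)) {
    warning(sum(!keep), " transcript(s) absent from matrix, e.g. ",
            transcript_ids[!keep][1])
  }
  ids <- transcript_ids[keep]
  expression_matrix(em$values[ids, , drop = FALSE], em$groups,
                    em$transcript_class[ids])
}

#' Read a tab-separated expression matrix
#'
#' First column `transcript_id`, header row of sample ids, numeric cells.
#'
#' @param path file path.
#' @param group_map named character vector sample id -> `"case"`/`"control"`;
#'   must cover every sample column.
#' @param transcript_class class of the transcripts in this file (one value).
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, group_map, transcript_class = "mRNA") {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop_format(path, ": expected transcript_id plus >= 1 sample column")
  tid <- raw[[1]]
  if (anyDuplicated(tid)) {
    stop_format(path, ": duplicate transcript id: ", tid[duplicated(tid)][1])
  }
  vals <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
                 dimnames = list(tid, colnames(raw)[-1]))
  for (j in seq_len(ncol(vals))) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop_format(path, ": non-numeric value '", col[bad[1]], "' at row ",
                  bad[1], " (", tid[bad[1]], "), column ", colnames(vals)[j])
    }
    vals[, j] <- num
  }
  expression_matrix(vals, group_map, transcript_class)
}

#' Write an expression matrix as TSV
#'
#' Full-precision serialization; `read_expression_tsv()` on the result
#' reproduces values and ordering exactly.
#'
#' @param em an `expr_matrix`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con))
    writeLines(paste(c("transcript_id", colnames(em$values)), collapse = "\t"), con)
    body <- apply(em$values, 1, function(r) paste(format_full(r), collapse = "\t"))
    writeLines(paste(rownames(em$values), body, sep = "\t"), con)
  })
}

#' Log2 values of an expression matrix
#'
#' @param em an `expr_matrix`.
#' @param pseudo_count added before the log for count data (0 for
#'   intensities). With `pseudo_count = 0` any zero value is an error.
#' @return numeric matrix of log2 values.
#' @export
em_log2 <- function(em, pseudo_count = 0) {
  v <- em$values + pseudo_count
  if (any(v <= 0)) {
    stop_config("zero values present; use a positive pseudo_count for count matrices")
  }
  log2(v)
}
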