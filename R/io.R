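#' Read FASTA sequences as RNA records
#'
#' Sequences are normalized to the RNA alphabet (T mapped to U, uppercased);
#' record ids are the first whitespace-delimited token of each header. The
#' topology (linear or circular) is a property of the file as a whole:
#' circRNA backsplice products are circular, everything else linear.
#'
#' @param path FASTA file.
#' @param topology `"linear"` or `"circular"`.
#' @return a list of sequence records, each `list(id, seq, topology)`,
#'   input order preserved.
#' @export
read_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  seqs <- as.character(set)
  empty <- which(nchar(seqs) == 0L)
  if (length(empty)) {
    stop_format(path, ": empty sequence for record ", ids[empty[1]])
  }
  seqs <- normalize_rna(seqs, ids)
  if (anyDuplicated(ids)) {
    stop_format(path, ": duplicate record id: ", ids[duplicated(ids)][1])
  }
  mapply(function(i, s) list(id = i, seq = s, topology = topology),
         ids, seqs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write sequence records as FASTA
#'
#' @param records list of `list(id, seq, ...)` records.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con))
    for (r in records) {
      writeLines(c(paste0(">", r$id), r$seq), con)
    }
  })
}

#' Read a GMT gene-set file
#'
#' Standard GMT: `term_id TAB description TAB member...`, one set per line.
#' Members are de-duplicated within a term.
#'
#' @param path GMT file.
#' @return a named list of gene sets, each `list(term_name, members)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_format(path, ": line ", i, " has ", length(f),
                  " fields; GMT needs term, description and >= 1 member")
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop_format(path, ": line ", i, " has no members")
    if (f[1] %in% names(sets)) stop_format(path, ": duplicate term id ", f[1])
    sets[[f[1]]] <- list(term_name = f[2], members = members)
  }
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of `list(term_name, members)`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con))
    for (id in names(sets)) {
      writeLines(paste(c(id, sets[[id]]$term_name, sets[[id]]$members),
                       collapse = "\t"), con)
    }
  })
}

## Canonical edge ordering shared by all network serializations: lexicographic
## by (node_a, node_b, sign), so permuting the input rows cannot change the
## bytes on disk.
canonical_edges <- function(edges) {
  need <- c("node_a", "node_b", "sign")
  missing <- setdiff(need, colnames(edges))
  if (length(missing)) {
    stop_config("edge table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(edges)) {
    edges <- edges[order(edges$node_a, edges$node_b, edges$sign), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}

#' Serialize a signed network
#'
#' Writes a correlation-edge table in one of three dialects with a
#' deterministic lexicographic node/edge order, so the output bytes do not
#' depend on the order edges were produced in.
#'
#' * `"tsv"` — full edge table (round-trips via [read_network()]),
#' * `"sif"` — `node_a <sign> node_b` (Cytoscape simple interaction format),
#' * `"graphml"` — nodes with a `class` attribute, edges with `pcc`,
#'   `p_value` and `sign`.
#'
#' @param edges data.frame with at least `node_a`, `node_b`, `sign`
#'   (`"positive"`/`"negative"`); `class_a`, `class_b`, `pcc`, `p_value`
#'   are serialized when present.
#' @param path output path.
#' @param dialect `"tsv"`, `"sif"` or `"graphml"`.
#' @return the path, invisibly.
#' @export
write_network <- function(edges, path, dialect = c("tsv", "sif", "graphml")) {
  if (length(dialect) == 1L && !dialect %in% c("tsv", "sif", "graphml")) {
    stop_config("unknown network dialect: ", dialect)
  }
  dialect <- match.arg(dialect)
  edges <- canonical_edges(edges)
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con))
    if (dialect == "tsv") {
      cols <- intersect(c("node_a", "node_b", "class_a", "class_b",
                          "pcc", "p_value", "sign"), colnames(edges))
      writeLines(paste(cols, collapse = "\t"), con)
      if (nrow(edges)) {
        body <- vapply(seq_len(nrow(edges)), function(i) {
          paste(vapply(cols, function(cn) {
            v <- edges[[cn]][i]
            if (is.numeric(v)) format_full(v) else as.character(v)
          }, character(1)), collapse = "\t")
        }, character(1))
        writeLines(body, con)
      }
    } else if (dialect == "sif") {
      if (nrow(edges)) {
        writeLines(paste(edges$node_a, edges$sign, edges$node_b, sep = "\t"), con)
      }
    } else {
      node_class <- character(0)
      for (side in c("a", "b")) {
        ids <- edges[[paste0("node_", side)]]
        cls <- edges[[paste0("class_", side)]] %||% rep("", length(ids))
        node_class[ids] <- cls
      }
      nodes <- sort(names(node_class))
      writeLines(c(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
        "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
        "  <key id=\"class\" for=\"node\" attr.name=\"class\" attr.type=\"string\"/>",
        "  <key id=\"pcc\" for=\"edge\" attr.name=\"pcc\" attr.type=\"double\"/>",
        "  <key id=\"p_value\" for=\"edge\" attr.name=\"p_value\" attr.type=\"double\"/>",
        "  <key id=\"sign\" for=\"edge\" attr.name=\"sign\" attr.type=\"string\"/>",
        "  <graph edgedefault=\"undirected\">"), con)
      for (n in nodes) {
        writeLines(sprintf("    <node id=\"%s\"><data key=\"class\">%s</data></node>",
                           n, node_class[[n]]), con)
      }
      if (nrow(edges)) {
        for (i in seq_len(nrow(edges))) {
          writeLines(sprintf(paste0(
            "    <edge source=\"%s\" target=\"%s\">",
            "<data key=\"pcc\">%s</data>",
            "<data key=\"p_value\">%s</data>",
            "<data key=\"sign\">%s</data></edge>"),
            edges$node_a[i], edges$node_b[i],
            format_full(edges$pcc[i] %||% NA_real_),
            format_full(edges$p_value[i] %||% NA_real_),
            edges$sign[i]), con)
        }
      }
      writeLines(c("  </graph>", "</graphml>"), con)
    }
  })
}

#' Read a network written by [write_network()]
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"sif"`.
#' @return edge data.frame in canonical order.
#' @export
read_network <- function(path, dialect = c("tsv", "sif")) {
  if (length(dialect) == 1L && !dialect %in% c("tsv", "sif")) {
    stop_config("unknown network dialect: ", dialect)
  }
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE, quote = "",
                            colClasses = "character")
    for (cn in intersect(c("pcc", "p_value"), colnames(df))) {
      df[[cn]] <- as.numeric(df[[cn]])
    }
    canonical_edges(df)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      return(data.frame(node_a = character(0), sign = character(0),
                        node_b = character(0)))
    }
    parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    canonical_edges(data.frame(node_a = parts[, 1], sign = parts[, 2],
                               node_b = parts[, 3]))
  }
}

#' Read a BED-like transcript annotation
#'
#' Six tab-separated columns: chrom, start, end, transcript_id, class,
#' strand. Coordinates are 0-based half-open.
#'
#' @param path file path.
#' @return data.frame with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`, `class`, `length`.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, quote = "")
  need <- c("chrom", "start", "end", "transcript_id", "class", "strand")
  missing <- setdiff(need, colnames(df))
  if (length(missing)) {
    stop_format(path, ": annotation lacks column(s): ",
                paste(missing, collapse = ", "))
  }
  if (any(df$start >= df$end)) stop_format(path, ": start must be < end")
  if (!all(df$strand %in% c("+", "-"))) stop_format(path, ": strand must be + or -")
  if (anyDuplicated(df$transcript_id)) {
    stop_format(path, ": duplicate transcript id: ",
                df$transcript_id[duplicated(df$transcript_id)][1])
  }
  if (!"length" %in% colnames(df)) df$length <- df$end - df$start
  df[, c("transcript_id", "chrom", "start", "end", "strand", "class", "length")]
}

#' Write a BED-like transcript annotation
#'
#' @param ann annotation data.frame (see [read_annotation_tsv()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_annotation_tsv <- function(ann, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con))
    writeLines("chrom\tstart\tend\ttranscript_id\tclass\tstrand\tlength", con)
    if (nrow(ann)) {
      writeLines(paste(ann$chrom, ann$start, ann$end, ann$transcript_id,
                       ann$class, ann$strand, ann$length, sep = "\t"), con)
    }
  })
}

#' Write a result table as TSV with deterministic formatting
#'
#' Numbers are serialized at full precision; writes are atomic.
#'
#' @param df data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  atomic_write(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con))
    writeLines(paste(colnames(df), collapse = "\t"), con)
    if (nrow(df)) {
      body <- vapply(seq_len(nrow(df)), function(i) {
        paste(vapply(colnames(df), function(cn) {
          v <- df[[cn]][i]
          if (is.numeric(v)) format_full(v) else as.character(v)
        }, character(1)), collapse = "\t")
      }, character(1))
      writeLines(body, con)
    }
  })
}
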