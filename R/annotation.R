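LNC_CATEGORIES <- c("intergenic", "intronic_antisense", "natural_antisense",
                    "bidirectional", "intron_sense_overlapping",
                    "exon_sense_overlapping")

## Build GRanges for coding models. `coding_exons` is a long table with one
## row per exon: gene_id, chrom, strand, start, end (0-based half-open).
coding_granges <- function(coding_exons) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  missing <- setdiff(need, colnames(coding_exons))
  if (length(missing)) {
    stop_format("coding model table lacks column(s): ",
                paste(missing, collapse = ", "))
  }
  if (!all(coding_exons$strand %in% c("+", "-"))) {
    stop_format("coding model strand must be + or -")
  }
  exons <- GenomicRanges::GRanges(
    seqnames = coding_exons$chrom,
    ranges = IRanges::IRanges(start = coding_exons$start + 1L,
                              end = coding_exons$end),
    strand = coding_exons$strand,
    gene_id = coding_exons$gene_id)
  # gene bodies and introns computed per gene in base R (small tables)
  body_df <- do.call(rbind, lapply(split(coding_exons, coding_exons$gene_id),
                                   function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end))
  }))
  intron_df <- do.call(rbind, lapply(split(coding_exons, coding_exons$gene_id),
                                     function(g) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2L) return(NULL)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1],
               start = g$end[-nrow(g)], end = g$start[-1])
  }))
  bodies_gr <- GenomicRanges::GRanges(
    seqnames = body_df$chrom,
    ranges = IRanges::IRanges(start = body_df$start + 1L, end = body_df$end),
    strand = body_df$strand, gene_id = body_df$gene_id)
  introns <- if (is.null(intron_df) || !nrow(intron_df)) {
    GenomicRanges::GRanges()
  } else {
    GenomicRanges::GRanges(
      seqnames = intron_df$chrom,
      ranges = IRanges::IRanges(start = intron_df$start + 1L,
                                end = intron_df$end),
      strand = intron_df$strand, gene_id = intron_df$gene_id)
  }
  # TSS: start of the body on +, end on - (1-based coordinates)
  tss_pos <- ifelse(body_df$strand == "+", body_df$start + 1L, body_df$end)
  list(exons = exons, bodies = bodies_gr, introns = introns,
       tss = data.frame(gene_id = body_df$gene_id, chrom = body_df$chrom,
                        strand = body_df$strand, tss = tss_pos))
}

#' Positional classification of lncRNAs against coding gene models
#'
#' Assigns each lncRNA exactly one of the six positional categories used in
#' lncRNA subgroup analyses: intergenic, intronic antisense, natural
#' antisense, bidirectional, intron sense-overlapping and exon
#' sense-overlapping. Precedence (first match wins):
#'
#' 1. `exon_sense_overlapping` — same strand, overlaps >= 1 coding exon;
#' 2. `intron_sense_overlapping` — same strand, overlaps a gene body but
#'    only its introns;
#' 3. `intronic_antisense` — opposite strand, contained entirely within one
#'    intron;
#' 4. `natural_antisense` — opposite strand, overlaps a gene body;
#' 5. `bidirectional` — no gene-body overlap; a coding TSS on the opposite
#'    strand lies head-to-head within `divergence_window` bp of the lncRNA
#'    TSS;
#' 6. `intergenic` — none of the above.
#'
#' @param lnc annotation data.frame for the lncRNAs (`transcript_id`,
#'   `chrom`, `start`, `end`, `strand`; 0-based half-open).
#' @param coding_exons long exon table for coding genes (`gene_id`, `chrom`,
#'   `strand`, `start`, `end`; 0-based half-open).
#' @param divergence_window max TSS-to-TSS distance (bp) for the
#'   bidirectional call, default 1000.
#' @return data.frame `transcript_id`, `category`.
#' @export
classify_lncrna <- function(lnc, coding_exons, divergence_window = 1000) {
  if (any(!lnc$strand %in% c("+", "-"))) {
    stop_format("lncRNA strand must be + or -")
  }
  cm <- coding_granges(coding_exons)
  q <- GenomicRanges::GRanges(
    seqnames = lnc$chrom,
    ranges = IRanges::IRanges(start = lnc$start + 1L, end = lnc$end),
    strand = lnc$strand)

  same_strand_hit <- function(subject) {
    h <- suppressWarnings(
      GenomicRanges::findOverlaps(q, subject, ignore.strand = TRUE))
    ss <- as.character(GenomicRanges::strand(q))[S4Vectors::queryHits(h)] ==
      as.character(GenomicRanges::strand(subject))[S4Vectors::subjectHits(h)]
    list(same = unique(S4Vectors::queryHits(h)[ss]),
         anti = unique(S4Vectors::queryHits(h)[!ss]))
  }
  ex <- same_strand_hit(cm$exons)
  body <- same_strand_hit(cm$bodies)
  within_intron <- suppressWarnings(
    GenomicRanges::findOverlaps(q, cm$introns, type = "within",
                                ignore.strand = TRUE))
  wi_anti <- unique(S4Vectors::queryHits(within_intron)[
    as.character(GenomicRanges::strand(q))[S4Vectors::queryHits(within_intron)] !=
      as.character(GenomicRanges::strand(cm$introns))[S4Vectors::subjectHits(within_intron)]])
  any_body <- unique(c(body$same, body$anti))

  n <- nrow(lnc)
  category <- rep(NA_character_, n)
  category[ex$same] <- "exon_sense_overlapping"
  idx <- setdiff(body$same, ex$same)
  category[idx] <- "intron_sense_overlapping"
  idx <- setdiff(wi_anti, which(!is.na(category)))
  category[idx] <- "intronic_antisense"
  idx <- setdiff(body$anti, which(!is.na(category)))
  category[idx] <- "natural_antisense"

  # bidirectional: only transcripts with no gene-body overlap at all
  free <- which(is.na(category))
  free <- setdiff(free, any_body)
  if (length(free)) {
    lnc_tss <- ifelse(lnc$strand == "+", lnc$start + 1L, lnc$end)
    for (i in free) {
      cand <- cm$tss[cm$tss$chrom == lnc$chrom[i] &
                       cm$tss$strand != lnc$strand[i], , drop = FALSE]
      if (!nrow(cand)) next
      # head-to-head (divergent): the + partner must start at/right of the
      # - partner's TSS so transcription runs apart.
      if (lnc$strand[i] == "+") {
        ok <- lnc_tss[i] >= cand$tss
      } else {
        ok <- cand$tss >= lnc_tss[i]
      }
      d <- abs(cand$tss - lnc_tss[i])
      if (any(ok & d <= divergence_window)) category[i] <- "bidirectional"
    }
  }
  category[is.na(category)] <- "intergenic"
  data.frame(transcript_id = lnc$transcript_id, category = category,
             row.names = NULL)
}

#' Length histogram of transcripts
#'
#' Left-closed right-open bins. The default edges start at 200 bp (the
#' lncRNA length definition) and end open-ended above 3 kb. Transcripts
#' shorter than the first edge are collected into a `sub_minimum` overflow
#' bin with a warning.
#'
#' @param lengths numeric vector of transcript lengths (bp).
#' @param bin_edges increasing breaks; `Inf` appended if absent.
#' @return named integer vector of counts; names like `[200,1000)`.
#' @export
length_histogram <- function(lengths, bin_edges = c(200, 1000, 2000, 3000, Inf)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop_config("bin_edges must be strictly increasing")
  }
  if (!is.infinite(bin_edges[length(bin_edges)])) bin_edges <- c(bin_edges, Inf)
  labs <- paste0("[", bin_edges[-length(bin_edges)], ",",
                 bin_edges[-1], ")")
  counts <- setNames(integer(length(labs)), labs)
  sub <- sum(lengths < bin_edges[1])
  if (sub > 0) {
    warning(sub, " transcript(s) shorter than the first bin edge (",
            bin_edges[1], " bp)")
  }
  if (length(lengths)) {
    inb <- lengths[lengths >= bin_edges[1]]
    if (length(inb)) {
      idx <- findInterval(inb, bin_edges, left.open = FALSE)
      tab <- table(factor(idx, levels = seq_along(labs)))
      counts[] <- as.integer(tab)
    }
  }
  c(counts, sub_minimum = sub)
}

#' Gene-count-normalized chromosome distribution of deregulated transcripts
#'
#' For each chromosome: the fraction of deregulated transcripts located
#' there divided by the fraction of all genes located there — the
#' "normalized by the amount of genes per chromosome" enrichment ratio.
#'
#' @param deregulated ids of deregulated transcripts.
#' @param annotation annotation data.frame (`transcript_id`, `chrom`).
#' @param genes_per_chrom named numeric vector: chromosome -> gene count;
#'   must be positive for every chromosome bearing a deregulated transcript.
#' @return data.frame `chrom`, `n_deregulated`, `n_genes_on_chrom`,
#'   `fraction_deregulated`, `fraction_genes`, `enrichment_ratio`, sorted by
#'   decreasing ratio (chromosome name breaks ties). Ids absent from the
#'   annotation are excluded with a warning; the count of exclusions is
#'   attached as attribute `n_missing`.
#' @export
chromosome_enrichment <- function(deregulated, annotation, genes_per_chrom) {
  hit <- match(deregulated, annotation$transcript_id)
  missing <- is.na(hit)
  if (any(missing)) {
    warning(sum(missing), " deregulated id(s) absent from annotation, e.g. ",
            deregulated[missing][1])
  }
  chroms <- annotation$chrom[hit[!missing]]
  if (!length(chroms)) stop_config("no deregulated transcript found in annotation")
  tab <- table(chroms)
  bad <- setdiff(names(tab), names(genes_per_chrom))
  if (length(bad) || any(genes_per_chrom[names(tab)] <= 0)) {
    stop_config("genes_per_chrom must be positive for every chromosome ",
                "bearing a deregulated transcript")
  }
  res <- data.frame(
    chrom = names(tab),
    n_deregulated = as.integer(tab),
    n_genes_on_chrom = as.numeric(genes_per_chrom[names(tab)]),
    row.names = NULL
  )
  res$fraction_deregulated <- res$n_deregulated / sum(res$n_deregulated)
  res$fraction_genes <- res$n_genes_on_chrom / sum(genes_per_chrom)
  res$enrichment_ratio <- res$fraction_deregulated / res$fraction_genes
  res <- res[order(-res$enrichment_ratio, res$chrom), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_missing") <- sum(missing)
  res
}
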