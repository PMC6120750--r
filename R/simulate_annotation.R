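LNC_CATEGORY_PROBS <- c(intergenic = 0.6245, intronic_antisense = 0.1328,
                        natural_antisense = 0.1138, bidirectional = 0.0616,
                        intron_sense_overlapping = 0.0495,
                        exon_sense_overlapping = 0.0179)

#' Simulate a toy genome annotation with known lncRNA categories
#'
#' Lays every coding gene out in its own 100 kb block (three exons, two
#' introns, alternating strand) across chromosomes chr1-chr22/chrX, and
#' places each lncRNA in one block so that it realizes a known positional
#' category: overlapping an exon on the same strand, inside an intron on
#' either strand, antisense across an exon, divergently transcribed within
#' the TSS window, or tens of kilobases from any gene. Category frequencies
#' follow the distribution typical of deregulated lncRNA sets (intergenic
#' dominating), with every category represented at least once; lncRNA
#' lengths are drawn mostly from the 200-1000 bp range. circRNA and miRNA
#' loci are placed inside host blocks for completeness.
#'
#' @param config a [sim_config()].
#' @param truth truth set from [simulate_expression()] (used only for ids).
#' @return `list(transcripts, coding_exons, genes_per_chrom,
#'   lnc_categories)`: the BED-like annotation of all transcript classes,
#'   the long exon table of the coding models, the per-chromosome coding
#'   gene counts, and the true category per lncRNA.
#' @export
simulate_annotation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_rng(derive_seed(cfg$seed, 3L), {
    chroms <- paste0("chr", c(1:22, "X"))
    mrna_ids <- sim_ids("mRNA", cfg$n_mrna)
    lnc_ids <- sim_ids("lncRNA", cfg$n_lncrna)
    circ_ids <- sim_ids("circRNA", cfg$n_circrna)
    mir_ids <- sim_ids("miRNA", cfg$n_mirna)

    block_chrom <- sample(chroms, cfg$n_mrna, replace = TRUE)
    block_index <- stats::ave(seq_len(cfg$n_mrna), block_chrom,
                              FUN = seq_along)
    block_start <- (block_index - 1L) * 100000L
    gene_start <- block_start + 10000L
    gene_strand <- ifelse(seq_len(cfg$n_mrna) %% 2L == 1L, "+", "-")

    exon_off <- rbind(c(0L, 300L), c(1000L, 1300L), c(2000L, 2400L))
    coding_exons <- data.frame(
      gene_id = rep(mrna_ids, each = 3L),
      chrom = rep(block_chrom, each = 3L),
      strand = rep(gene_strand, each = 3L),
      start = rep(gene_start, each = 3L) + rep(exon_off[, 1], cfg$n_mrna),
      end = rep(gene_start, each = 3L) + rep(exon_off[, 2], cfg$n_mrna))

    mrna_ann <- data.frame(transcript_id = mrna_ids, chrom = block_chrom,
                           start = gene_start, end = gene_start + 2400L,
                           strand = gene_strand, class = "mRNA",
                           length = 2400L)

    ## lncRNA categories: each represented once, remainder multinomial
    n_l <- cfg$n_lncrna
    cats <- names(LNC_CATEGORY_PROBS)
    category <- c(cats[seq_len(min(length(cats), n_l))],
                  if (n_l > length(cats)) {
                    sample(cats, n_l - length(cats), replace = TRUE,
                           prob = LNC_CATEGORY_PROBS)
                  })
    flip <- function(s) ifelse(s == "+", "-", "+")
    g <- gene_start[seq_len(n_l)]
    s_g <- gene_strand[seq_len(n_l)]
    l_start <- integer(n_l)
    l_end <- integer(n_l)
    l_strand <- character(n_l)
    set_cat <- function(which, start, end, strand) {
      l_start[which] <<- start
      l_end[which] <<- end
      l_strand[which] <<- strand
    }
    i <- category == "exon_sense_overlapping"
    set_cat(i, g[i] + 100L, g[i] + 500L, s_g[i])
    i <- category == "intron_sense_overlapping"
    set_cat(i, g[i] + 350L, g[i] + 950L, s_g[i])
    i <- category == "intronic_antisense"
    set_cat(i, g[i] + 1350L, g[i] + 1950L, flip(s_g[i]))
    i <- category == "natural_antisense"
    set_cat(i, g[i] + 2100L, g[i] + 2600L, flip(s_g[i]))
    i <- category == "bidirectional" & s_g == "+"
    set_cat(i, g[i] - 700L, g[i] - 200L, "-")
    i <- category == "bidirectional" & s_g == "-"
    set_cat(i, g[i] + 2600L, g[i] + 3100L, "+")
    i <- category == "intergenic"
    if (any(i)) {
      n_i <- sum(i)
      u <- stats::runif(n_i)
      len <- round(ifelse(u < 0.7, stats::runif(n_i, 200, 1000),
                          ifelse(u < 0.9, stats::runif(n_i, 1000, 2000),
                                 stats::runif(n_i, 2000, 4000))))
      set_cat(i, g[i] + 40000L, g[i] + 40000L + as.integer(len),
              sample(c("+", "-"), n_i, replace = TRUE))
    }
    lnc_ann <- data.frame(transcript_id = lnc_ids,
                          chrom = block_chrom[seq_len(n_l)],
                          start = l_start, end = l_end,
                          strand = l_strand, class = "lncRNA",
                          length = l_end - l_start)

    circ_ann <- data.frame(
      transcript_id = circ_ids,
      chrom = block_chrom[seq_len(cfg$n_circrna)],
      start = gene_start[seq_len(cfg$n_circrna)] + 1300L,
      end = gene_start[seq_len(cfg$n_circrna)] + 1300L + cfg$circ_length,
      strand = gene_strand[seq_len(cfg$n_circrna)], class = "circRNA",
      length = cfg$circ_length)
    mir_ann <- data.frame(
      transcript_id = mir_ids,
      chrom = block_chrom[seq_len(cfg$n_mirna)],
      start = gene_start[seq_len(cfg$n_mirna)] + 5000L,
      end = gene_start[seq_len(cfg$n_mirna)] + 5000L + cfg$mirna_length,
      strand = "+", class = "miRNA", length = cfg$mirna_length)

    transcripts <- rbind(mrna_ann, lnc_ann, circ_ann, mir_ann)
    rownames(transcripts) <- NULL
    genes_per_chrom <- table(factor(block_chrom, levels = chroms))
    genes_per_chrom <- setNames(as.numeric(genes_per_chrom),
                                names(genes_per_chrom))
    genes_per_chrom <- genes_per_chrom[genes_per_chrom > 0]
    list(transcripts = transcripts, coding_exons = coding_exons,
         genes_per_chrom = genes_per_chrom,
         lnc_categories = data.frame(transcript_id = lnc_ids,
                                     category = category))
  })
}

## Synthetic GMT: one term enriched in the upregulated DE mRNAs plus
## random background terms over the mRNA universe.
simulate_gene_sets <- function(config, truth) {
  cfg <- config
  with_rng(derive_seed(cfg$seed, 4L), {
    mrna_ids <- sim_ids("mRNA", cfg$n_mrna)
    up <- truth$de$transcript_id[truth$de$class == "mRNA" &
                                   truth$de$direction == "up"]
    size <- min(cfg$gmt_term_size, cfg$n_mrna)
    n_hit <- min(length(up), max(1L, round(0.75 * size)))
    sets <- list()
    if (n_hit > 0) {
      members <- c(sample(up, n_hit),
                   sample(setdiff(mrna_ids, up), size - n_hit))
      sets[["SET_0001"]] <- list(
        term_name = "osteogenic differentiation (planted)",
        members = sort(members))
    }
    for (k in seq_len(max(0L, cfg$n_gmt_terms - length(sets)))) {
      sets[[sprintf("SET_%04d", k + 1L)]] <- list(
        term_name = sprintf("background set %d", k),
        members = sort(sample(mrna_ids, size)))
    }
    sets
  })
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_expression()], [simulate_sequences()],
#' [simulate_annotation()] and the synthetic GMT generator under one seed
#' and merges the planted truth (including the planted enriched term and
#' the true lncRNA categories).
#'
#' @param config a [sim_config()].
#' @return `list(matrices, sequences, annotation, gene_sets, truth,
#'   config)`.
#' @export
simulate_study <- function(config = sim_config()) {
  expr <- simulate_expression(config)
  seqs <- simulate_sequences(config, expr$truth)
  ann <- simulate_annotation(config, expr$truth)
  sets <- simulate_gene_sets(config, expr$truth)
  truth <- expr$truth
  truth$lnc_categories <- ann$lnc_categories
  truth$planted_term <- if ("SET_0001" %in% names(sets)) "SET_0001" else NA_character_
  list(matrices = expr$matrices, sequences = seqs, annotation = ann,
       gene_sets = sets, truth = truth, config = config)
}

#' Write a simulated study to disk
#'
#' Serializes the expression matrices (TSV), sequences (FASTA), annotation
#' (BED-like TSV plus the coding exon table and per-chromosome gene
#' counts), gene sets (GMT), sample groups (TSV) and the truth set (JSON).
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  for (cl in names(study$matrices)) {
    write_expression_tsv(study$matrices[[cl]], p(sprintf("expr_%s.tsv", cl)))
  }
  groups <- study$matrices[[1]]$groups
  write_table_tsv(data.frame(sample_id = names(groups), group = groups),
                  p("groups.tsv"))
  write_fasta(study$sequences$mirnas, p("mirnas.fa"))
  write_fasta(study$sequences$mrna_utrs, p("mrna_utrs.fa"))
  write_fasta(study$sequences$circrnas, p("circrnas.fa"))
  write_annotation_tsv(study$annotation$transcripts, p("annotation.tsv"))
  write_table_tsv(study$annotation$coding_exons, p("coding_exons.tsv"))
  write_table_tsv(data.frame(chrom = names(study$annotation$genes_per_chrom),
                             n_genes = study$annotation$genes_per_chrom),
                  p("genes_per_chrom.tsv"))
  write_gmt(study$gene_sets, p("gene_sets.gmt"))
  atomic_write(p("truth.json"), function(tmp) {
    jsonlite::write_json(study$truth, tmp, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  })
  invisible(dir)
}
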