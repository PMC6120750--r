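#!/usr/bin/env Rscript

# Subclassify the deregulated lncRNAs by genomic position (six categories),
# tabulate their length distribution, and rank chromosomes by deregulated
# density after normalizing for the number of genes per chromosome.

library(olfcerna)

study_dir <- "results/study"
out <- "results/annotation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_annotation_tsv(file.path(study_dir, "annotation.tsv"))
coding <- read.delim(file.path(study_dir, "coding_exons.tsv"))
gpc_df <- read.delim(file.path(study_dir, "genes_per_chrom.tsv"))
gpc <- setNames(gpc_df$n_genes, gpc_df$chrom)
truth <- jsonlite::read_json(file.path(study_dir, "truth.json"),
                             simplifyVector = TRUE)
de_lnc <- read.delim("results/de/de_lncRNA.tsv")
dereg <- de_lnc$transcript_id[de_lnc$passes_filter]

lnc <- ann[ann$class == "lncRNA", ]
cls <- classify_lncrna(lnc, coding, divergence_window = 1000)
write_table_tsv(cls, file.path(out, "lncrna_classes.tsv"))

dereg_cls <- cls[cls$transcript_id %in% dereg, ]
pct <- sort(100 * table(dereg_cls$category) / nrow(dereg_cls),
            decreasing = TRUE)
cat("deregulated lncRNA categories (%):\n")
print(round(pct, 2))

agree <- mean(cls$category == truth$lnc_categories$category[
  match(cls$transcript_id, truth$lnc_categories$transcript_id)])
cat(sprintf("agreement with planted categories: %.1f%%\n", 100 * agree))

hist <- length_histogram(lnc$length[lnc$transcript_id %in% dereg])
write_table_tsv(data.frame(bin = names(hist), count = as.integer(hist)),
                file.path(out, "length_histogram.tsv"))
cat("deregulated lncRNA length bins:\n")
print(hist)

chrom <- chromosome_enrichment(dereg, ann, gpc)
write_table_tsv(chrom, file.path(out, "chromosome_enrichment.tsv"))
cat("top chromosomes by gene-count-normalized deregulation:\n")
print(head(chrom, 3))
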