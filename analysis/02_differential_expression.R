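#!/usr/bin/env Rscript

# Quantile-normalize the array classes, run per-class two-group DE
# (Student's t on log2 values, BH FDR, strict fold change > 2 & p < 0.05
# filter) and score the calls against the planted truth.

library(olfcerna)

study_dir <- "results/study"
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups_df <- read.delim(file.path(study_dir, "groups.tsv"))
groups <- setNames(groups_df$group, groups_df$sample_id)
truth <- jsonlite::read_json(file.path(study_dir, "truth.json"),
                             simplifyVector = TRUE)

for (cl in c("mRNA", "lncRNA", "circRNA", "miRNA")) {
  em <- read_expression_tsv(file.path(study_dir, sprintf("expr_%s.tsv", cl)),
                            groups, cl)
  is_counts <- cl == "miRNA"
  if (!is_counts) em <- quantile_normalize(em)
  de <- differential_expression(em, de_config(), counts = is_counts)
  write_de_tsv(de, file.path(out, sprintf("de_%s.tsv", cl)))

  planted <- truth$de$transcript_id[truth$de$class == cl]
  hit <- de$transcript_id %in% planted
  up <- sum(de$passes_filter & de$direction == "up")
  down <- sum(de$passes_filter & de$direction == "down")
  cat(sprintf(
    "%-8s %4d up / %4d down at FC>2 & p<0.05 | sensitivity %5.1f%% (%d planted), false positives %d\n",
    cl, up, down, 100 * sum(de$passes_filter[hit]) / max(1, length(planted)),
    length(planted), sum(de$passes_filter[!hit])))

  # heat-map leaf order of the significant transcripts
  sig <- de$transcript_id[de$passes_filter]
  if (length(sig) >= 2) {
    ord <- hierarchical_order(log2(em$values[sig, , drop = FALSE] +
                                     as.integer(is_counts)))
    writeLines(ord$order, file.path(out, sprintf("cluster_order_%s.txt", cl)))
  }
}
cat("DE tables and clustering orders written to", out, "\n")
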