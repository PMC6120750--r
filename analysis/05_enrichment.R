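#!/usr/bin/env Rscript

# Hypergeometric over-representation of the upregulated mRNAs against the
# study gene sets, reported with the -log10(p) enrichment score and BH FDR.

library(olfcerna)

study_dir <- "results/study"
out <- "results/enrichment"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sets <- read_gmt(file.path(study_dir, "gene_sets.gmt"))
truth <- jsonlite::read_json(file.path(study_dir, "truth.json"),
                             simplifyVector = TRUE)
de <- read.delim("results/de/de_mRNA.tsv")
universe <- de$transcript_id
query <- de$transcript_id[de$passes_filter & de$direction == "up"]

res <- hypergeometric_enrich(query, sets, universe)
res <- top_terms(res, nrow(res))
write_table_tsv(res, file.path(out, "enrichment_up_mRNA.tsv"))

cat(sprintf("query: %d upregulated mRNAs over a universe of %d\n",
            length(query), length(universe)))
cat("top terms by enrichment score:\n")
top <- top_terms(res, 5)
print(data.frame(term = top$term_id, k = top$k, K = top$K,
                 score = round(top$enrichment_score, 2),
                 fdr = signif(top$fdr, 3)))
cat(sprintf("planted term %s ranks %d (FDR %.3g)\n", truth$planted_term,
            which(res$term_id == truth$planted_term),
            res$fdr[res$term_id == truth$planted_term]))
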