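#!/usr/bin/env Rscript

# Build the three integration networks: the coding/non-coding (CNC)
# co-expression network at |PCC| >= 0.968 & p < 0.05, the
# negatively-correlated seed-site-backed miRNA target network, and the
# circRNA-miRNA-mRNA ceRNA triplet network, then score them against the
# planted truth.

library(olfcerna)

study_dir <- "results/study"
out <- "results/networks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups_df <- read.delim(file.path(study_dir, "groups.tsv"))
groups <- setNames(groups_df$group, groups_df$sample_id)
truth <- jsonlite::read_json(file.path(study_dir, "truth.json"),
                             simplifyVector = TRUE)

em <- de <- list()
for (cl in c("mRNA", "lncRNA", "circRNA", "miRNA")) {
  m <- read_expression_tsv(file.path(study_dir, sprintf("expr_%s.tsv", cl)),
                           groups, cl)
  if (cl != "miRNA") m <- quantile_normalize(m)
  em[[cl]] <- m
  de[[cl]] <- read.delim(sprintf("results/de/de_%s.tsv", cl))
}
pf <- function(cl) de[[cl]]$transcript_id[de[[cl]]$passes_filter]

cnc <- build_cnc_network(em$mRNA, em$lncRNA, pf("mRNA"), pf("lncRNA"))
write_network(cnc, file.path(out, "cnc_edges.tsv"), "tsv")
write_network(cnc, file.path(out, "cnc_edges.sif"), "sif")
s <- network_summary(cnc)
cat(sprintf("CNC network: %d nodes, %d connections (%d positive, %d negative)\n",
            s$n_nodes, s$n_edges, s$sign_counts["positive"],
            s$sign_counts["negative"]))
pr <- truth$coexpr_pairs
sgn <- cnc$sign[match(paste(pr$mrna_id, pr$lncrna_id),
                      paste(cnc$node_a, cnc$node_b))]
cat(sprintf("planted pairs recovered with correct sign: %d/%d\n",
            sum(!is.na(sgn) & sgn == pr$sign), nrow(pr)))

ids <- function(x) vapply(x, `[[`, character(1), "id")
mirs <- read_fasta(file.path(study_dir, "mirnas.fa"), "linear")
utrs <- read_fasta(file.path(study_dir, "mrna_utrs.fa"), "linear")
circs <- read_fasta(file.path(study_dir, "circrnas.fa"), "circular")
mirs_de <- mirs[ids(mirs) %in% pf("miRNA")]
utrs_de <- utrs[ids(utrs) %in% pf("mRNA")]
circs_de <- circs[ids(circs) %in% pf("circRNA")]

sites <- scan_all_sites(mirs_de, utrs_de)
tgt <- build_mirna_target_network(em$miRNA, em$mRNA, de$miRNA, de$mRNA, sites)
write_table_tsv(tgt, file.path(out, "target_edges.tsv"))
cat(sprintf("miRNA target network: %d negatively correlated, site-backed edges\n",
            nrow(tgt)))

trip <- build_cerna_network(em$circRNA, em$miRNA, em$mRNA,
                            de$circRNA, de$miRNA, de$mRNA,
                            circs_de, utrs_de, mirs_de)
write_table_tsv(trip, file.path(out, "cerna_triplets.tsv"))
write_network(cerna_edges(trip), file.path(out, "cerna_edges.sif"), "sif")
if (nrow(trip)) {
  write_table_tsv(cerna_node_attributes(trip, de$circRNA, de$miRNA, de$mRNA),
                  file.path(out, "cerna_node_attributes.tsv"))
}
tt <- truth$triplets
got <- paste(trip$circ_id, trip$mirna_id, trip$mrna_id)
want <- paste(tt$circ_id, tt$mirna_id, tt$mrna_id)
cat(sprintf("ceRNA network: %d triplets; planted recovered %d/%d; unplanted %d\n",
            nrow(trip), sum(want %in% got), length(want),
            sum(!got %in% want)))
cat(sprintf("junction-spanning planted circRNA sites: %d\n",
            sum(truth$planted_sites$spans_junction)))
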