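# olfcerna

Multi-omics integration pipeline for **ossification of the ligamentum
flavum (OLF)** — ectopic bone formation in a spinal ligament — comparing
ossified against normal tissue (4 vs 4 samples) across four transcript
classes (mRNA, lncRNA, circRNA, miRNA) and inferring competing-endogenous-RNA
(ceRNA) circuitry. The package is aimed at transcriptomics analysts who
want the complete, testable chain from expression matrices and sequences
to differential-expression tables, co-expression and target networks, and
ceRNA triplets, with a seeded synthetic-data generator that plants known
truth so every stage can be validated.

## What it computes

* **Differential expression** per class: quantile normalization, two-sided
  equal-variance Student's *t* on log2 values, fold change from linear
  group means, the strict filter **FC > 2 & p < 0.05**, BH FDR alongside;
  average-linkage clustering (distance 1 − PCC) for heat-map ordering, and
  the 2^−ΔΔCt qPCR helper.
* **lncRNA subclassification** into intergenic, intronic antisense,
  natural antisense, bidirectional, intron sense-overlapping and exon
  sense-overlapping, plus length histograms and gene-count-normalized
  chromosome enrichment.
* **Canonical miRNA seed sites** (6mer, 7mer-A1, 7mer-m8, 8mer; seed =
  miRNA positions 2–7, target-strand patterns by reverse complement, A
  anchor) on linear transcripts *and* circular RNAs, where a site may span
  the backsplice junction.
* **Networks**: the coding/non-coding (CNC) co-expression network at
  **|PCC| ≥ 0.968, p < 0.05** (pooled samples); the miRNA target network
  (seed site + strong negative correlation + anti-directional DE); and the
  **circRNA–miRNA–mRNA ceRNA network** — a triplet is emitted when the
  same miRNA has sites on both the circRNA and the mRNA and both
  miRNA-involving edges pass the negative-correlation rule.
* **Enrichment**: upper-tail hypergeometric over-representation against
  GMT gene sets, enrichment score = −log10(p), BH FDR.

## Worked example

The numbered scripts under `analysis/` run the whole study; `run_pipeline()`
does the same in one call. Generating the synthetic study and running the
network stage:

```r
library(olfcerna)
summary <- run_pipeline(list(seed = 1, out_dir = "results/run"))
```

or step by step via the scripts:

```sh
Rscript analysis/01_simulate_study.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_lncrna_annotation.R
Rscript analysis/04_networks.R
Rscript analysis/05_enrichment.R
```

which prints (seed 1):

```
transcripts: 2000 mRNA, 1500 lncRNA, 400 circRNA, 150 miRNA
planted DE transcripts: 405 (|log2FC| >= 1.2)
planted co-expression pairs: 10; planted ceRNA triplets: 5

mRNA      101 up /   96 down at FC>2 & p<0.05 | sensitivity  98.5% (200 planted), false positives 0
lncRNA     73 up /   75 down at FC>2 & p<0.05 | sensitivity  98.7% (150 planted), false positives 0
circRNA    20 up /   20 down at FC>2 & p<0.05 | sensitivity 100.0% (40 planted), false positives 0
miRNA       7 up /    8 down at FC>2 & p<0.05 | sensitivity 100.0% (15 planted), false positives 0

deregulated lncRNA categories (%): intergenic 59.46, intronic_antisense 14.19,
  natural_antisense 13.51, bidirectional 8.11, intron_sense_overlapping 3.38,
  exon_sense_overlapping 1.35   (agreement with planted categories: 100.0%)

CNC network: 337 nodes, 11523 connections (5691 positive, 5832 negative)
miRNA target network: 5 negatively correlated, site-backed edges
ceRNA network: 5 triplets; planted recovered 5/5; unplanted 0

planted term SET_0001 ranks 1 (FDR 2.37e-15)
```

Reading the numbers: every planted ceRNA triplet is recovered and nothing
else passes the shared-site + negative-correlation gates; the DE filter
finds ~99% of planted > 2-fold changes with no false positives at this
noise level; the lncRNA classifier reproduces the planted positional
categories exactly, with the intergenic class dominating as expected for
deregulated lncRNA sets. The large CNC edge count is expected: in a
two-group design every strongly deregulated transcript pair correlates
across pooled samples, which is precisely the property the study's CNC
construction exploits.

A single seed-site query:

```r
site_patterns("UGAGGUAGUAGGUUGUAUAGUU")   # let-7a
#>      8mer    7mer_m8    7mer_A1       6mer
#> "CUACCUCA"  "CUACCUC"  "UACCUCA"   "UACCUC"
scan_sites(list(id = "let7", seq = "UGAGGUAGUAGGUUGUAUAGUU"),
           list(id = "circ", seq = "CCUCAGGGGGGCUA", topology = "circular"))
#>   mirna_id target_id site_type start length spans_junction
#> 1     let7      circ      8mer    11      8           TRUE
```

The same fourteen bases scanned as a linear sequence contain no site — the
8mer only exists across the backsplice junction.

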