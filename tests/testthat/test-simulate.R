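# a small but complete configuration keeps the generator tests fast
small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_mrna = 150, n_lncrna = 100, n_circrna = 40,
             n_mirna = 30, n_cerna_triplets = 3, n_coexpr_pairs = 4, ...)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_study(small_cfg(seed = 42))
  b <- simulate_study(small_cfg(seed = 42))
  expect_identical(a$matrices$mRNA$values, b$matrices$mRNA$values)
  expect_identical(a$matrices$miRNA$values, b$matrices$miRNA$values)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$truth, b$truth)
  expect_identical(a$annotation, b$annotation)
  c <- simulate_study(small_cfg(seed = 43))
  expect_false(identical(a$matrices$mRNA$values, c$matrices$mRNA$values))
})

test_that("configuration invariants are validated", {
  expect_error(sim_config(noise_sd = 0), class = "olfcerna_config_error")
  expect_error(sim_config(de_fraction = 1.2), class = "olfcerna_config_error")
  expect_error(sim_config(n_mrna = 0), class = "olfcerna_config_error")
  # too few DE slots for the requested planted triplets
  expect_error(sim_config(n_mirna = 10, de_fraction = 0.1,
                          n_cerna_triplets = 5),
               class = "olfcerna_config_error")
  expect_error(sim_config(utr_length = 6), class = "olfcerna_config_error")
})

test_that("de_fraction zero yields an empty truth set and no planted effects", {
  cfg <- sim_config(seed = 2, n_mrna = 100, n_lncrna = 50, n_circrna = 20,
                    n_mirna = 20, de_fraction = 0,
                    n_cerna_triplets = 0, n_coexpr_pairs = 0)
  e <- simulate_expression(cfg)
  expect_equal(nrow(e$truth$de), 0)
  expect_equal(nrow(e$truth$triplets), 0)
  de <- differential_expression(quantile_normalize(e$matrices$mRNA))
  # anything passing now is a false positive by construction; at fold
  # change > 2 with sd 0.25 there should be essentially none
  expect_lte(sum(de$passes_filter), 2)
})

test_that("planted group-mean differences are calibrated on the log2 scale", {
  # 200+ planted DE transcripts at fixed effect 2: the mean observed log2FC
  # across them must land within +-0.1 of 2
  cfg <- sim_config(seed = 10, n_mrna = 2000, n_lncrna = 10, n_circrna = 10,
                    n_mirna = 10, de_fraction = 0.15,
                    log2fc_mean = 2, log2fc_sd = 1e-9, log2fc_min = 0,
                    n_cerna_triplets = 0, n_coexpr_pairs = 0)
  e <- simulate_expression(cfg)
  de <- differential_expression(e$matrices$mRNA)
  planted <- e$truth$de[e$truth$de$class == "mRNA", ]
  expect_gte(nrow(planted), 200)
  obs <- de$log2fc[match(planted$transcript_id, de$transcript_id)]
  signed <- obs * sign(planted$planted_log2fc)
  expect_lt(abs(mean(signed) - 2), 0.1)
})

test_that("planted co-expression pairs approach |PCC| = 1 as noise vanishes", {
  cfg <- sim_config(seed = 3, n_mrna = 100, n_lncrna = 50, n_circrna = 20,
                    n_mirna = 20, n_cerna_triplets = 0, n_coexpr_pairs = 3,
                    noise_sd = 1e-7)
  e <- simulate_expression(cfg)
  pr <- e$truth$coexpr_pairs
  for (k in seq_len(nrow(pr))) {
    r <- cor(log2(e$matrices$lncRNA$values[pr$lncrna_id[k], ]),
             log2(e$matrices$mRNA$values[pr$mrna_id[k], ]))
    expect_lt(abs(abs(r) - 1), 1e-6)
    expect_equal(if (r > 0) "positive" else "negative", pr$sign[k])
  }
})

test_that("planted sites are realized verbatim and the background is scrubbed", {
  cfg <- small_cfg(seed = 8)
  e <- simulate_expression(cfg)
  seqs <- simulate_sequences(cfg, e$truth)
  targets <- c(seqs$mrna_utrs, seqs$circrnas)
  ps <- e$truth$planted_sites

  for (k in seq_len(nrow(ps))) {
    rec <- targets[[ps$target_id[k]]]
    pat <- site_patterns(seqs$mirnas[[ps$mirna_id[k]]])[[ps$site_type[k]]]
    L <- nchar(rec$seq)
    idx <- ((ps$start[k] + seq_len(nchar(pat)) - 1L) %% L) + 1L
    window <- paste(strsplit(rec$seq, "")[[1]][idx], collapse = "")
    expect_equal(window, pat)
    if (ps$spans_junction[k]) {
      expect_true(ps$start[k] + nchar(pat) > L)
      expect_identical(rec$topology, "circular")
    }
  }

  # exhaustive scrub check: the only scanner hits anywhere are the planted
  # sites themselves
  found <- scan_all_sites(seqs$mirnas, targets)
  expect_setequal(paste(found$mirna_id, found$target_id, found$site_type,
                        found$start),
                  paste(ps$mirna_id, ps$target_id, ps$site_type, ps$start))

  # a junction-planted site disappears when the same sequence is linear
  j <- which(ps$spans_junction)
  if (length(j)) {
    k <- j[1]
    rec <- targets[[ps$target_id[k]]]
    lin <- scan_sites(seqs$mirnas[[ps$mirna_id[k]]],
                      list(id = rec$id, seq = rec$seq, topology = "linear"))
    expect_false(any(lin$start == ps$start[k]))
  }
})

test_that("the worked 8mer example plants the complement of the seed", {
  # a miRNA with positions 2-8 = GAGGUAG planted as an 8mer at position 10
  # must write CUACCUCA at target[10..18)
  mir <- list(id = "m", seq = "UGAGGUAGUAGGUUGUAUAGUU")
  pat <- site_patterns(mir)[["8mer"]]
  expect_equal(pat, oracle_patterns(mir$seq)[["8mer"]])
  target <- paste0(strrep("G", 10), pat, strrep("G", 10))
  s <- scan_sites(mir, target)
  expect_equal(s$start, 10)
  expect_equal(substr(target, 11, 18), "CUACCUCA")
})

test_that("written study artifacts load back consistently", {
  dir <- withr::local_tempdir()
  study <- simulate_study(small_cfg(seed = 5))
  write_study(study, dir)
  gm <- study$matrices$mRNA$groups
  back <- read_expression_tsv(file.path(dir, "expr_mRNA.tsv"), gm, "mRNA")
  expect_identical(back$values, study$matrices$mRNA$values)
  mirs <- read_fasta(file.path(dir, "mirnas.fa"), "linear")
  expect_equal(vapply(mirs, `[[`, character(1), "seq"),
               vapply(study$sequences$mirnas, `[[`, character(1), "seq"))
  ann <- read_annotation_tsv(file.path(dir, "annotation.tsv"))
  expect_equal(nrow(ann), nrow(study$annotation$transcripts))
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_equal(length(sets), length(study$gene_sets))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sort(truth$de$transcript_id),
               sort(study$truth$de$transcript_id))
})
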