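test_that("pearson_with_p matches cor.test and the closed-form beta tail", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- pearson_with_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(got$pcc, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p_value, ct$p.value, tolerance = 1e-9)
    # independent closed form: 2P(T > t) = I_{1-r^2}((n-2)/2, 1/2)
    expect_equal(got$p_value, pbeta(1 - got$pcc^2, (n - 2) / 2, 0.5),
                 tolerance = 1e-9)
  }

  exact <- pearson_with_p(1:8, 2 * (1:8) + 1)
  expect_equal(exact$pcc, 1)
  expect_equal(exact$p_value, 0)
  expect_true(exact$exact_fit)
  anti <- pearson_with_p(1:8, -(1:8))
  expect_equal(anti$pcc, -1)

  expect_error(pearson_with_p(rep(1, 8), 1:8), class = "olfcerna_config_error")
  expect_error(pearson_with_p(1:2, 1:2), class = "olfcerna_config_error")
})

test_that("the correlation p at the retention threshold is ~8e-5 at n = 8", {
  p <- pcc_pvalue(0.968, 8)
  expect_lt(abs(p - 8e-5) / 8e-5, 0.05)
  expect_equal(p, pbeta(1 - 0.968^2, 3, 0.5), tolerance = 1e-9)
})

test_that("CNC edges respect the |PCC| and p thresholds with signs", {
  gm <- study_groups()
  set.seed(21)
  # controlled correlations against a fixed mRNA profile
  base <- as.numeric(scale(rnorm(8)))
  mk <- function(r) {
    z <- residuals(lm(rnorm(8) ~ base))
    z <- z / sd(z)
    as.numeric(r * base + sqrt(1 - r^2) * z)
  }
  m_mrna <- matrix(2^(10 + base), 1, 8,
                   dimnames = list("m1", names(gm)))
  lncs <- rbind(l_hi = 2^(10 + mk(0.99)),
                l_lo = 2^(10 + mk(0.95)),
                l_neg = 2^(10 + mk(-0.995)))
  colnames(lncs) <- names(gm)
  em_m <- expression_matrix(m_mrna, gm, "mRNA")
  em_l <- expression_matrix(lncs, gm, "lncRNA")
  edges <- build_cnc_network(em_m, em_l, "m1", rownames(lncs))
  expect_setequal(edges$node_b, c("l_hi", "l_neg"))  # 0.95 is below 0.968
  expect_equal(edges$sign[edges$node_b == "l_hi"], "positive")
  expect_equal(edges$sign[edges$node_b == "l_neg"], "negative")
  expect_true(all(abs(edges$pcc) >= 0.968 & edges$p_value < 0.05))

  # absent transcripts are skipped with a warning; empty input is valid
  expect_warning(build_cnc_network(em_m, em_l, c("m1", "ghost"), "l_hi"))
  empty <- build_cnc_network(em_m, em_l, "m1", character(0))
  expect_equal(nrow(empty), 0)
})

test_that("target edges need a site, strong negative correlation and opposite DE", {
  gm <- study_groups()
  g <- ifelse(gm == "case", 0.5, -0.5)
  set.seed(33)
  mir_v <- 10 - 2 * g + rnorm(8, 0, 0.02)        # down in case
  mrna_up <- 10 + 2 * g + rnorm(8, 0, 0.02)      # up in case
  mrna_co <- 10 - 2 * g + rnorm(8, 0, 0.02)      # down like the miRNA
  em_mir <- expression_matrix(
    matrix(round(2^mir_v), 1, 8, dimnames = list("mir1", names(gm))),
    gm, "miRNA")
  em_mrna <- expression_matrix(
    rbind(t_up = 2^mrna_up, t_co = 2^mrna_co,
          t_nosite = 2^mrna_up) |> `colnames<-`(names(gm)),
    gm, "mRNA")
  de_mir <- differential_expression(em_mir, counts = TRUE)
  de_mrna <- differential_expression(em_mrna)
  sites <- data.frame(mirna_id = "mir1",
                      target_id = c("t_up", "t_co"),
                      site_type = "8mer", start = 0L, length = 8L,
                      spans_junction = FALSE)
  edges <- build_mirna_target_network(em_mir, em_mrna, de_mir, de_mrna, sites)
  # t_up: site + anti-correlated + anti-directional -> retained
  # t_co: site but positively correlated and co-directional -> excluded
  # t_nosite: anti-correlated but no site -> excluded
  expect_equal(edges$node_b, "t_up")
  expect_equal(edges$sign, "negative")
  expect_true(all(edges$pcc < 0))
  expect_equal(edges$n_sites, 1)
})

test_that("ceRNA triplets satisfy every gate and recover the planted truth", {
  cfg <- sim_config(seed = 4, n_mrna = 600, n_lncrna = 200, n_circrna = 120,
                    n_mirna = 60, n_cerna_triplets = 4, n_coexpr_pairs = 3)
  study <- simulate_study(cfg)
  de <- list()
  for (cl in c("mRNA", "lncRNA", "circRNA", "miRNA")) {
    em <- study$matrices[[cl]]
    if (cl != "miRNA") em <- quantile_normalize(em)
    study$matrices[[cl]] <- em
    de[[cl]] <- differential_expression(em, counts = cl == "miRNA")
  }
  pf <- function(cl) de[[cl]]$transcript_id[de[[cl]]$passes_filter]
  ids <- function(x) vapply(x, `[[`, character(1), "id")
  mir_recs <- study$sequences$mirnas[ids(study$sequences$mirnas) %in% pf("miRNA")]
  utr_recs <- study$sequences$mrna_utrs[ids(study$sequences$mrna_utrs) %in% pf("mRNA")]
  circ_recs <- study$sequences$circrnas[ids(study$sequences$circrnas) %in% pf("circRNA")]
  trip <- build_cerna_network(study$matrices$circRNA, study$matrices$miRNA,
                              study$matrices$mRNA,
                              de$circRNA, de$miRNA, de$mRNA,
                              circ_recs, utr_recs, mir_recs)
  tt <- study$truth$triplets
  expect_setequal(paste(trip$circ_id, trip$mirna_id, trip$mrna_id),
                  paste(tt$circ_id, tt$mirna_id, tt$mrna_id))

  # re-assert the gates on every emitted triplet from first principles
  thr <- coexpr_config()
  for (k in seq_len(nrow(trip))) {
    expect_true(trip$r_circ_mir[k] < 0 &&
                  abs(trip$r_circ_mir[k]) >= thr$pcc_threshold)
    expect_true(trip$r_mir_mrna[k] < 0 &&
                  abs(trip$r_mir_mrna[k]) >= thr$pcc_threshold)
    expect_lt(trip$p_circ_mir[k], thr$p_threshold)
    expect_lt(trip$p_mir_mrna[k], thr$p_threshold)
    expect_true(trip$dir_circ[k] != trip$dir_mir[k])
    expect_true(trip$dir_mrna[k] != trip$dir_mir[k])
    ev <- shared_sites(study$sequences$mirnas[[trip$mirna_id[k]]],
                       study$sequences$circrnas[[trip$circ_id[k]]],
                       study$sequences$mrna_utrs[[trip$mrna_id[k]]])
    expect_true(ev$shared)
    expect_gt(nrow(ev$sites_a), 0)
    expect_gt(nrow(ev$sites_b), 0)
  }

  attrs <- cerna_node_attributes(trip, de$circRNA, de$miRNA, de$mRNA)
  expect_setequal(attrs$id,
                  unique(c(trip$circ_id, trip$mirna_id, trip$mrna_id)))
  expect_true(all(attrs$abs_log2fc > 1))
})

test_that("network summaries are deterministic with sorted degree tables", {
  tri <- data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "a"),
                    sign = c("positive", "negative", "positive"))
  s <- network_summary(tri)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_true(all(s$degree$degree == 2))
  expect_equal(unname(s$sign_counts["negative"]), 1)

  star <- data.frame(node_a = "hub", node_b = paste0("leaf", 1:10),
                     sign = "positive")
  expect_equal(network_summary(star)$degree$degree[1], 10)
  expect_equal(network_summary(star)$degree$id[1], "hub")

  empty <- network_summary(star[0, ])
  expect_equal(empty$n_nodes, 0)
  expect_equal(empty$n_edges, 0)
})

test_that("permuting miRNA sample labels collapses the target network", {
  cfg <- sim_config(seed = 14, n_mrna = 600, n_lncrna = 200, n_circrna = 120,
                    n_mirna = 60, n_cerna_triplets = 4, n_coexpr_pairs = 3)
  study <- simulate_study(cfg)
  em_mir <- study$matrices$miRNA
  em_mrna <- quantile_normalize(study$matrices$mRNA)
  de_mir <- differential_expression(em_mir, counts = TRUE)
  de_mrna <- differential_expression(em_mrna)
  pf_mir <- de_mir$transcript_id[de_mir$passes_filter]
  pf_mrna <- de_mrna$transcript_id[de_mrna$passes_filter]
  ids <- function(x) vapply(x, `[[`, character(1), "id")
  sites <- scan_all_sites(
    study$sequences$mirnas[ids(study$sequences$mirnas) %in% pf_mir],
    study$sequences$mrna_utrs[ids(study$sequences$mrna_utrs) %in% pf_mrna])
  before <- nrow(build_mirna_target_network(em_mir, em_mrna, de_mir, de_mrna,
                                            sites))
  expect_gte(before, cfg$n_cerna_triplets)

  set.seed(99)
  perm_total <- 0
  gm <- em_mir$groups
  for (b in 1:5) {
    perm <- em_mir
    # a permutation that preserves (or exactly swaps) the case/control
    # partition does not break the labels; reject those
    repeat {
      shuffle <- sample(ncol(perm$values))
      g2 <- unname(gm[shuffle])
      if (!identical(g2, unname(gm)) &&
          !identical(g2, ifelse(unname(gm) == "case", "control", "case"))) break
    }
    colnames_keep <- colnames(perm$values)
    perm$values <- perm$values[, shuffle, drop = FALSE]
    colnames(perm$values) <- colnames_keep
    perm_total <- perm_total +
      nrow(build_mirna_target_network(perm, em_mrna, de_mir, de_mrna, sites))
  }
  # chance-level retention under the |PCC| >= 0.968 tail is far below the
  # unpermuted count
  expect_lt(perm_total / 5, 0.05 * before + 1e-9)
})
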