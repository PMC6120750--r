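test_that("quantile normalization matches the order-statistic rule", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(m) <- c("a", "b", "c")
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out[, 2]), c(2.5, 3.5, 4.5))

  # rank positions preserved under permutation of one column
  m2 <- cbind(s1 = c(3, 1, 2), s2 = c(4, 5, 6))
  out2 <- quantile_normalize(m2)
  expect_equal(unname(out2[, 1]), c(4.5, 2.5, 3.5))

  # ties share the mean of the tied ranks' target values:
  # targets are rowMeans(sorted) = (2, 2.5, 3.5); ranks 1-2 tied -> 2.25
  mt <- cbind(s1 = c(1, 1, 2), s2 = c(3, 4, 5))
  outt <- quantile_normalize(mt)
  expect_equal(unname(outt[, 1]), c(2.25, 2.25, 3.5))
  expect_equal(unname(outt[, 2]), c(2, 2.5, 3.5))

  # identical distributions are a fixed point
  eq <- cbind(s1 = c(5, 1, 3), s2 = c(1, 3, 5))
  expect_equal(quantile_normalize(eq), eq)

  # grand sum preserved
  set.seed(3)
  r <- matrix(2^rnorm(600, 8), 100, 6)
  expect_equal(sum(quantile_normalize(r)), sum(r), tolerance = 1e-9)

  expect_error(quantile_normalize(matrix(1:3, 3, 1)),
               class = "olfcerna_config_error")
})

test_that("differential expression computes fold change, t test and the strict filter", {
  gm <- study_groups()
  # deterministic matrix: case mean 8, control mean 2 for t1 with slight
  # within-group spread; t2 is null; t3 sits exactly at fold change 2
  v <- rbind(
    t1 = c(7.9, 8.1, 7.9, 8.1, 1.9, 2.1, 1.9, 2.1),
    t2 = c(5, 5.1, 4.9, 5, 5, 5.1, 4.9, 5),
    t3 = c(4, 4, 4.0001, 3.9999, 2, 2, 2.0001, 1.9999))
  colnames(v) <- names(gm)
  em <- expression_matrix(v, gm, "mRNA")
  de <- differential_expression(em, de_config())
  r1 <- de[de$transcript_id == "t1", ]
  expect_equal(r1$mean_case, 8)
  expect_equal(r1$mean_control, 2)
  expect_equal(r1$fold_change, 4)
  expect_equal(r1$log2fc, 2)
  expect_equal(r1$direction, "up")
  expect_true(r1$passes_filter)
  expect_equal(r1$fold_change, 2^r1$log2fc, tolerance = 1e-9)

  r2 <- de[de$transcript_id == "t2", ]
  expect_false(r2$passes_filter)
  expect_equal(r2$direction, "unchanged")

  # fold change exactly 2 fails the strict "> 2" rule regardless of p
  r3 <- de[de$transcript_id == "t3", ]
  expect_equal(r3$fold_change, 2)
  expect_true(r3$p_value < 0.05)
  expect_false(r3$passes_filter)

  # group with < 2 samples is rejected
  em_small <- expression_matrix(v[, c(1, 5, 6, 7, 8)],
                                gm[c(1, 5, 6, 7, 8)], "mRNA")
  expect_error(differential_expression(em_small),
               class = "olfcerna_config_error")
})

test_that("degenerate zero-variance rows follow the stated conventions", {
  gm <- study_groups()
  v <- rbind(flat = rep(4, 8),
             split = c(rep(8, 4), rep(2, 4)))
  colnames(v) <- names(gm)
  de <- differential_expression(expression_matrix(v, gm, "mRNA"))
  expect_equal(de$p_value[de$transcript_id == "flat"], 1)
  expect_false(de$degenerate[de$transcript_id == "flat"])
  expect_equal(de$p_value[de$transcript_id == "split"], .Machine$double.xmin)
  expect_true(de$degenerate[de$transcript_id == "split"])
})

test_that("BH adjustment matches the step-up formula and is monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.01, 0.5)), c(0.02, 0.5))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(5:50, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("label swap negates log2FC and preserves p-values; scaling changes neither", {
  set.seed(9)
  gm <- study_groups()
  v <- matrix(2^rnorm(80, 8, 1), 10, 8,
              dimnames = list(paste0("t", 1:10), names(gm)))
  em <- expression_matrix(v, gm, "mRNA")
  de <- differential_expression(em)

  swapped <- ifelse(gm == "case", "control", "case")
  de_sw <- differential_expression(expression_matrix(v, swapped, "mRNA"))
  expect_equal(de_sw$log2fc, -de$log2fc)
  expect_equal(de_sw$p_value, de$p_value)

  de_sc <- differential_expression(expression_matrix(v * 37.5, gm, "mRNA"))
  expect_equal(de_sc$log2fc, de$log2fc, tolerance = 1e-12)
  expect_equal(de_sc$p_value, de$p_value, tolerance = 1e-12)
})

test_that("hierarchical ordering merges identical profiles first and matches a naive linkage", {
  x <- rbind(a = c(1, 2, 3, 4, 5, 6),
             b = c(2, 4, 6, 8, 10, 12),   # perfectly correlated with a
             c = c(6, 5, 4, 3, 2, 1),     # anti-correlated
             d = c(1, 3, 2, 5, 4, 6),
             e = c(6, 4, 5, 2, 3, 1))
  res <- hierarchical_order(x)
  expect_setequal(res$order, rownames(x))
  # a and b (distance 0) merge first
  expect_setequal(res$tree$labels[-res$tree$merge[1, ]], c("a", "b"))

  # merge sets and heights match the naive average-linkage oracle
  # (merges with tied heights may come out in either order; compare as
  # height-sorted (height, members) pairs)
  d <- 1 - cor(t(x[sort(rownames(x)), ]))
  diag(d) <- 0
  oracle <- oracle_average_linkage(d)
  expect_equal(sort(res$tree$height), sort(oracle$heights),
               tolerance = 1e-12)
  labels <- res$tree$labels
  hclust_sets <- lapply(seq_len(nrow(res$tree$merge)), function(i) {
    members <- function(node) {
      if (node < 0) return(labels[-node])
      unlist(lapply(res$tree$merge[node, ], members))
    }
    sort(members(i))
  })
  canon <- function(heights, sets) {
    key <- order(heights, vapply(sets, paste, character(1), collapse = ","))
    lapply(key, function(i) sets[[i]])
  }
  expect_equal(canon(res$tree$height, hclust_sets),
               canon(oracle$heights, oracle$sets))
  # each merged cluster is contiguous in the leaf order
  for (s in hclust_sets) {
    pos <- match(s, res$order)
    expect_equal(sort(pos), seq(min(pos), max(pos)))
  }

  # deterministic across repeated calls and input row permutations
  res2 <- hierarchical_order(x[c(3, 1, 5, 2, 4), ])
  expect_identical(res$order, res2$order)

  expect_warning(hierarchical_order(rbind(k = rep(1, 4), l = c(1, 2, 3, 4))),
                 "constant")
})

test_that("relative expression follows 2^-ddCt", {
  expect_equal(relative_expression_ddct(20, 20, 20, 20), 1)
  # ddCt = -2 -> 4-fold up
  expect_equal(relative_expression_ddct(18, 20, 20, 20), 4)
  # ddCt = 1 -> halved
  expect_equal(relative_expression_ddct(21, 20, 20, 20), 0.5)
  # ddCt = (25-24) - (22-20) = -1 -> doubled
  expect_equal(relative_expression_ddct(25, 24, 22, 20), 2)
})
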