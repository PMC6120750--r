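# let-7a: mature positions 2-8 are GAGGUAG, the classic worked seed.
LET7 <- "UGAGGUAGUAGGUUGUAUAGUU"

test_that("site patterns are the antiparallel complement of the seed region", {
  pats <- site_patterns(LET7)
  expect_equal(pats[["8mer"]], "CUACCUCA")
  expect_equal(pats[["7mer_m8"]], "CUACCUC")
  expect_equal(pats[["7mer_A1"]], "UACCUCA")
  expect_equal(pats[["6mer"]], "UACCUC")

  # independent complement-table oracle across random miRNAs
  set.seed(11)
  for (i in 1:25) {
    s <- rand_rna(22)
    expect_identical(as.list(site_patterns(s)), oracle_patterns(s))
  }

  # an 8 nt miRNA is the boundary case with all four patterns defined
  expect_length(site_patterns("ACGUACGU"), 4)
  expect_error(site_patterns("ACGUACG"), class = "olfcerna_format_error")
  expect_error(site_patterns("ACGNACGU"), class = "olfcerna_format_error")
})

test_that("overlapping calls collapse to the most specific site type", {
  s <- scan_sites(LET7, "AAACUACCUCAAAA")
  expect_equal(nrow(s), 1)
  expect_equal(s$site_type, "8mer")
  expect_equal(s$start, 3)
  expect_false(s$spans_junction)

  # no occurrences at all
  expect_equal(nrow(scan_sites(LET7, "GGGGGGGGGGGG")), 0)
  # target shorter than the shortest pattern: empty result, not an error
  expect_equal(nrow(scan_sites(LET7, "ACG")), 0)

  # raw hits exposed behind the collapse flag include the inner calls
  raw <- scan_sites(LET7, "AAACUACCUCAAAA", collapse = FALSE)
  expect_true(all(c("8mer", "7mer_m8", "7mer_A1", "6mer") %in% raw$site_type))
})

test_that("junction-spanning sites exist only under circular topology", {
  circ <- list(id = "c", seq = "CCUCAGGGGGGCUA", topology = "circular")
  s <- scan_sites(LET7, circ)
  expect_equal(nrow(s), 1)
  expect_equal(s$site_type, "8mer")
  expect_true(s$spans_junction)
  expect_equal(s$start, 11)

  lin <- scan_sites(LET7, "CCUCAGGGGGGCUA")
  expect_equal(nrow(lin), 0)
})

test_that("scanner equals brute-force window enumeration on random pairs", {
  set.seed(101)
  for (i in 1:60) {
    mir <- rand_rna(22)
    L <- sample(10:120, 1)
    tgt <- rand_rna(L)
    circular <- i %% 2 == 0
    got <- scan_sites(list(id = "m", seq = mir),
                      list(id = "t", seq = tgt,
                           topology = if (circular) "circular" else "linear"))
    want <- oracle_scan(mir, tgt, circular)
    expect_equal(got[, c("site_type", "start", "length", "spans_junction")],
                 want, info = paste("pair", i))
  }
})

test_that("rotating a circular target shifts starts and preserves site types", {
  set.seed(7)
  for (i in 1:10) {
    tgt <- rand_rna(40)
    mir <- rand_rna(22)
    base <- scan_sites(list(id = "m", seq = mir),
                       list(id = "t", seq = tgt, topology = "circular"))
    off <- sample(1:39, 1)
    rot <- paste0(substr(tgt, off + 1, 40), substr(tgt, 1, off))
    rotated <- scan_sites(list(id = "m", seq = mir),
                          list(id = "t", seq = rot, topology = "circular"))
    expect_equal(sort(table(rotated$site_type)), sort(table(base$site_type)))
    expect_setequal((base$start - off) %% 40, rotated$start)
  }
})

test_that("no reported weaker site lies inside a reported 8mer window", {
  # deterministic fixture: an 8mer and a separate lone 6mer coexist
  pats <- site_patterns(LET7)
  tgt0 <- paste0("GGG", pats[["8mer"]], "GGG", pats[["6mer"]], "GGG")
  s0 <- scan_sites(LET7, tgt0)
  expect_setequal(s0$site_type, c("8mer", "6mer"))
  expect_equal(s0$start[s0$site_type == "8mer"], 3)
  expect_equal(s0$start[s0$site_type == "6mer"], 14)

  set.seed(23)
  for (i in 1:40) {
    mir <- rand_rna(22)
    tgt <- paste0(rand_rna(40), site_patterns(mir)[["8mer"]], rand_rna(40))
    s <- scan_sites(list(id = "m", seq = mir), list(id = "t", seq = tgt))
    eights <- s[s$site_type == "8mer", ]
    weak <- s[s$site_type != "8mer", ]
    expect_gte(nrow(eights), 1)
    for (j in seq_len(nrow(weak))) {
      inside <- weak$start[j] >= eights$start &
        weak$start[j] + weak$length[j] <= eights$start + 8
      expect_false(any(inside))
    }
  }
})

test_that("vectorized multi-target scan equals pairwise scanning", {
  set.seed(5)
  mirs <- lapply(1:4, function(i) list(id = paste0("m", i), seq = rand_rna(22)))
  # embed known patterns so the comparison covers non-trivial hits,
  # including a junction-wrapped circular one
  p1 <- site_patterns(mirs[[1]]$seq)
  p2 <- site_patterns(mirs[[2]]$seq)
  tgts <- c(
    lapply(1:4, function(i) list(id = paste0("t", i), seq = rand_rna(80),
                                 topology = "linear")),
    list(list(id = "t5", seq = paste0(rand_rna(20), p1[["8mer"]],
                                      rand_rna(20), p2[["6mer"]],
                                      rand_rna(10)),
              topology = "linear"),
         list(id = "t6",
              seq = paste0(substr(p1[["7mer_m8"]], 4, 7), rand_rna(40),
                           substr(p1[["7mer_m8"]], 1, 3)),
              topology = "circular")),
    lapply(7:10, function(i) list(id = paste0("t", i), seq = rand_rna(50),
                                  topology = "circular")))
  all_fast <- scan_all_sites(mirs, tgts)
  expect_gte(nrow(all_fast), 3)
  expect_true(any(all_fast$spans_junction))
  all_slow <- do.call(rbind, Filter(function(x) nrow(x) > 0,
    unlist(lapply(mirs, function(m) lapply(tgts, function(t) scan_sites(m, t))),
           recursive = FALSE)))
  rownames(all_slow) <- NULL
  expect_equal(all_fast, all_slow)
})

test_that("shared-site evidence respects the minimum site type", {
  # construct targets carrying known sites for the let-7 seed
  a <- list(id = "a", seq = "GGGUACCUCGGG", topology = "linear")   # 6mer only
  b <- list(id = "b", seq = "GGGCUACCUCAGG", topology = "linear")  # 8mer
  m <- list(id = "m", seq = LET7)
  any_rule <- shared_sites(m, a, b, min_site_type = "any")
  expect_true(any_rule$shared)
  expect_equal(any_rule$sites_a$site_type, "6mer")
  expect_equal(any_rule$sites_b$site_type, "8mer")

  expect_false(shared_sites(m, a, b, min_site_type = "7mer")$shared)
  none <- list(id = "n", seq = "GGGGGGGGGGGG", topology = "linear")
  expect_false(shared_sites(m, none, b)$shared)
})
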