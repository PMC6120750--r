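# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the code paths under test: complements via a
# lookup table, site scanning via exhaustive window comparison, tail
# probabilities via explicit summation, linkage via a naive agglomerator.

options(olfcerna.quiet = TRUE)

oracle_complement <- c(A = "U", C = "G", G = "C", U = "A")

oracle_revcomp <- function(s) {
  ch <- strsplit(s, "")[[1]]
  paste(rev(unname(oracle_complement[ch])), collapse = "")
}

oracle_patterns <- function(mir_seq) {
  six <- oracle_revcomp(substr(mir_seq, 2, 7))
  m8 <- oracle_revcomp(substr(mir_seq, 2, 8))
  list(`8mer` = paste0(m8, "A"), `7mer_m8` = m8,
       `7mer_A1` = paste0(six, "A"), `6mer` = six)
}

# Exhaustive window enumeration with the same containment-collapse rule,
# implemented independently (per-position character walk, no regex).
oracle_scan <- function(mir_seq, target_seq, circular = FALSE) {
  pats <- oracle_patterns(mir_seq)
  L <- nchar(target_seq)
  tch <- strsplit(target_seq, "")[[1]]
  window_at <- function(start, len) {
    idx <- ((start + seq_len(len) - 1L) %% L) + 1L
    paste(tch[idx], collapse = "")
  }
  hits <- list()
  for (ty in names(pats)) {
    plen <- nchar(pats[[ty]])
    if (L < plen) next
    starts <- if (circular) 0:(L - 1L) else if (L >= plen) 0:(L - plen) else integer(0)
    for (s in starts) {
      if (!circular && s + plen > L) next
      if (window_at(s, plen) == pats[[ty]]) {
        hits[[length(hits) + 1L]] <- list(site_type = ty, start = s, length = plen)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(site_type = character(0), start = integer(0),
                      length = integer(0), spans_junction = logical(0)))
  }
  spec <- c(`6mer` = 1, `7mer_A1` = 2, `7mer_m8` = 3, `8mer` = 4)
  keep <- rep(TRUE, length(hits))
  for (i in seq_along(hits)) {
    for (j in seq_along(hits)) {
      if (spec[[hits[[j]]$site_type]] <= spec[[hits[[i]]$site_type]]) next
      off <- hits[[i]]$start - hits[[j]]$start
      if (circular) off <- off %% L
      if (off >= 0 && off + hits[[i]]$length <= hits[[j]]$length) {
        keep[i] <- FALSE
      }
    }
  }
  hits <- hits[keep]
  df <- data.frame(
    site_type = vapply(hits, `[[`, character(1), "site_type"),
    start = vapply(hits, `[[`, integer(1), "start"),
    length = vapply(hits, function(h) as.integer(h$length), integer(1)))
  df$spans_junction <- circular & (df$start + df$length > L)
  df <- df[order(df$start, -spec[df$site_type]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

oracle_hyper_upper_tail <- function(N, K, n, k) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive average-linkage agglomeration over a distance matrix. Returns the
# merge heights and the member set created at each merge.
oracle_average_linkage <- function(d) {
  ids <- rownames(d)
  clusters <- lapply(ids, identity)
  heights <- numeric(0)
  merged_sets <- list()
  cluster_dist <- function(a, b) {
    mean(d[a, b, drop = FALSE])
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- cluster_dist(clusters[[i]], clusters[[j]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    new <- c(clusters[[best[1]]], clusters[[best[2]]])
    heights <- c(heights, best_d)
    merged_sets[[length(merged_sets) + 1L]] <- sort(new)
    clusters <- c(clusters[-best], list(new))
  }
  list(heights = heights, sets = merged_sets)
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# small helper: expression matrix with exactly controlled pairwise sample
# correlation between two rows (used for threshold tests)
make_pair_matrix <- function(r, n = 8, ids = c("a", "b")) {
  x <- seq_len(n)
  x <- (x - mean(x)) / stats::sd(x)
  z <- stats::rnorm(n)
  z <- stats::residuals(stats::lm(z ~ x))
  z <- z / stats::sd(z)
  y <- r * x + sqrt(1 - r^2) * z
  m <- rbind(x, y)
  rownames(m) <- ids
  colnames(m) <- paste0("s", seq_len(n))
  m
}

study_groups <- function(n_case = 4, n_control = 4) {
  setNames(rep(c("case", "control"), c(n_case, n_control)),
           c(sprintf("OLF_%d", seq_len(n_case)),
             sprintf("NLF_%d", seq_len(n_control))))
}
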