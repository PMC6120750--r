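## Canonical miRNA seed-site taxonomy.
##
## Site patterns are written 5'->3' in TARGET orientation. With the seed
## defined as miRNA positions 2-7 (1-based, 5'->3') and m8 = position 8:
##   6mer     = revcomp(miR[2..7])
##   7mer-m8  = revcomp(miR[2..8])
##   7mer-A1  = 6mer followed by A   (the A faces miRNA position 1)
##   8mer     = 7mer-m8 followed by A
## The A1/8mer anchor is a literal adenosine on the target regardless of the
## miRNA's own position-1 base (canonical rule).

SITE_TYPES <- c("8mer", "7mer_m8", "7mer_A1", "6mer")

## Higher = more specific; used for precedence collapse and min-site filters.
SITE_SPECIFICITY <- c(`6mer` = 1L, `7mer_A1` = 2L, `7mer_m8` = 3L, `8mer` = 4L)

site_rank <- function(min_site_type) {
  if (min_site_type %in% c("any", "6mer")) return(1L)
  if (min_site_type == "7mer") return(2L)
  if (min_site_type %in% names(SITE_SPECIFICITY)) {
    return(unname(SITE_SPECIFICITY[min_site_type]))
  }
  stop_config("unknown min_site_type: ", min_site_type)
}

#' Target-strand site patterns for a mature miRNA
#'
#' @param mirna a sequence record (`list(id, seq, ...)`) or a plain RNA
#'   string; at least 8 nt.
#' @return named character vector with elements `8mer`, `7mer_m8`,
#'   `7mer_A1`, `6mer`, each written 5'->3' in target orientation.
#' @examples
#' site_patterns("UGAGGUAGUAGGUUGUAUAGUU")  # let-7a: 8mer = CUACCUCA
#' @export
site_patterns <- function(mirna) {
  seq <- if (is.list(mirna)) mirna$seq else mirna
  seq <- normalize_rna(seq)
  if (nchar(seq) < 8L) {
    stop_format("mature miRNA must be >= 8 nt for seed-site patterns (got ",
                nchar(seq), ")")
  }
  six <- reverse_complement_rna(substr(seq, 2L, 7L))
  m8 <- reverse_complement_rna(substr(seq, 2L, 8L))
  c(`8mer` = paste0(m8, "A"),
    `7mer_m8` = m8,
    `7mer_A1` = paste0(six, "A"),
    `6mer` = six)
}

## All start positions (0-based) of fixed pattern in text.
fixed_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Scan a target transcript for canonical miRNA seed sites
#'
#' Finds every occurrence of the four canonical site patterns of `mirna` on
#' `target`. Circular targets (circRNAs) are scanned across the backsplice
#' junction by extending the sequence with its own first
#' `max pattern length - 1` bases; positions are reported modulo the target
#' length and `spans_junction` flags wrap-around sites.
#'
#' By default overlapping calls at one locus are collapsed to the most
#' specific type (8mer > 7mer-m8 > 7mer-A1 > 6mer): a site is suppressed when
#' its window is contained in the window of a reported higher-precedence
#' site. `collapse = FALSE` returns the raw hits.
#'
#' @param mirna sequence record or RNA string of the mature miRNA (>= 8 nt).
#' @param target sequence record (`list(id, seq, topology)`); a plain string
#'   is treated as a linear target.
#' @param collapse collapse overlapping calls by precedence (default TRUE).
#' @return data.frame with columns `mirna_id`, `target_id`, `site_type`,
#'   `start` (0-based), `length`, `spans_junction`, ordered by start then
#'   decreasing specificity.
#' @export
scan_sites <- function(mirna, target, collapse = TRUE) {
  if (!is.list(mirna)) mirna <- list(id = "miRNA", seq = mirna)
  if (!is.list(target)) target <- list(id = "target", seq = target, topology = "linear")
  pats <- site_patterns(mirna)
  tseq <- normalize_rna(target$seq)
  L <- nchar(tseq)
  circular <- identical(target$topology, "circular")
  hits <- list()
  for (ty in SITE_TYPES) {
    pat <- pats[[ty]]
    plen <- nchar(pat)
    if (L < plen) next
    if (circular) {
      ext <- paste0(tseq, substr(tseq, 1L, plen - 1L))
      st <- fixed_matches(pat, ext)
      st <- st[st < L]
    } else {
      st <- fixed_matches(pat, tseq)
    }
    if (length(st)) {
      hits[[ty]] <- data.frame(site_type = ty, start = st, length = plen)
    }
  }
  if (!length(hits)) {
    return(empty_sites(mirna$id, target$id))
  }
  format_hits(do.call(rbind, hits), mirna$id %||% "miRNA",
              target$id %||% "target", L, circular, collapse)
}

## Precedence collapse + canonical ordering of a raw hit table
## (columns site_type, start, length) for one (miRNA, target) pair.
format_hits <- function(df, mirna_id, target_id, L, circular, collapse) {
  if (collapse && nrow(df) > 1L) {
    keep <- rep(TRUE, nrow(df))
    spec <- SITE_SPECIFICITY[df$site_type]
    for (i in seq_len(nrow(df))) {
      for (j in seq_len(nrow(df))) {
        if (spec[j] <= spec[i]) next
        # window containment, on the circle when the target is circular:
        # arc i is inside arc j iff its offset from j's start fits in j.
        off <- df$start[i] - df$start[j]
        if (circular) off <- off %% L
        if (off >= 0 && off + df$length[i] <= df$length[j]) {
          keep[i] <- FALSE
          break
        }
      }
    }
    df <- df[keep, , drop = FALSE]
  }
  df$mirna_id <- mirna_id
  df$target_id <- target_id
  df$spans_junction <- circular & (df$start + df$length > L)
  df <- df[order(df$start, -SITE_SPECIFICITY[df$site_type]), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("mirna_id", "target_id", "site_type", "start", "length", "spans_junction")]
}

empty_sites <- function(mirna_id = character(0), target_id = character(0)) {
  data.frame(mirna_id = character(0), target_id = character(0),
             site_type = character(0), start = integer(0),
             length = integer(0), spans_junction = logical(0))
}

#' Scan many miRNAs against many targets
#'
#' Equivalent to calling [scan_sites()] for every (miRNA, target) pair,
#' but each site pattern is searched across all target sequences in one
#' vectorized pass.
#'
#' @param mirnas list of miRNA sequence records.
#' @param targets list of target sequence records.
#' @param collapse see [scan_sites()].
#' @return one site data.frame over all pairs.
#' @export
scan_all_sites <- function(mirnas, targets, collapse = TRUE) {
  if (!length(mirnas) || !length(targets)) return(empty_sites())
  tids <- vapply(targets, function(t) t$id %||% "target", character(1))
  tseqs <- normalize_rna(vapply(targets, `[[`, character(1), "seq"), tids)
  circ <- vapply(targets, function(t) identical(t$topology, "circular"),
                 logical(1))
  Ls <- nchar(tseqs)
  texts <- ifelse(circ, paste0(tseqs, substr(tseqs, 1L, 7L)), tseqs)
  out <- list()
  for (m in mirnas) {
    pats <- site_patterns(m)
    mid <- m$id %||% "miRNA"
    raw <- vector("list", length(targets))
    for (ty in SITE_TYPES) {
      pat <- pats[[ty]]
      plen <- nchar(pat)
      g <- gregexpr(pat, texts, fixed = TRUE)
      for (k in seq_along(targets)) {
        st <- g[[k]]
        if (st[1] == -1L) next
        st <- as.integer(st) - 1L
        if (circ[k]) {
          # starts must lie on the unextended sequence, and a wrapped
          # window must not lap the circle more than once
          st <- if (Ls[k] < plen) integer(0) else st[st < Ls[k]]
        }
        if (length(st)) {
          raw[[k]] <- rbind(raw[[k]],
                            data.frame(site_type = ty, start = st,
                                       length = plen))
        }
      }
    }
    for (k in seq_along(targets)) {
      if (is.null(raw[[k]])) next
      out[[length(out) + 1L]] <- format_hits(raw[[k]], mid, tids[k],
                                             Ls[k], circ[k], collapse)
    }
  }
  if (!length(out)) return(empty_sites())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Shared-site test between two targets of one miRNA
#'
#' The ceRNA evidence rule: a miRNA links two transcripts when both carry at
#' least one canonical seed site of at least `min_site_type` specificity.
#'
#' @param mirna miRNA sequence record.
#' @param target_a,target_b target sequence records (topology respected).
#' @param min_site_type `"any"`/`"6mer"`, `"7mer"` (either 7mer type),
#'   `"7mer_A1"`, `"7mer_m8"` or `"8mer"`.
#' @return `list(shared, sites_a, sites_b)`; `shared` is TRUE iff both
#'   targets carry qualifying sites, and the site tables hold the evidence.
#' @export
shared_sites <- function(mirna, target_a, target_b, min_site_type = "any") {
  rank <- site_rank(min_site_type)
  sa <- scan_sites(mirna, target_a)
  sb <- scan_sites(mirna, target_b)
  sa <- sa[SITE_SPECIFICITY[sa$site_type] >= rank, , drop = FALSE]
  sb <- sb[SITE_SPECIFICITY[sb$site_type] >= rank, , drop = FALSE]
  list(shared = nrow(sa) > 0 && nrow(sb) > 0, sites_a = sa, sites_b = sb)
}
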