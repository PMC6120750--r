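#' Simulation configuration for the synthetic study
#'
#' Defines the two-group design the generator emulates: 4 ossified vs 4
#' normal samples, log-normal intensity noise on the log2 scale, planted
#' differential expression clearing the fold-change > 2 filter, planted
#' high-PCC coding/non-coding pairs, and planted ceRNA triplets whose three
#' members carry the sign structure the integration analysis assumes
#' (circRNA and mRNA co-directional, miRNA anti-directional) and share seed
#' sites for the same miRNA on both the circRNA and the mRNA.
#'
#' @param n_case,n_control samples per group (default 4 and 4).
#' @param n_mrna,n_lncrna,n_circrna,n_mirna transcripts per class. The
#'   defaults are a scaled-down but array-like platform; they are large
#'   enough that quantile normalization leaves individual expression
#'   profiles essentially undistorted, as on a real array.
#' @param de_fraction fraction of each class planted as differentially
#'   expressed (includes pair/triplet members).
#' @param log2fc_mean,log2fc_sd mean and sd of planted |log2 fold changes|.
#' @param log2fc_min truncation point of planted effects; the default 1.2
#'   keeps planted transcripts comfortably above the fold-change > 2 filter.
#' @param structured_log2fc_min truncation point for members of planted
#'   co-expression pairs and ceRNA triplets, whose recovery contract is
#'   exact; the default 1.8 makes missing the fold-change filter
#'   vanishingly unlikely at the default noise level.
#' @param noise_sd within-group standard deviation on the log2 scale.
#' @param baseline_log2_range uniform range of log2 baseline intensities.
#' @param mirna_baseline_log2_range uniform range of log2 baseline counts
#'   for miRNAs (counts are rounded after exponentiation).
#' @param n_coexpr_pairs planted high-|PCC| lncRNA-mRNA pairs.
#' @param n_cerna_triplets planted circRNA-miRNA-mRNA triplets; each uses a
#'   distinct miRNA so no unplanted triplet can share sites by construction.
#' @param latent_resid_frac fraction of `noise_sd` left independent for
#'   members of planted correlated pairs/triplets; the rest is a shared
#'   per-sample latent profile (this ratio tunes the planted |PCC|).
#' @param mirna_length mature miRNA length (nt).
#' @param utr_length,circ_length target sequence lengths (nt).
#' @param junction_site_fraction fraction of planted circRNA sites placed
#'   across the backsplice junction.
#' @param divergence_window TSS-to-TSS window (bp) for bidirectional
#'   lncRNAs in the simulated genome.
#' @param n_gmt_terms,gmt_term_size gene sets in the synthetic GMT (one of
#'   which is planted to be enriched in the upregulated mRNAs).
#' @param seed integer seed; every generator draw derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_case = 4, n_control = 4,
                       n_mrna = 2000, n_lncrna = 1500, n_circrna = 400,
                       n_mirna = 150,
                       de_fraction = 0.1,
                       log2fc_mean = 2, log2fc_sd = 0.5, log2fc_min = 1.2,
                       structured_log2fc_min = 1.8,
                       noise_sd = 0.25,
                       baseline_log2_range = c(6, 12),
                       mirna_baseline_log2_range = c(8, 13),
                       n_coexpr_pairs = 10, n_cerna_triplets = 5,
                       latent_resid_frac = 0.15,
                       mirna_length = 22, utr_length = 300, circ_length = 400,
                       junction_site_fraction = 0.3,
                       divergence_window = 1000,
                       n_gmt_terms = 15, gmt_term_size = 20,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c(cfg$n_case, cfg$n_control, cfg$n_mrna, cfg$n_lncrna,
              cfg$n_circrna, cfg$n_mirna)
  if (any(counts < 1)) stop_config("all sample/transcript counts must be >= 1")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) {
    stop_config("de_fraction must be in [0,1]")
  }
  if (cfg$noise_sd <= 0) stop_config("noise_sd must be > 0")
  if (cfg$latent_resid_frac <= 0 || cfg$latent_resid_frac >= 1) {
    stop_config("latent_resid_frac must be in (0,1)")
  }
  if (cfg$utr_length < 8 || cfg$circ_length < 8) {
    stop_config("target sequences must be >= 8 nt to carry a seed site")
  }
  if (cfg$mirna_length < 8) stop_config("mirna_length must be >= 8")
  if (cfg$n_lncrna > cfg$n_mrna) {
    stop_config("the toy genome hosts each lncRNA in its own coding-gene ",
                "block; n_lncrna must be <= n_mrna")
  }
  n_de <- function(n) floor(cfg$de_fraction * n)
  if (cfg$n_cerna_triplets > 0 &&
      (n_de(cfg$n_circrna) < cfg$n_cerna_triplets ||
       n_de(cfg$n_mirna) < cfg$n_cerna_triplets ||
       n_de(cfg$n_mrna) < cfg$n_cerna_triplets + cfg$n_coexpr_pairs)) {
    stop_config("de_fraction x class counts leave too few DE slots for the ",
                "requested planted triplets/pairs")
  }
  if (cfg$n_coexpr_pairs > 0 && n_de(cfg$n_lncrna) < cfg$n_coexpr_pairs) {
    stop_config("de_fraction x n_lncrna leaves too few DE lncRNAs for the ",
                "requested planted co-expression pairs")
  }
  structure(cfg, class = "sim_config")
}

sim_ids <- function(class, n) {
  prefix <- c(mRNA = "mRNA", lncRNA = "lncRNA", circRNA = "circRNA",
              miRNA = "miR")[[class]]
  sprintf("%s_%04d", prefix, seq_len(n))
}

derive_seed <- function(seed, k) (as.integer(seed) %% 1000000000L) + k

## |log2FC| ~ N(mean, sd) truncated below at minv (rejection sampling).
draw_log2fc <- function(n, cfg, minv = cfg$log2fc_min) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, cfg$log2fc_mean, cfg$log2fc_sd)
    out <- c(out, x[x >= minv])
  }
  out[seq_len(n)]
}

#' Simulate expression matrices with planted truth
#'
#' Draws one expression matrix per transcript class under the configured
#' two-group design. Null transcripts have equal group means; planted DE
#' transcripts have a group-mean log2 difference equal to their planted
#' effect. Members of planted co-expression pairs and ceRNA triplets share
#' a per-sample latent profile (loaded with the sign of their regulation
#' direction) so their pooled-sample |PCC| exceeds the network retention
#' threshold in expectation. miRNA matrices are integer counts; the other
#' classes are linear intensities.
#'
#' The returned truth set also fixes the planted seed-site placements
#' (site type, position, junction flag) that [simulate_sequences()]
#' realizes.
#'
#' @param config a [sim_config()].
#' @return `list(matrices, truth)`: named list of [expression_matrix()]
#'   objects (mRNA, lncRNA, circRNA, miRNA) and the truth set
#'   (`de`, `coexpr_pairs`, `planted_sites`, `triplets`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_rng(derive_seed(cfg$seed, 1L), {
    samples <- c(sprintf("OLF_%d", seq_len(cfg$n_case)),
                 sprintf("NLF_%d", seq_len(cfg$n_control)))
    groups <- setNames(rep(c("case", "control"), c(cfg$n_case, cfg$n_control)),
                       samples)
    gs <- ifelse(groups == "case", 0.5, -0.5)  # group half-effect coding
    n_s <- length(samples)

    ids <- list(mRNA = sim_ids("mRNA", cfg$n_mrna),
                lncRNA = sim_ids("lncRNA", cfg$n_lncrna),
                circRNA = sim_ids("circRNA", cfg$n_circrna),
                miRNA = sim_ids("miRNA", cfg$n_mirna))
    n_de <- vapply(names(ids), function(cl) {
      as.integer(floor(cfg$de_fraction * length(ids[[cl]])))
    }, integer(1))

    ## ---- planted structure bookkeeping -------------------------------
    ## direction: +1 up in case, -1 down. Triplets alternate the two sign
    ## patterns (circ/mRNA up with miR down, and the mirror).
    dir_of <- lapply(ids, function(x) setNames(integer(length(x)), x))
    fc_of <- lapply(ids, function(x) setNames(numeric(length(x)), x))
    latent_of <- lapply(ids, function(x) setNames(integer(length(x)), x))

    nt <- cfg$n_cerna_triplets
    np <- cfg$n_coexpr_pairs
    triplets <- data.frame(circ_id = character(0), mirna_id = character(0),
                           mrna_id = character(0))
    if (nt > 0) {
      triplets <- data.frame(circ_id = ids$circRNA[seq_len(nt)],
                             mirna_id = ids$miRNA[seq_len(nt)],
                             mrna_id = ids$mRNA[seq_len(nt)])
      pat <- ifelse(seq_len(nt) %% 2L == 1L, 1L, -1L)
      for (k in seq_len(nt)) {
        dir_of$circRNA[triplets$circ_id[k]] <- pat[k]
        dir_of$mRNA[triplets$mrna_id[k]] <- pat[k]
        dir_of$miRNA[triplets$mirna_id[k]] <- -pat[k]
        latent_of$circRNA[triplets$circ_id[k]] <- k
        latent_of$mRNA[triplets$mrna_id[k]] <- k
        latent_of$miRNA[triplets$mirna_id[k]] <- k
      }
    }
    coexpr <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                         sign = character(0))
    if (np > 0) {
      lnc_members <- ids$lncRNA[seq_len(np)]
      mrna_members <- ids$mRNA[nt + seq_len(np)]
      pair_sign <- ifelse(stats::runif(np) < 0.5, 1L, -1L)
      lnc_dir <- ifelse(stats::runif(np) < 0.5, 1L, -1L)
      coexpr <- data.frame(lncrna_id = lnc_members, mrna_id = mrna_members,
                           sign = ifelse(pair_sign > 0, "positive", "negative"))
      for (k in seq_len(np)) {
        dir_of$lncRNA[lnc_members[k]] <- lnc_dir[k]
        dir_of$mRNA[mrna_members[k]] <- pair_sign[k] * lnc_dir[k]
        latent_of$lncRNA[lnc_members[k]] <- nt + k
        latent_of$mRNA[mrna_members[k]] <- nt + k
      }
    }
    ## fill the remaining DE quota per class with independent transcripts
    for (cl in names(ids)) {
      planted <- sum(dir_of[[cl]] != 0L)
      extra <- n_de[[cl]] - planted
      if (extra > 0) {
        pool <- names(dir_of[[cl]])[dir_of[[cl]] == 0L]
        chosen <- sample(pool, extra)
        dir_of[[cl]][chosen] <- ifelse(stats::runif(extra) < 0.5, 1L, -1L)
      }
    }
    for (cl in names(ids)) {
      de_ids <- names(dir_of[[cl]])[dir_of[[cl]] != 0L]
      structured <- de_ids[latent_of[[cl]][de_ids] > 0L]
      plain <- setdiff(de_ids, structured)
      fc_of[[cl]][plain] <- draw_log2fc(length(plain), cfg)
      # members of planted correlation structures must survive the
      # fold-change filter essentially always (their recovery contract is
      # exact), so their effects are truncated at a higher floor
      fc_of[[cl]][structured] <- draw_log2fc(
        length(structured), cfg,
        minv = max(cfg$log2fc_min, cfg$structured_log2fc_min))
    }

    ## ---- draw the matrices -------------------------------------------
    n_latent <- nt + np
    latent <- if (n_latent > 0) {
      matrix(stats::rnorm(n_latent * n_s, 0,
                          cfg$noise_sd * sqrt(1 - cfg$latent_resid_frac^2)),
             n_latent, n_s)
    } else {
      matrix(0, 0, n_s)
    }
    eta <- cfg$noise_sd * cfg$latent_resid_frac

    draw_class <- function(cl) {
      tid <- ids[[cl]]
      rng <- if (cl == "miRNA") cfg$mirna_baseline_log2_range else cfg$baseline_log2_range
      baseline <- stats::runif(length(tid), rng[1], rng[2])
      dirs <- dir_of[[cl]][tid]
      fcs <- fc_of[[cl]][tid]
      lat <- latent_of[[cl]][tid]
      y <- matrix(NA_real_, length(tid), n_s, dimnames = list(tid, samples))
      for (i in seq_along(tid)) {
        mu <- baseline[i] + dirs[i] * fcs[i] * gs
        if (lat[i] > 0L) {
          y[i, ] <- mu + dirs[i] * latent[lat[i], ] + stats::rnorm(n_s, 0, eta)
        } else {
          y[i, ] <- mu + stats::rnorm(n_s, 0, cfg$noise_sd)
        }
      }
      v <- 2^y
      if (cl == "miRNA") v <- round(v)
      expression_matrix(v, groups, cl)
    }
    matrices <- lapply(setNames(names(ids), names(ids)), draw_class)

    ## ---- planted seed-site placements --------------------------------
    site_pool <- c("8mer", "7mer_m8", "7mer_A1", "6mer")
    site_prob <- c(0.4, 0.3, 0.2, 0.1)
    site_len <- c(`8mer` = 8L, `7mer_m8` = 7L, `7mer_A1` = 7L, `6mer` = 6L)
    planted_sites <- data.frame(mirna_id = character(0), target_id = character(0),
                                target_class = character(0),
                                site_type = character(0), start = integer(0),
                                spans_junction = logical(0))
    if (nt > 0) {
      rows <- list()
      for (k in seq_len(nt)) {
        ty_c <- sample(site_pool, 1, prob = site_prob)
        len_c <- site_len[[ty_c]]
        junction <- stats::runif(1) < cfg$junction_site_fraction
        start_c <- if (junction) {
          cfg$circ_length - sample.int(len_c - 1L, 1)
        } else {
          sample.int(cfg$circ_length - len_c + 1L, 1) - 1L
        }
        ty_m <- sample(site_pool, 1, prob = site_prob)
        len_m <- site_len[[ty_m]]
        start_m <- sample.int(cfg$utr_length - len_m + 1L, 1) - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = triplets$mirna_id[k],
          target_id = c(triplets$circ_id[k], triplets$mrna_id[k]),
          target_class = c("circRNA", "mRNA"),
          site_type = c(ty_c, ty_m), start = c(start_c, start_m),
          spans_junction = c(junction, FALSE))
      }
      planted_sites <- do.call(rbind, rows)
      rownames(planted_sites) <- NULL
    }

    de_rows <- list()
    for (cl in names(ids)) {
      de_ids <- names(dir_of[[cl]])[dir_of[[cl]] != 0L]
      if (length(de_ids)) {
        de_rows[[cl]] <- data.frame(
          transcript_id = de_ids, class = cl,
          direction = ifelse(dir_of[[cl]][de_ids] > 0, "up", "down"),
          planted_log2fc = dir_of[[cl]][de_ids] * fc_of[[cl]][de_ids])
      }
    }
    de <- if (length(de_rows)) {
      out <- do.call(rbind, de_rows)
      rownames(out) <- NULL
      out
    } else {
      data.frame(transcript_id = character(0), class = character(0),
                 direction = character(0), planted_log2fc = numeric(0))
    }
    truth <- list(de = de, coexpr_pairs = coexpr,
                  planted_sites = planted_sites, triplets = triplets)
    list(matrices = matrices, truth = truth)
  })
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

## Positions (0-based, modulo L for circular) covered by a window.
window_positions <- function(start, len, L, circular) {
  pos <- start + seq_len(len) - 1L
  if (circular) pos %% L else pos
}

#' Realize planted seed sites in synthetic sequences
#'
#' Generates mature miRNA sequences for every simulated miRNA and target
#' sequences (linear 3'UTRs for DE mRNAs, circular sequences for DE
#' circRNAs), writes each planted site in as the exact target-strand
#' pattern at its planted position (junction-spanning sites wrap across the
#' circular boundary), and then scrubs the background: any remaining site
#' of any simulated miRNA on any generated target is destroyed by rewriting
#' one background base inside the offending window, iterating until no
#' unplanned site survives (bounded retries, then error). miRNA sequences
#' are drawn so that no miRNA's site pattern is a substring of another
#' miRNA's 8mer site pattern, which guarantees the scrub can always avoid
#' planted windows.
#'
#' @param config a [sim_config()].
#' @param truth truth set from [simulate_expression()].
#' @return `list(mirnas, mrna_utrs, circrnas)` of sequence-record lists.
#' @export
simulate_sequences <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  site_len <- c(`8mer` = 8L, `7mer_m8` = 7L, `7mer_A1` = 7L, `6mer` = 6L)
  bad_pos <- truth$planted_sites$start +
    site_len[truth$planted_sites$site_type]
  if (any(truth$planted_sites$target_class == "mRNA" &
          bad_pos > cfg$utr_length)) {
    stop_config("utr_length too short for a planted site position")
  }
  with_rng(derive_seed(cfg$seed, 2L), {
    ## mature miRNAs with mutually compatible site patterns
    ## Mutual compatibility: no miRNA's site pattern may sit inside another
    ## miRNA's 8mer site pattern (in either direction of seniority), or a
    ## planted site of one could harbour an unremovable site of the other.
    ## Every pattern is a substring of its own 8mer, so checking all stored
    ## patterns against the new 8mer and all new patterns against the
    ## stored 8mers covers every pattern-in-pattern containment.
    mir_ids <- sim_ids("miRNA", cfg$n_mirna)
    mir_seqs <- character(0)
    eightmers <- character(0)
    all_patterns <- character(0)
    for (id in mir_ids) {
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        s <- random_rna(cfg$mirna_length)
        pats <- site_patterns(s)
        clash <-
          any(vapply(all_patterns, grepl, logical(1), x = pats[["8mer"]],
                     fixed = TRUE)) ||
          any(vapply(pats, function(p) {
            any(grepl(p, eightmers, fixed = TRUE))
          }, logical(1)))
        if (!clash) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop_config("could not draw a compatible miRNA sequence for ", id)
      mir_seqs[id] <- s
      eightmers <- c(eightmers, pats[["8mer"]])
      all_patterns <- c(all_patterns, unname(pats))
    }
    mirnas <- lapply(mir_ids, function(id) {
      list(id = id, seq = mir_seqs[[id]], topology = "linear")
    })
    names(mirnas) <- mir_ids

    ## targets: DE mRNAs (linear UTRs) and DE circRNAs (circular)
    de <- truth$de
    mrna_ids <- de$transcript_id[de$class == "mRNA"]
    circ_ids <- de$transcript_id[de$class == "circRNA"]
    targets <- list()
    for (id in mrna_ids) {
      targets[[id]] <- list(id = id, seq = random_rna(cfg$utr_length),
                            topology = "linear")
    }
    for (id in circ_ids) {
      targets[[id]] <- list(id = id, seq = random_rna(cfg$circ_length),
                            topology = "circular")
    }

    ## realize planted sites
    ps <- truth$planted_sites
    planted_windows <- lapply(setNames(names(targets), names(targets)),
                              function(id) integer(0))
    if (nrow(ps)) {
      for (k in seq_len(nrow(ps))) {
        tid <- ps$target_id[k]
        if (is.null(targets[[tid]])) next
        pat <- site_patterns(mir_seqs[[ps$mirna_id[k]]])[[ps$site_type[k]]]
        rec <- targets[[tid]]
        L <- nchar(rec$seq)
        circular <- identical(rec$topology, "circular")
        pos <- window_positions(ps$start[k], nchar(pat), L, circular)
        chars <- strsplit(rec$seq, "")[[1]]
        chars[pos + 1L] <- strsplit(pat, "")[[1]]
        targets[[tid]]$seq <- paste(chars, collapse = "")
        planted_windows[[tid]] <- union(planted_windows[[tid]], pos)
      }
    }

    ## scrub: destroy every unplanned site of every miRNA on every target.
    ## Uses a light-weight raw hit finder (no data.frame construction) for
    ## speed; the public scanner is exercised by the recovery tests.
    planted_key <- if (nrow(ps)) {
      paste(ps$mirna_id, ps$target_id, ps$site_type, ps$start)
    } else {
      character(0)
    }
    mir_pats <- lapply(mir_seqs, function(s) site_patterns(s)[SITE_TYPES])
    tids_v <- names(targets)
    circ_v <- vapply(targets, function(t) identical(t$topology, "circular"),
                     logical(1))
    Ls <- vapply(targets, function(t) nchar(t$seq), integer(1))
    for (round in seq_len(100L)) {
      dirty <- FALSE
      rewritten <- character(0)
      seqs_v <- vapply(targets, `[[`, character(1), "seq")
      texts <- ifelse(circ_v, paste0(seqs_v, substr(seqs_v, 1L, 7L)), seqs_v)
      for (mid in mir_ids) {
        for (i in seq_along(SITE_TYPES)) {
          ty <- SITE_TYPES[i]
          pat <- mir_pats[[mid]][[i]]
          plen <- nchar(pat)
          g <- gregexpr(pat, texts, fixed = TRUE)
          for (k in seq_along(tids_v)) {
            st <- g[[k]]
            if (st[1] == -1L) next
            st <- as.integer(st) - 1L
            if (circ_v[k]) {
              if (Ls[k] < plen) next
              st <- st[st < Ls[k]]
            }
            tid <- tids_v[k]
            L <- Ls[k]
            circular <- circ_v[k]
            for (s0 in st) {
              key <- paste(mid, tid, ty, s0)
              if (key %in% planted_key) next
              # an earlier rewrite this round may already have destroyed it
              cur <- targets[[tid]]$seq
              curtext <- if (circular) paste0(cur, substr(cur, 1L, 7L)) else cur
              if (substr(curtext, s0 + 1L, s0 + plen) != pat) next
              pos <- window_positions(s0, plen, L, circular)
              free <- setdiff(pos, planted_windows[[tid]])
              if (!length(free)) {
                # raw sub-sites of a planted site of the same miRNA are
                # legitimate (collapsed in reported scans); skip them.
                planted_here <- ps[ps$target_id == tid &
                                     ps$mirna_id == mid, , drop = FALSE]
                inside_own <- FALSE
                if (nrow(planted_here)) {
                  for (q in seq_len(nrow(planted_here))) {
                    own <- window_positions(planted_here$start[q],
                                            site_len[planted_here$site_type[q]],
                                            L, circular)
                    if (all(pos %in% own)) inside_own <- TRUE
                  }
                }
                if (inside_own) next
                stop_config("unscrubbable site collision on ", tid, ": ", ty,
                            " of ", mid, " at ", s0)
              }
              # random choice over the free positions: always rewriting the
              # same boundary base can cycle when each nucleotide there
              # enables some miRNA's pattern
              p <- free[sample.int(length(free), 1)]
              chars <- strsplit(targets[[tid]]$seq, "")[[1]]
              chars[p + 1L] <- sample(setdiff(c("A", "C", "G", "U"),
                                             chars[p + 1L]), 1)
              targets[[tid]]$seq <- paste(chars, collapse = "")
              dirty <- TRUE
                rewritten <- c(rewritten, paste0(key, " (pos ", p, ")"))
            }
          }
        }
      }
      if (!dirty) break
      if (round == 100L) {
        stop_config("background scrub did not converge; persistent site(s): ",
                    paste(utils::head(rewritten, 5), collapse = "; "))
      }
    }
    list(mirnas = mirnas,
         mrna_utrs = targets[names(targets) %in% mrna_ids],
         circrnas = targets[names(targets) %in% circ_ids])
  })
}
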