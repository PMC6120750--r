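PIPELINE_STEPS <- c("simulate", "de", "classify", "cnc", "targets",
                    "cerna", "enrich")

#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema accepted by [validate_config()]:
#' a `sim` block (see [sim_config()]), a `de` block (fold change > 2,
#' p < 0.05), a `coexpr` block (|PCC| >= 0.968, p < 0.05), the steps to
#' run, the seed and the output directory.
#'
#' @param out_dir output directory for run artifacts.
#' @param seed integer seed.
#' @return nested configuration list.
#' @export
default_config <- function(out_dir = "results/run", seed = 1) {
  list(
    seed = seed,
    out_dir = out_dir,
    steps = PIPELINE_STEPS,
    sim = list(),
    de = list(fc_threshold = 2, p_threshold = 0.05),
    coexpr = list(pcc_threshold = 0.968, p_threshold = 0.05,
                  min_site_type = "any"),
    divergence_window = 1000
  )
}

## Recursively merge user values over defaults, rejecting unknown keys.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop_config("config key ", path, " must be a mapping")
  valid <- if (identical(path, "sim")) {
    names(formals(sim_config))
  } else {
    names(defaults)
  }
  for (key in names(user)) {
    here <- paste0(path, if (nzchar(path)) "." else "", key)
    if (!key %in% valid) {
      stop_config("unknown config key: ", here)
    }
    if (is.list(defaults[[key]]) && !key %in% c("steps")) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], here)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list; injects defaults (fold
#' change 2, p 0.05, |PCC| 0.968 — the study's printed thresholds),
#' rejects unknown keys and range-checks every threshold.
#'
#' @param config YAML path or nested list (possibly partial).
#' @return normalized configuration list with concrete `sim_cfg`,
#'   `de_cfg` and `coexpr_cfg` objects attached.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  cfg <- merge_config(default_config(), config)
  unknown_steps <- setdiff(cfg$steps, PIPELINE_STEPS)
  if (length(unknown_steps)) {
    stop_config("unknown step(s): ", paste(unknown_steps, collapse = ", "))
  }
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  sim_args$divergence_window <- sim_args$divergence_window %||%
    cfg$divergence_window
  cfg$sim_cfg <- do.call(sim_config, sim_args)
  cfg$de_cfg <- do.call(de_config, cfg$de)
  cfg$coexpr_cfg <- do.call(coexpr_config, cfg$coexpr)
  cfg
}

log_line <- function(con, ...) {
  msg <- paste0(...)
  writeLines(msg, con)
  if (!isTRUE(getOption("olfcerna.quiet", FALSE))) message(msg)
}

#' Run the integration pipeline
#'
#' Executes the requested steps in dependency order — simulate the study,
#' quantile-normalize the array classes and compute per-class differential
#' expression, classify lncRNAs and tabulate their lengths and chromosome
#' enrichment, then build the CNC co-expression network, the
#' negatively-correlated miRNA target network, the ceRNA triplet network
#' and the gene-set enrichment of the upregulated mRNAs — writing every
#' artifact atomically under `config$out_dir` and returning a run summary.
#' Identical configuration and seed produce byte-identical outputs; wall
#' time is logged to `run.log` only.
#'
#' Steps read their inputs from memory when an earlier step of the same
#' run produced them, otherwise from the files a previous run left in
#' `out_dir`; a missing prerequisite raises a dependency error naming the
#' step that should have produced it.
#'
#' @param config a [validate_config()] result, a partial list, or a YAML
#'   path.
#' @return the run summary (also written to `summary.json`), invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (is.list(config) && !is.null(config$sim_cfg)) config else validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$out_dir, ...)
  log_con <- file(p("run.log"), open = "at")
  on.exit(close(log_con))
  t0 <- Sys.time()
  log_line(log_con, "pipeline start; steps: ", paste(cfg$steps, collapse = ","),
           "; seed: ", cfg$seed)

  state <- new.env(parent = emptyenv())
  need <- function(what, producer, loader) {
    if (!is.null(state[[what]])) return(state[[what]])
    v <- tryCatch(loader(), error = function(e) NULL)
    if (is.null(v)) {
      stop_dependency("step needs '", what, "' but the '", producer,
                      "' step has not produced it; run '", producer, "' first")
    }
    state[[what]] <- v
    v
  }
  load_study <- function() {
    if (!file.exists(p("expr_mRNA.tsv"))) return(NULL)
    groups_df <- utils::read.delim(p("groups.tsv"))
    groups <- setNames(groups_df$group, groups_df$sample_id)
    mats <- lapply(setNames(TRANSCRIPT_CLASSES, TRANSCRIPT_CLASSES),
                   function(cl) {
                     read_expression_tsv(p(sprintf("expr_%s.tsv", cl)),
                                         groups, cl)
                   })
    list(matrices = mats,
         sequences = list(
           mirnas = read_fasta(p("mirnas.fa"), "linear"),
           mrna_utrs = read_fasta(p("mrna_utrs.fa"), "linear"),
           circrnas = read_fasta(p("circrnas.fa"), "circular")),
         annotation = list(
           transcripts = read_annotation_tsv(p("annotation.tsv")),
           coding_exons = utils::read.delim(p("coding_exons.tsv")),
           genes_per_chrom = with(utils::read.delim(p("genes_per_chrom.tsv")),
                                  setNames(n_genes, chrom))),
         gene_sets = read_gmt(p("gene_sets.gmt")))
  }
  load_de <- function() {
    if (!file.exists(p("de_mRNA.tsv"))) return(NULL)
    lapply(setNames(TRANSCRIPT_CLASSES, TRANSCRIPT_CLASSES), function(cl) {
      df <- utils::read.delim(p(sprintf("de_%s.tsv", cl)))
      df$passes_filter <- as.logical(df$passes_filter)
      df
    })
  }

  summary <- list(package = "olfcerna",
                  version = as.character(utils::packageVersion("olfcerna")),
                  seed = cfg$seed,
                  steps = cfg$steps,
                  thresholds = list(fc = cfg$de_cfg$fc_threshold,
                                    p = cfg$de_cfg$p_threshold,
                                    pcc = cfg$coexpr_cfg$pcc_threshold),
                  skipped = setdiff(PIPELINE_STEPS, cfg$steps))

  if ("simulate" %in% cfg$steps) {
    log_line(log_con, "simulate: generating synthetic study")
    study <- simulate_study(cfg$sim_cfg)
    write_study(study, cfg$out_dir)
    state$study <- study[c("matrices", "sequences", "annotation", "gene_sets")]
    state$truth <- study$truth
  }

  if ("de" %in% cfg$steps) {
    study <- need("study", "simulate", load_study)
    de <- list()
    norm <- list()
    for (cl in TRANSCRIPT_CLASSES) {
      em <- study$matrices[[cl]]
      is_counts <- cl == "miRNA"
      if (!is_counts) em <- quantile_normalize(em)
      norm[[cl]] <- em
      de[[cl]] <- differential_expression(em, cfg$de_cfg, counts = is_counts)
      write_de_tsv(de[[cl]], p(sprintf("de_%s.tsv", cl)))
    }
    state$de <- de
    state$normalized <- norm
    summary$de_counts <- lapply(de, function(d) {
      list(up = sum(d$passes_filter & d$direction == "up"),
           down = sum(d$passes_filter & d$direction == "down"))
    })
    log_line(log_con, "de: ",
             paste(vapply(TRANSCRIPT_CLASSES, function(cl) {
               sprintf("%s %d up/%d down", cl, summary$de_counts[[cl]]$up,
                       summary$de_counts[[cl]]$down)
             }, character(1)), collapse = "; "))
  }

  passing <- function(cl) {
    d <- state$de[[cl]]
    d$transcript_id[d$passes_filter]
  }
  get_norm <- function(cl) {
    if (!is.null(state$normalized)) return(state$normalized[[cl]])
    study <- need("study", "simulate", load_study)
    if (cl == "miRNA") study$matrices[[cl]] else quantile_normalize(study$matrices[[cl]])
  }

  if ("classify" %in% cfg$steps) {
    study <- need("study", "simulate", load_study)
    ann <- study$annotation
    lnc <- ann$transcripts[ann$transcripts$class == "lncRNA", , drop = FALSE]
    classes <- classify_lncrna(lnc, ann$coding_exons,
                               divergence_window = cfg$divergence_window)
    write_table_tsv(classes, p("lncrna_classes.tsv"))
    pct <- table(factor(classes$category, levels = LNC_CATEGORIES))
    summary$lncrna_category_percent <- as.list(
      round(100 * as.numeric(pct) / sum(pct), 2) |> setNames(names(pct)))
    hist <- length_histogram(lnc$length)
    write_table_tsv(data.frame(bin = names(hist), count = as.integer(hist)),
                    p("lncrna_length_histogram.tsv"))
    de_avail <- tryCatch(need("de", "de", load_de), error = function(e) NULL)
    if (!is.null(de_avail)) {
      state$de <- de_avail
      chrom <- chromosome_enrichment(passing("lncRNA"), ann$transcripts,
                                     ann$genes_per_chrom)
      write_table_tsv(chrom, p("lncrna_chromosome_enrichment.tsv"))
    }
    log_line(log_con, "classify: ", nrow(classes), " lncRNAs in ",
             length(unique(classes$category)), " categories")
  }

  if ("cnc" %in% cfg$steps) {
    study <- need("study", "simulate", load_study)
    de <- need("de", "de", load_de)
    state$de <- de
    cnc <- build_cnc_network(get_norm("mRNA"), get_norm("lncRNA"),
                             passing("mRNA"), passing("lncRNA"),
                             cfg$coexpr_cfg)
    write_network(cnc, p("cnc_edges.tsv"), "tsv")
    write_network(cnc, p("cnc_edges.sif"), "sif")
    s <- network_summary(cnc)
    summary$cnc <- list(n_nodes = s$n_nodes, n_edges = s$n_edges,
                        positive = unname(s$sign_counts["positive"]),
                        negative = unname(s$sign_counts["negative"]))
    log_line(log_con, "cnc: ", s$n_nodes, " nodes, ", s$n_edges, " edges")
  }

  if ("targets" %in% cfg$steps || "cerna" %in% cfg$steps) {
    study <- need("study", "simulate", load_study)
    de <- need("de", "de", load_de)
    state$de <- de
    seq_ids <- function(x) vapply(x, `[[`, character(1), "id")
    mir_recs <- study$sequences$mirnas[
      seq_ids(study$sequences$mirnas) %in% passing("miRNA")]
    utr_recs <- study$sequences$mrna_utrs[
      seq_ids(study$sequences$mrna_utrs) %in% passing("mRNA")]
    if ("targets" %in% cfg$steps) {
      sites <- scan_all_sites(mir_recs, utr_recs)
      write_table_tsv(sites, p("mirna_mrna_sites.tsv"))
      tgt <- build_mirna_target_network(get_norm("miRNA"), get_norm("mRNA"),
                                        de$miRNA, de$mRNA, sites,
                                        cfg$coexpr_cfg)
      write_table_tsv(tgt, p("target_edges.tsv"))
      s <- network_summary(tgt[, colnames(tgt) != "n_sites"])
      summary$target_network <- list(n_nodes = s$n_nodes, n_edges = s$n_edges)
      log_line(log_con, "targets: ", s$n_edges, " negatively correlated edges")
    }
    if ("cerna" %in% cfg$steps) {
      circ_recs <- study$sequences$circrnas[
        seq_ids(study$sequences$circrnas) %in% passing("circRNA")]
      triplets <- build_cerna_network(
        get_norm("circRNA"), get_norm("miRNA"), get_norm("mRNA"),
        de$circRNA, de$miRNA, de$mRNA,
        circ_recs, utr_recs, mir_recs, cfg$coexpr_cfg)
      write_table_tsv(triplets, p("cerna_triplets.tsv"))
      write_network(cerna_edges(triplets), p("cerna_edges.sif"), "sif")
      if (nrow(triplets)) {
        attrs <- cerna_node_attributes(triplets, de$circRNA, de$miRNA, de$mRNA)
        write_table_tsv(attrs, p("cerna_node_attributes.tsv"))
      }
      summary$cerna <- list(n_triplets = nrow(triplets))
      log_line(log_con, "cerna: ", nrow(triplets), " triplets")
    }
  }

  if ("enrich" %in% cfg$steps) {
    study <- need("study", "simulate", load_study)
    de <- need("de", "de", load_de)
    state$de <- de
    universe <- rownames(study$matrices$mRNA$values)
    d <- de$mRNA
    query <- d$transcript_id[d$passes_filter & d$direction == "up"]
    enr <- hypergeometric_enrich(query, study$gene_sets, universe)
    enr <- enr[order(-enr$enrichment_score, enr$fdr, enr$term_id), ]
    write_table_tsv(enr, p("enrichment_up_mRNA.tsv"))
    top <- top_terms(enr, 10)
    summary$enrichment <- list(
      n_terms = nrow(enr),
      top_term = if (nrow(top)) top$term_id[1] else NA,
      top_score = if (nrow(top)) top$enrichment_score[1] else NA)
    log_line(log_con, "enrich: top term ", summary$enrichment$top_term,
             " (score ", round(summary$enrichment$top_score, 2), ")")
  }

  atomic_write(p("summary.json"), function(tmp) {
    jsonlite::write_json(summary, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  log_line(log_con, sprintf("pipeline done in %.1f s",
                            as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(summary)
}
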