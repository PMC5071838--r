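# End-to-end orchestration: simulate -> clean -> subtract -> classify ->
# count -> differential expression (-> targets), with a run manifest.

#' Default run configuration
#'
#' All thresholds of the pipeline in one list; serializes losslessly
#' through JSON ([write_run_config()] / [read_run_config()]).
#'
#' @param seed RNG seed for the simulation.
#' @param out_dir output directory.
#' @param n_mirnas,genome_length,depth simulation sizes.
#' @param contamination_fraction,degenerate_fraction read class mix.
#' @param fc_map named list/vector of true fold changes (condition2 /
#'   condition1).
#' @param adapter3 3' adapter.
#' @param min_len,max_len,min_qual cleaning thresholds.
#' @param max_mismatch mapping mismatch allowance.
#' @param mfe_max,min_stem_pairs hairpin validation thresholds.
#' @param alpha,fc_min DE call thresholds.
#' @param utr_fasta,term_map optional target-prediction inputs (paths);
#'   the target stage runs only when `utr_fasta` is given.
#' @param enrich_alpha enrichment threshold on corrected p.
#' @return `run_config` list.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("savmir_run_"),
                       n_mirnas = 60L, genome_length = 50000L, depth = 1e5,
                       contamination_fraction = 0.10,
                       degenerate_fraction = 0.02,
                       fc_map = list(), adapter3 = DEFAULT_ADAPTER3,
                       min_len = 15L, max_len = 30L, min_qual = 20,
                       max_mismatch = 1L, mfe_max = -18, min_stem_pairs = 16L,
                       alpha = 0.05, fc_min = 1.5,
                       utr_fasta = NULL, term_map = NULL,
                       enrich_alpha = 0.001) {
  cfg <- mget(names(formals()))      # fixed field order for serialization
  check(cfg$min_len <= cfg$max_len, "min_len must be <= max_len")
  check(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0, 1]")
  check(cfg$fc_min >= 1, "fc_min must be >= 1")
  check(cfg$mfe_max <= 0, "mfe_max is a free energy and must be <= 0")
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$fc_map <- as.list(cfg$fc_map)
  do.call(run_config, cfg)
}

#' Run the whole pipeline from one configuration
#'
#' Stages: reference + library simulation, read cleaning, ncRNA/repeat
#' subtraction, conserved/novel classification with hairpin validation,
#' count matrix assembly, chi-squared differential expression with
#' Bonferroni correction, and (when UTRs are configured) seed-match
#' target prediction with term enrichment. Every intermediate artifact is
#' written under `out_dir`; the manifest records parameters, per-stage
#' read ledger and md5 hashes of all outputs. Re-running the same config
#' reproduces byte-identical outputs.
#'
#' @param config a `run_config` (or path to its JSON).
#' @return the manifest (list), invisibly also written to
#'   `out_dir/manifest.json`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  check(inherits(config, "run_config"), "config must be a run_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- simulate ---------------------------------------------------------
  ref <- stage("simulate", make_reference(config$seed, config$n_mirnas,
                                          config$genome_length))
  spec <- library_spec(seed = config$seed + 1L, depth = config$depth,
                       adapter3 = config$adapter3,
                       contamination_fraction = config$contamination_fraction,
                       degenerate_fraction = config$degenerate_fraction)
  sim <- stage("simulate",
               simulate_libraries(ref, spec, unlist(config$fc_map), out))
  write_fasta(ref$genome, file.path(out, "genome.fa"))
  write_fasta(ref$precursors, file.path(out, "hairpin.fa"))
  write_fasta(ref$matures, file.path(out, "mature.fa"))
  write_fasta(ref$ncrna_decoys, file.path(out, "ncrna.fa"))
  write_fasta(ref$repeat_decoys, file.path(out, "repeats.fa"))

  # --- clean ------------------------------------------------------------
  cl <- stage("clean", clean_reads(sim$fastq, adapter3 = config$adapter3,
                                   min_len = config$min_len,
                                   max_len = config$max_len,
                                   min_qual = config$min_qual))
  write_tag_fasta(cl$tags, file.path(out, "tags.fa"))
  write_tsv(cl$tags, file.path(out, "tags.tsv"))
  ledger_df <- data.frame(stage = rownames(cl$ledger), cl$ledger,
                          check.names = FALSE)

  # --- subtract ---------------------------------------------------------
  libs <- names(sim$fastq)
  nc_idx <- reference_index(ref$ncrna_decoys, "ncrna")
  rp_idx <- reference_index(ref$repeat_decoys, "repeat")
  sub1 <- stage("subtract", subtract_tags(cl$tags, rp_idx, config$max_mismatch))
  sub2 <- stage("subtract", subtract_tags(sub1$kept, nc_idx, config$max_mismatch))
  subtract_row <- function(stage, removed) {
    row <- data.frame(stage = stage,
                      t(colSums(removed[, libs, drop = FALSE])),
                      check.names = FALSE)
    row[libs] <- lapply(row[libs], as.integer)
    row
  }
  ledger_df <- rbind(ledger_df,
    subtract_row("repeat", sub1$removed),
    subtract_row("ncrna", sub2$removed))
  write_tsv(ledger_df, file.path(out, "ledger.tsv"))

  # --- classify ---------------------------------------------------------
  known <- ref$precursors[ref$mature_info$conserved]
  mir_idx <- reference_index(c(known, ref$matures[ref$mature_info$conserved]),
                             "precursor", name = "known-miRNA")
  gen_idx <- reference_index(ref$genome, "genome")
  ann <- stage("classify",
               annotate_tags(sub2$kept, mir_idx, gen_idx, fold_check = TRUE,
                             mfe_max = config$mfe_max,
                             min_stem_pairs = config$min_stem_pairs))
  write_tsv(ann, file.path(out, "annotations.tsv"))
  fam <- assign_families(ann[ann$class %in% c("conserved", "novel"), ])
  write_tsv(fam, file.path(out, "families.tsv"))

  # --- counts + DE ------------------------------------------------------
  mirna_tags <- ann[ann$class %in% c("conserved", "novel"), , drop = FALSE]
  id_by_seq <- setNames(ref$mature_info$id, ref$mature_info$seq)
  mirna_tags$mirna_id <- ifelse(mirna_tags$seq %in% names(id_by_seq),
                                id_by_seq[mirna_tags$seq],
                                paste0("tag:", mirna_tags$seq))
  counts <- data.frame(mirna_id = mirna_tags$mirna_id,
                       mirna_tags[, libs, drop = FALSE],
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts, file.path(out, "counts.tsv"))
  totals <- cl$n_raw
  # orientation: condition 2 (second library) is WL in the report
  de <- stage("diffexp", de_table(
    counts[, c("mirna_id", libs[2], libs[1])],
    totals = c(totals[libs[2]], totals[libs[1]]),
    alpha = config$alpha, fc_min = config$fc_min))
  write_tsv(de, file.path(out, "de.tsv"))

  # --- targets (optional) ----------------------------------------------
  target_files <- character()
  if (!is.null(config$utr_fasta)) {
    utrs <- read_fasta(config$utr_fasta)
    de_mirnas <- de$mirna_id[de$call != "ns"]
    mir_seqs <- ref$matures[intersect(de_mirnas, names(ref$matures))]
    sites <- stage("targets", scan_targets(mir_seqs, utrs))
    tg <- aggregate_targets(sites)
    write_tsv(sites, file.path(out, "sites.tsv"))
    write_tsv(tg, file.path(out, "targets.tsv"))
    target_files <- c("sites.tsv", "targets.tsv")
    if (!is.null(config$term_map)) {
      tm <- read_tsv(config$term_map)
      enr <- stage("targets", hypergeom_enrich(unique(tg$transcript),
                                               names(utrs), tm,
                                               alpha = config$enrich_alpha))
      write_tsv(enr, file.path(out, "enrichment.tsv"))
      target_files <- c(target_files, "enrichment.tsv")
    }
  }

  files <- c("winged.fastq", "wingless.fastq", "truth.tsv", "genome.fa",
             "hairpin.fa", "mature.fa", "ncrna.fa", "repeats.fa", "tags.fa",
             "tags.tsv", "ledger.tsv", "annotations.tsv", "families.tsv",
             "counts.tsv", "de.tsv", target_files)
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  manifest <- list(
    parameters = unclass(config)[setdiff(names(config), "out_dir")],
    n_raw = as.list(cl$n_raw),
    ledger = ledger_df,
    n_tags = nrow(cl$tags),
    n_mirna_tags = nrow(mirna_tags),
    class_counts = as.list(table(ann$class)),
    de_calls = as.list(table(de$call)),
    hashes = hashes
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", pretty = TRUE)
  invisible(manifest)
}
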