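# Ground-truthed synthetic references and two-condition small RNA libraries.
#
# The generator states the world the downstream analysis assumes: ~22 nt
# mature miRNAs with a 5'-U bias excised from stem-loop precursors embedded
# in a genome, rRNA/tRNA-like and repeat contamination including a 27-28 nt
# piRNA-like length class, reads of fixed 36 nt built as insert + 3'
# adapter, and per-miRNA abundances with condition-specific fold changes.

# paper-stated 3' chimeric oligonucleotide adapter
DEFAULT_ADAPTER3 <- "TGGAATTCTCGGGTGCCAAGG"
DEFAULT_ADAPTER5 <- "GTTCAGAGTTCTACAGTCCGACGATC"

MATURE_LEN_PROFILE <- c(
  `18` = 0.02, `19` = 0.03, `20` = 0.08, `21` = 0.15, `22` = 0.40,
  `23` = 0.15, `24` = 0.08, `25` = 0.05, `26` = 0.04
)

# contamination insert lengths: junk below 15 nt, a broad sRNA range and a
# piRNA-like 27-28 nt class for the bimodal length histogram
CONTAM_LEN_PROFILE <- local({
  p <- setNames(numeric(21), 10:30)
  p[as.character(10:14)] <- 0.03   # removed by the length filter
  p[as.character(15:26)] <- 0.04
  p[as.character(27:28)] <- 0.15
  p[as.character(29:30)] <- 0.035
  p / sum(p)
})

random_mature <- function(n, u5_bias = 0.4) {
  lens <- sample(as.integer(names(MATURE_LEN_PROFILE)), n, replace = TRUE,
                 prob = MATURE_LEN_PROFILE)
  first <- ifelse(runif(n) < u5_bias, "T",
                  sample(c("A", "C", "G"), n, replace = TRUE))
  vapply(seq_len(n), function(i) {
    paste0(first[i], paste(sample(DNA_BASES, lens[i] - 1L, replace = TRUE),
                           collapse = ""))
  }, "")
}

#' Embed a mature miRNA in a synthetic stem-loop precursor
#'
#' Builds a precursor whose 5' (or 3') arm carries the mature verbatim,
#' whose opposite arm carries its full reverse complement, with an 8-15 nt
#' terminal loop and a ~10 nt closing stem extension so the hairpin is
#' unambiguous under [validate_hairpin()] defaults regardless of the
#' mature's GC content.
#'
#' @param mature 18-26 nt sequence (ACGT or ACGU).
#' @param seed integer RNG seed; the same (mature, seed) always returns the
#'   same precursor.
#' @param arm which arm carries the mature (`"5p"` or `"3p"`).
#' @return character precursor with attributes `mature_start`,
#'   `mature_end` (1-based inclusive) and `arm`.
#' @export
embed_hairpin <- function(mature, seed, arm = c("5p", "3p")) {
  arm <- match.arg(arm)
  mature <- canonical_dna(mature, allow_n = FALSE, what = "mature")
  check(nchar(mature) >= 18 && nchar(mature) <= 26,
        "mature length must be in [18, 26] nt")
  with_seed(seed, {
    ext  <- paste(sample(DNA_BASES, 10, replace = TRUE,
                         prob = c(0.15, 0.35, 0.35, 0.15)), collapse = "")
    loop_len <- sample(8:15, 1)
    loop <- random_dna(1, loop_len)
    if (arm == "5p") {
      pre <- paste0(ext, mature, loop, revcomp(mature), revcomp(ext))
      m1 <- nchar(ext) + 1L
    } else {
      pre <- paste0(ext, revcomp(mature), loop, mature, revcomp(ext))
      m1 <- nchar(ext) + nchar(mature) + loop_len + 1L
    }
    structure(pre, mature_start = m1, mature_end = m1 + nchar(mature) - 1L,
              arm = arm)
  })
}

#' Generate a ground-truthed synthetic reference bundle
#'
#' Creates `n_mirnas` mature miRNAs (length peaked at 22 nt, 5'-U bias),
#' one hairpin precursor each, a genome hosting every precursor at a
#' non-overlapping position, ncRNA (rRNA/tRNA-like) and repeat decoy sets
#' sharing no 18-26 nt substring with any mature, and a truth table of
#' per-mature relative abundances. A `conserved_fraction` of the matures
#' is flagged conserved: those precursors form the known-miRNA reference
#' that stands in for miRBase downstream; the rest are novel (genome-only).
#'
#' @param seed integer RNG seed.
#' @param n_mirnas number of matures (>= 1).
#' @param genome_length genome size in nt; must host all precursors.
#' @param conserved_fraction fraction flagged conserved (default 0.5).
#' @param n_ncrna,n_repeat decoy set sizes.
#' @param u5_bias probability the first mature base is U (default 0.4).
#' @return object of class `reference_bundle`: list with `genome`,
#'   `precursors`, `matures`, `mature_info` (id, seq, precursor_id, arm,
#'   conserved, mature_start/end, genome_start), `ncrna_decoys`,
#'   `repeat_decoys`, `truth` (mirna_id, base_weight, conserved).
#' @export
make_reference <- function(seed, n_mirnas, genome_length = 50000,
                           conserved_fraction = 0.5,
                           n_ncrna = 10, n_repeat = 5, u5_bias = 0.4) {
  check(n_mirnas >= 1, "n_mirnas must be >= 1")
  with_seed(seed, {
    matures <- random_mature(n_mirnas, u5_bias)
    while (anyDuplicated(matures))   # vanishing probability, but be exact
      matures[duplicated(matures)] <- random_mature(sum(duplicated(matures)), u5_bias)

    conserved <- seq_len(n_mirnas) <= round(n_mirnas * conserved_fraction)
    ids <- ifelse(conserved,
                  sprintf("sav-miR-%d", seq_len(n_mirnas)),
                  sprintf("PC-%d", seq_len(n_mirnas)))
    names(matures) <- ids

    pre_seeds <- sample.int(.Machine$integer.max, n_mirnas)
    arms <- sample(c("5p", "3p"), n_mirnas, replace = TRUE)
    precursors <- setNames(vector("list", n_mirnas), paste0(ids, "-pre"))
    for (i in seq_len(n_mirnas))
      precursors[[i]] <- embed_hairpin(matures[[i]], pre_seeds[i], arms[i])
    pre_seqs <- setNames(vapply(precursors, as.character, ""), names(precursors))

    pre_len <- nchar(pre_seqs)
    if (sum(pre_len) > genome_length)
      stop("genome too small to place all precursors", call. = FALSE)
    # random non-overlapping placement: split the slack into n+1 gaps
    slack <- genome_length - sum(pre_len)
    gaps <- as.vector(rmultinom(1, slack, rep(1, n_mirnas + 1L)))
    order_ix <- sample.int(n_mirnas)
    pieces <- character(2L * n_mirnas + 1L)
    starts <- integer(n_mirnas)
    pos <- 0L
    for (k in seq_len(n_mirnas)) {
      pieces[2L * k - 1L] <- random_dna(1, gaps[k])
      pos <- pos + gaps[k]
      i <- order_ix[k]
      pieces[2L * k] <- pre_seqs[i]
      starts[i] <- pos + 1L
      pos <- pos + pre_len[i]
    }
    pieces[2L * n_mirnas + 1L] <- random_dna(1, gaps[n_mirnas + 1L])
    genome <- c(chr1 = paste(pieces, collapse = ""))

    mers18 <- unlist(lapply(matures, function(m) {
      n <- nchar(m)
      if (n < 18) return(character())
      substring(m, 1:(n - 17), 18:n)
    }), use.names = FALSE)
    fresh_decoy <- function(len) {
      repeat {
        d <- random_dna(1, len)
        if (!any(vapply(mers18, function(k) grepl(k, d, fixed = TRUE), NA)))
          return(d)
      }
    }
    nc_kind <- rep_len(c("rRNA", "tRNA", "snRNA", "snoRNA"), n_ncrna)
    ncrna <- setNames(vapply(sample(70:150, n_ncrna, replace = TRUE),
                             fresh_decoy, ""),
                      sprintf("%s_%d", nc_kind, seq_len(n_ncrna)))
    reps <- setNames(vapply(sample(150:300, n_repeat, replace = TRUE),
                            fresh_decoy, ""),
                     sprintf("repeat_%d", seq_len(n_repeat)))

    w <- exp(rnorm(n_mirnas, 0, 1.2))
    truth <- data.frame(mirna_id = ids, base_weight = w / sum(w),
                        conserved = conserved, stringsAsFactors = FALSE)

    info <- data.frame(
      id = ids, seq = unname(matures), precursor_id = names(precursors),
      arm = arms, conserved = conserved,
      mature_start = vapply(precursors, attr, 0L, "mature_start"),
      mature_end = vapply(precursors, attr, 0L, "mature_end"),
      genome_start = starts, stringsAsFactors = FALSE
    )
    structure(list(genome = genome, precursors = pre_seqs, matures = matures,
                   mature_info = info, ncrna_decoys = ncrna,
                   repeat_decoys = reps, truth = truth),
              class = "reference_bundle")
  })
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat(sprintf(paste0("reference_bundle: %d matures (%d conserved), genome %d nt, ",
                     "%d ncRNA + %d repeat decoys\n"),
              length(x$matures), sum(x$truth$conserved), nchar(x$genome),
              length(x$ncrna_decoys), length(x$repeat_decoys)))
  invisible(x)
}

#' Library simulation settings
#'
#' @param seed integer RNG seed.
#' @param depth reads per library (exact FASTQ record count).
#' @param adapter3,adapter5 adapter sequences; the 3' adapter is ligated to
#'   every insert and must be at least 6 nt or trimming is ambiguous.
#' @param contamination_fraction expected fraction of reads drawn from
#'   decoy sequences (includes the 27-28 nt piRNA-like class).
#' @param degenerate_fraction expected fraction of reads built to violate
#'   exactly one sequence-composition rule each.
#' @param quality_mean,quality_sd per-base Phred quality model (truncated
#'   normal, Phred+33 encoding).
#' @param read_length fixed pre-trim read length, nt.
#' @return validated `library_spec` list.
#' @export
library_spec <- function(seed = 1L, depth = 1e5,
                         adapter3 = DEFAULT_ADAPTER3,
                         adapter5 = DEFAULT_ADAPTER5,
                         contamination_fraction = 0.10,
                         degenerate_fraction = 0.02,
                         quality_mean = 34, quality_sd = 3,
                         read_length = 36L) {
  check(depth >= 0, "depth must be >= 0")
  check(nchar(adapter3) >= 6, "3' adapter shorter than 6 nt: trimming would be ambiguous")
  check(contamination_fraction >= 0 && degenerate_fraction >= 0 &&
          contamination_fraction + degenerate_fraction < 1,
        "contamination + degenerate fractions must sum to < 1")
  structure(list(seed = as.integer(seed), depth = as.integer(depth),
                 adapter3 = canonical_dna(adapter3),
                 adapter5 = canonical_dna(adapter5),
                 contamination_fraction = contamination_fraction,
                 degenerate_fraction = degenerate_fraction,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 read_length = as.integer(read_length)),
            class = "library_spec")
}

# all composition rules violated by seq (same rules as filter_composition)
composition_reasons <- function(seq) {
  r <- character()
  if (nchar(gsub("[^N]", "", seq)) >= 2) r <- c(r, "N")
  if (grepl("A{7,}", seq)) r <- c(r, "polyA")
  if (grepl("C{8,}", seq)) r <- c(r, "polyC")
  if (grepl("G{6,}", seq)) r <- c(r, "polyG")
  if (grepl("T{7,}", seq)) r <- c(r, "polyT")
  if (grepl("([ACGTN]{2})\\1{9,}", seq, perl = TRUE)) r <- c(r, "dimer")
  if (grepl("([ACGTN]{3})\\1{5,}", seq, perl = TRUE)) r <- c(r, "trimer")
  if (grepl("([ACGTN]{4})\\1{4,}", seq, perl = TRUE)) r <- c(r, "tetramer")
  r
}

# one insert violating exactly the requested rule. A 2-mer repeated 10
# times is unavoidably also a 4-mer repeated 5 times, so "exactly one" is
# read as: the requested rule is the first to fire and no rule outside its
# implied set fires.
degenerate_insert <- function(rule) {
  implied <- if (rule == "dimer") c("dimer", "tetramer") else rule
  repeat {
    s <- switch(rule,
      N = { x <- strsplit(random_dna(1, 20), "")[[1]]
            x[sample(20, 2)] <- "N"; paste(x, collapse = "") },
      polyA = paste0(random_dna(1, 6), strrep("A", 7), random_dna(1, 7)),
      polyC = paste0(random_dna(1, 6), strrep("C", 8), random_dna(1, 6)),
      polyG = paste0(random_dna(1, 7), strrep("G", 6), random_dna(1, 7)),
      polyT = paste0(random_dna(1, 6), strrep("T", 7), random_dna(1, 7)),
      dimer = strrep(paste(sample(DNA_BASES, 2), collapse = ""), 10),
      trimer = paste0(strrep(random_dna(1, 3), 6), random_dna(1, 2)),
      tetramer = strrep(random_dna(1, 4), 5)
    )
    r <- composition_reasons(s)
    if (length(r) && r[1] == rule && all(r %in% implied)) return(s)
  }
}

#' Simulate two-condition small RNA FASTQ libraries
#'
#' Each library holds exactly `spec$depth` reads of
#' `insert + 3' adapter`, truncated (or padded with random bases) to
#' `spec$read_length`, with Phred+33 qualities. miRNA inserts are sampled
#' multinomially with condition-1 probabilities proportional to the truth
#' table's base weights and condition-2 probabilities proportional to
#' `base_weight * fc_map`; with fixed depth this compositional closure
#' makes the expected realized ratio `fc / (1 + delta)` where
#' `delta = sum(w * (fc - 1))` — negligible when spiked mass is small.
#' Contamination reads are decoy substrings (with a 27-28 nt class) and
#' degenerate reads each violate exactly one composition rule.
#'
#' @param ref a `reference_bundle` from [make_reference()].
#' @param spec a `library_spec`.
#' @param fc_map named numeric vector of condition2/condition1 fold
#'   changes (> 0); missing miRNAs default to 1.
#' @param out_dir output directory (created if needed).
#' @param conditions length-2 character, condition labels in order
#'   (condition 1, condition 2); defaults to winged then wingless.
#' @return list with `fastq` (named paths), `truth` (path) and `truth_df`
#'   (mirna_id, cond1_count, cond2_count, true_fc).
#' @export
simulate_libraries <- function(ref, spec, fc_map = NULL, out_dir,
                               conditions = c("winged", "wingless")) {
  check(inherits(ref, "reference_bundle"), "ref must be a reference_bundle")
  check(inherits(spec, "library_spec"), "spec must be a library_spec")
  ids <- ref$truth$mirna_id
  fc <- setNames(rep(1, length(ids)), ids)
  if (!is.null(fc_map)) {
    check(all(fc_map > 0), "fold changes must be > 0")
    check(all(names(fc_map) %in% ids), "fc_map names must be mirna ids")
    fc[names(fc_map)] <- fc_map
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  w1 <- ref$truth$base_weight
  w2 <- w1 * fc
  decoys <- c(ref$ncrna_decoys, ref$repeat_decoys)

  counts <- matrix(0L, length(ids), 2, dimnames = list(ids, conditions))
  paths <- setNames(file.path(out_dir, paste0(conditions, ".fastq")), conditions)

  with_seed(spec$seed, {
    for (ci in 1:2) {
      w <- if (ci == 1) w1 else w2
      cat_counts <- as.vector(rmultinom(1, spec$depth,
        c((1 - spec$contamination_fraction - spec$degenerate_fraction),
          spec$contamination_fraction, spec$degenerate_fraction)))
      n_real <- cat_counts[1]; n_cont <- cat_counts[2]; n_deg <- cat_counts[3]

      mir_counts <- as.vector(rmultinom(1, n_real, w / sum(w)))
      counts[, ci] <- mir_counts
      inserts <- rep(unname(ref$matures), mir_counts)

      if (n_cont > 0) {
        lens <- sample(as.integer(names(CONTAM_LEN_PROFILE)), n_cont,
                       replace = TRUE, prob = CONTAM_LEN_PROFILE)
        src <- sample(decoys, n_cont, replace = TRUE)
        lens <- pmin(lens, nchar(src))
        off <- floor(runif(n_cont) * (nchar(src) - lens + 1)) + 1L
        inserts <- c(inserts, substring(src, off, off + lens - 1L))
      }
      if (n_deg > 0) {
        rules <- sample(c("N", "polyA", "polyC", "polyG", "polyT",
                          "dimer", "trimer", "tetramer"), n_deg, replace = TRUE)
        inserts <- c(inserts, vapply(rules, degenerate_insert, ""))
      }
      if (length(inserts)) inserts <- inserts[sample.int(length(inserts))]

      full <- if (length(inserts)) paste0(inserts, spec$adapter3)
              else character()
      short <- which(nchar(full) < spec$read_length)
      if (length(short)) {
        need <- spec$read_length - nchar(full[short])
        pool <- paste(sample(DNA_BASES, sum(need), replace = TRUE),
                      collapse = "")
        ends <- cumsum(need)
        full[short] <- paste0(full[short],
                              substring(pool, ends - need + 1L, ends))
      }
      seqs <- substr(full, 1L, spec$read_length)

      nread <- length(seqs)
      q <- round(rnorm(nread * spec$read_length, spec$quality_mean, spec$quality_sd))
      q <- pmax(2L, pmin(41L, as.integer(q)))
      qall <- rawToChar(as.raw(q + 33L))
      quals <- if (nread)
        substring(qall, (seq_len(nread) - 1L) * spec$read_length + 1L,
                  seq_len(nread) * spec$read_length)
      else character()

      reads <- data.frame(
        id = if (nread) sprintf("%s_%d", conditions[ci], seq_len(nread)) else character(),
        seq = seqs, qual = quals, stringsAsFactors = FALSE
      )
      write_fastq(reads, paths[ci])
    }
  })

  truth_df <- data.frame(mirna_id = ids,
                         cond1_count = counts[, 1], cond2_count = counts[, 2],
                         true_fc = unname(fc), stringsAsFactors = FALSE)
  truth_path <- file.path(out_dir, "truth.tsv")
  write_tsv(truth_df, truth_path)
  list(fastq = paths, truth = truth_path, truth_df = truth_df)
}
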