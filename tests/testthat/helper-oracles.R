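# Independent oracles and tiny fixture builders. These stay deliberately
# dumb (position-by-position R loops) so they share no code path with the
# implementation they check.

# brute-force Hamming scan: all ungapped full-length occurrences of
# pattern in subject with <= max_mm substitutions
oracle_hamming_scan <- function(pattern, subject, max_mm = 1L) {
  p <- utf8ToInt(pattern)
  s <- utf8ToInt(subject)
  m <- length(p); n <- length(s)
  starts <- integer(); mms <- integer()
  for (st in seq_len(max(0L, n - m + 1L))) {
    mm <- sum(s[st:(st + m - 1L)] != p)
    if (mm <= max_mm) { starts <- c(starts, st - 1L); mms <- c(mms, mm) }
  }
  list(start = starts, mismatches = mms)
}

# oracle complement table for the site scanner
oracle_comp <- c(A = "T", C = "G", G = "C", T = "A")

# exhaustive canonical seed-site scan, checked base by base
oracle_site_scan <- function(mirna, utr) {
  mb <- strsplit(mirna, "")[[1]]
  ub <- strsplit(utr, "")[[1]]
  n <- length(ub)
  res <- data.frame(start = integer(), site_type = character(),
                    stringsAsFactors = FALSE)
  # core = complement of miRNA positions 2..7, reversed onto the mRNA
  core <- rev(unname(oracle_comp[mb[2:7]]))
  m8 <- unname(oracle_comp[mb[8]])
  for (p in seq_len(max(0L, n - 5L))) {
    if (!all(ub[p:(p + 5L)] == core)) next
    has_m8 <- p > 1 && ub[p - 1L] == m8
    has_a1 <- p + 6L <= n && ub[p + 6L] == "A"
    if (has_m8 && has_a1)
      res <- rbind(res, data.frame(start = p - 2L, site_type = "8mer"))
    else if (has_m8)
      res <- rbind(res, data.frame(start = p - 2L, site_type = "7mer-m8"))
    else if (has_a1)
      res <- rbind(res, data.frame(start = p - 1L, site_type = "7mer-A1"))
  }
  res
}

# exact hypergeometric upper tail by enumeration
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

rand_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                       replace = TRUE), collapse = "")

# write a minimal FASTQ from sequences with constant quality
write_tiny_fastq <- function(seqs, path, qchar = "I") {
  lines <- character(0)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0("@r", i), seqs[i], "+",
               strrep(qchar, nchar(seqs[i])))
  }
  writeLines(lines, path)
  path
}

# a balanced CT table: targets x conditions x bio/tech reps around given
# per-condition dCT offsets from the reference
make_ct_table <- function(targets, conditions, dct_by_cond,
                          ref = "U6", n_bio = 3, n_tech = 3,
                          ref_ct = 20, jitter = 0, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (tg in c(targets, ref)) for (cond in conditions)
    for (b in seq_len(n_bio)) for (tc in seq_len(n_tech)) {
      base <- if (tg == ref) ref_ct else ref_ct + dct_by_cond[[cond]]
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, condition = cond, bio_rep = b, tech_rep = tc,
        ct = base + rnorm(1, 0, jitter), stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}
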