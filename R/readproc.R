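# Raw read cleaning: the digital filter cascade.
#
# Fixed stage order: 3' adapter trim -> length -> quality -> composition
# (ncRNA/repeat subtraction happens later, on collapsed tags). Length and
# composition are pure predicates on the trimmed sequence, so keep/remove
# decisions are order-insensitive between them; the ledger attributes each
# removal to the first stage that fires under this order.

#' Trim the 3' adapter from reads
#'
#' Finds the left-most position where a prefix of the adapter matches the
#' read with at most `max_mismatch` substitutions over at least
#' `min_overlap` bases (the match may run off the 3' end of the read) and
#' returns the insert 5' of it. Reads with no qualifying match are flagged
#' removed with reason `"3ADT"`.
#'
#' @param seq character vector of read sequences.
#' @param qual optional parallel vector of quality strings, trimmed with
#'   the sequence.
#' @param adapter3 adapter sequence (non-empty).
#' @param min_overlap minimum matched bases (>= 6).
#' @param max_mismatch substitutions allowed in the matched region.
#' @return data.frame with `seq`, `qual` (NA-free only if `qual` given),
#'   `removed` (logical) and `reason` (`"3ADT"` or NA). Trimmed sequences
#'   of removed reads are NA.
#' @export
trim_adapter <- function(seq, qual = NULL, adapter3,
                         min_overlap = 6L, max_mismatch = 1L) {
  check(nchar(adapter3) > 0, "empty adapter")
  check(min_overlap >= 6, "min_overlap must be >= 6")
  adapter3 <- canonical_dna(adapter3)
  cut <- .adapter_cut_cpp(seq, adapter3, as.integer(min_overlap),
                          as.integer(max_mismatch))
  removed <- is.na(cut)
  out <- data.frame(
    seq = ifelse(removed, NA_character_, substr(seq, 1L, cut - 1L)),
    removed = removed,
    reason = ifelse(removed, "3ADT", NA_character_),
    stringsAsFactors = FALSE
  )
  out$qual <- if (is.null(qual)) NA_character_
              else ifelse(removed, NA_character_, substr(qual, 1L, cut - 1L))
  out[, c("seq", "qual", "removed", "reason")]
}

#' Length filter
#'
#' Keeps inserts of 15-30 nt inclusive; shorter and longer reads are
#' removed.
#'
#' @param seq character vector of trimmed sequences.
#' @param min_len,max_len bounds, nt.
#' @return logical keep vector.
#' @export
filter_length <- function(seq, min_len = 15L, max_len = 30L) {
  n <- nchar(seq)
  n >= min_len & n <= max_len
}

#' Quality filter
#'
#' Keeps reads whose mean Phred score is at or above the threshold
#' (boundary inclusive: removal is for quality strictly below 20).
#'
#' @param qual character vector of Phred+33 quality strings.
#' @param threshold minimum mean Phred score.
#' @return logical keep vector.
#' @export
filter_quality <- function(qual, threshold = 20) {
  keep <- rep(FALSE, length(qual))
  ok <- !is.na(qual) & nzchar(qual)
  if (any(ok)) {
    q <- qual[ok]
    w <- nchar(q)
    cs <- cumsum(utf8ToInt(paste(q, collapse = "")) - 33)
    ends <- cumsum(w)
    means <- diff(c(0, cs[ends])) / w
    keep[ok] <- means >= threshold
  }
  keep
}

#' Sequence composition filter
#'
#' Removes a sequence when any rule fires: >= 2 N bases in total; a
#' homopolymer run of A >= 7, C >= 8, G >= 6 or T >= 7; or a tandem
#' repeat of a 2-mer unit >= 10 times, a 3-mer >= 6 times, or a 4-mer
#' >= 5 times. The reported reason names the first rule fired, in the
#' order N, polyA, polyC, polyG, polyT, dimer, trimer, tetramer.
#'
#' @param seq character vector (ACGTN alphabet; anything else errors).
#' @return data.frame with `keep` (logical) and `reason` (NA when kept).
#' @export
filter_composition <- function(seq) {
  seq <- canonical_dna(seq, allow_n = TRUE, what = "read")
  reason <- rep(NA_character_, length(seq))
  rules <- list(
    N        = function(s) nchar(gsub("[^N]", "", s)) >= 2,
    polyA    = function(s) grepl("A{7,}", s),
    polyC    = function(s) grepl("C{8,}", s),
    polyG    = function(s) grepl("G{6,}", s),
    polyT    = function(s) grepl("T{7,}", s),
    dimer    = function(s) grepl("([ACGTN]{2})\\1{9,}", s, perl = TRUE),
    trimer   = function(s) grepl("([ACGTN]{3})\\1{5,}", s, perl = TRUE),
    tetramer = function(s) grepl("([ACGTN]{4})\\1{4,}", s, perl = TRUE)
  )
  for (r in names(rules)) {
    open <- is.na(reason)
    if (!any(open)) break
    hit <- rules[[r]](seq[open])
    reason[open][hit] <- r
  }
  data.frame(keep = is.na(reason), reason = reason, stringsAsFactors = FALSE)
}

#' Collapse cleaned reads to unique tags with per-library counts
#'
#' @param reads named list of character vectors, one per library, of
#'   cleaned insert sequences.
#' @return data.frame with `seq` and one count column per library; the
#'   per-library count sums equal the input read numbers exactly.
#' @export
collapse_tags <- function(reads) {
  check(is.list(reads) && !is.null(names(reads)), "reads must be a named list")
  all_seq <- sort(unique(unlist(reads, use.names = FALSE)))
  out <- data.frame(seq = all_seq, stringsAsFactors = FALSE)
  for (lib in names(reads)) {
    tb <- table(reads[[lib]])
    out[[lib]] <- as.integer(tb[match(all_seq, names(tb))])
    out[[lib]][is.na(out[[lib]])] <- 0L
  }
  out[rowSums(as.matrix(out[, -1, drop = FALSE])) > 0L, , drop = FALSE]
}

base_freq <- function(chars) {
  f <- table(factor(chars, levels = DNA_BASES))
  as.vector(f) / max(1, sum(f))
}

#' Per-library summary statistics
#'
#' Length histogram, first/last base frequencies, per-position base
#' frequency matrix and the tag copy-number histogram, plus the filter
#' ledger — the descriptive statistics behind the usual length
#' distribution and nucleotide-bias figures.
#'
#' @param tags CleanTag table from [collapse_tags()] (one count column
#'   assumed summed if several).
#' @param raw optional character vector of raw (pre-filter) sequences for
#'   the raw length histogram.
#' @param ledger optional filter ledger data.frame to carry through.
#' @return list with `length_histogram` (unique tags per length 10-30),
#'   `raw_length_histogram`, `first_base_freq`, `last_base_freq`,
#'   `per_position_freq` (4 x max-length matrix, columns sum to 1),
#'   `read_count_frequency` (table of tag copy numbers) and
#'   `filter_ledger`.
#' @export
summarize_library <- function(tags, raw = NULL, ledger = NULL) {
  seqs <- tags$seq
  lens <- nchar(seqs)
  hist_levels <- 10:30
  length_histogram <- table(factor(lens, levels = hist_levels))
  raw_length_histogram <- if (is.null(raw)) NULL
    else table(factor(pmin(nchar(raw), 30), levels = hist_levels))

  chars <- strsplit(seqs, "")
  first_base_freq <- setNames(base_freq(vapply(chars, `[`, "", 1L)), DNA_BASES)
  last_base_freq <- setNames(
    base_freq(vapply(chars, function(x) x[length(x)], "")), DNA_BASES)

  maxlen <- if (length(lens)) max(lens) else 0L
  ppf <- matrix(0, 4, maxlen, dimnames = list(DNA_BASES, NULL))
  for (p in seq_len(maxlen)) {
    at <- vapply(chars, function(x) if (length(x) >= p) x[p] else NA_character_, "")
    ppf[, p] <- base_freq(at[!is.na(at)])
  }

  counts <- rowSums(as.matrix(tags[, setdiff(names(tags), "seq"), drop = FALSE]))
  read_count_frequency <- table(counts)

  list(length_histogram = length_histogram,
       raw_length_histogram = raw_length_histogram,
       first_base_freq = first_base_freq, last_base_freq = last_base_freq,
       per_position_freq = ppf, read_count_frequency = read_count_frequency,
       filter_ledger = ledger)
}

#' Run the whole cleaning cascade on one or two FASTQ libraries
#'
#' Applies adapter trimming, length, mean-quality and composition filters
#' in the package's fixed order, collapses survivors to unique tags and
#' returns a per-stage removal ledger whose totals plus survivors equal
#' the raw read count exactly.
#'
#' @param fastq named character vector of FASTQ paths (names are library
#'   labels).
#' @param adapter3 3' adapter sequence.
#' @param min_len,max_len insert length bounds.
#' @param min_qual mean Phred threshold.
#' @param min_overlap,max_mismatch adapter match settings.
#' @return list with `tags` (CleanTag table), `ledger` (stage x library
#'   removal counts with survivors row), `summaries` (per-library
#'   [summarize_library()] output) and `n_raw`.
#' @export
clean_reads <- function(fastq, adapter3 = DEFAULT_ADAPTER3,
                        min_len = 15L, max_len = 30L, min_qual = 20,
                        min_overlap = 6L, max_mismatch = 1L) {
  check(!is.null(names(fastq)), "fastq paths must be named by library")
  cleaned <- list(); summaries <- list()
  stages <- c("3ADT", "length", "quality", "composition")
  ledger <- matrix(0L, length(stages) + 1L, length(fastq),
                   dimnames = list(c(stages, "survivors"), names(fastq)))
  n_raw <- integer(length(fastq)); names(n_raw) <- names(fastq)

  for (lib in names(fastq)) {
    reads <- read_fastq(fastq[[lib]])
    n_raw[lib] <- nrow(reads)
    tr <- trim_adapter(reads$seq, reads$qual, adapter3, min_overlap, max_mismatch)
    ledger["3ADT", lib] <- sum(tr$removed)
    alive <- !tr$removed

    keep_len <- filter_length(tr$seq, min_len, max_len)
    ledger["length", lib] <- sum(alive & !keep_len)
    alive <- alive & keep_len

    keep_q <- filter_quality(tr$qual, min_qual)
    ledger["quality", lib] <- sum(alive & !keep_q)
    alive <- alive & keep_q

    comp <- filter_composition(ifelse(alive, tr$seq, "A"))
    ledger["composition", lib] <- sum(alive & !comp$keep)
    alive <- alive & comp$keep

    ledger["survivors", lib] <- sum(alive)
    cleaned[[lib]] <- tr$seq[alive]
  }

  tags <- collapse_tags(cleaned)
  for (lib in names(fastq)) {
    lib_tags <- tags[tags[[lib]] > 0, c("seq", lib)]
    summaries[[lib]] <- summarize_library(lib_tags,
      ledger = data.frame(stage = rownames(ledger), removed = ledger[, lib]))
  }
  list(tags = tags, ledger = ledger, summaries = summaries, n_raw = n_raw)
}
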