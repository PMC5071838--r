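# Tag annotation: decoy subtraction, <=1-mismatch mapping, conserved /
# semi-conserved / novel classification, seed families.

#' Build a reference index
#'
#' @param sequences named character vector (FASTA-derived).
#' @param kind one of `"ncrna"`, `"repeat"`, `"mature"`, `"precursor"`,
#'   `"genome"`.
#' @param name label for reports.
#' @return `reference_index` object.
#' @export
reference_index <- function(sequences, kind, name = kind) {
  kind <- match.arg(kind, c("ncrna", "repeat", "mature", "precursor", "genome"))
  check(length(sequences) > 0 && !is.null(names(sequences)),
        "reference sequences must be a non-empty named vector")
  sequences <- canonical_dna(sequences, allow_n = TRUE, what = name)
  structure(list(name = name, kind = kind, sequences = sequences),
            class = "reference_index")
}

#' Map a tag to a reference with at most one mismatch
#'
#' Reports every ungapped full-length occurrence of the tag in the index
#' with Hamming distance <= `max_mismatch`; for genome-kind indexes both
#' strands are scanned (a minus-strand hit is an occurrence of the
#' reverse complement at that plus-sense position). Hits are ordered by
#' (reference id, start).
#'
#' @param tag sequence of length >= 15.
#' @param index a `reference_index`.
#' @param max_mismatch allowed substitutions (default 1).
#' @return data.frame with `ref`, `start` (0-based), `strand`,
#'   `mismatches`.
#' @export
match_le1 <- function(tag, index, max_mismatch = 1L) {
  check(inherits(index, "reference_index"), "index must be a reference_index")
  tag <- canonical_dna(tag)
  check(nchar(tag) >= 15, "tag length must be >= 15")
  strands <- if (index$kind == "genome") c("+", "-") else "+"
  out <- list()
  for (strand in strands) {
    pat <- if (strand == "+") tag else revcomp(tag)
    for (ri in seq_along(index$sequences)) {
      subj <- index$sequences[[ri]]
      if (nchar(tag) > nchar(subj)) next
      mt <- .hamming_scan_cpp(pat, subj, max_mismatch)
      if (!length(mt$start)) next
      out[[length(out) + 1L]] <- data.frame(
        ref = names(index$sequences)[ri], start = mt$start, strand = strand,
        mismatches = mt$mismatches, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(ref = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$ref, res$start, res$strand), , drop = FALSE]
}

# fast any-hit test for a set of tags against an index; reference
# sequences are concatenated with an N spacer longer than any tag so no
# match can straddle a boundary within the mismatch budget.
has_hit <- function(tags, index, max_mismatch = 1L) {
  subject <- paste(index$sequences, collapse = strrep("N", 40L))
  hit <- .any_hit_cpp(tags, subject, max_mismatch)
  if (index$kind == "genome")
    hit <- hit | .any_hit_cpp(revcomp(tags), subject, max_mismatch)
  hit
}

#' Subtract tags matching an ncRNA or repeat decoy index
#'
#' A tag is removed iff it has at least one <=1-mismatch hit in the
#' index; the partition is exhaustive and disjoint.
#'
#' @param tags CleanTag table (with a `seq` column).
#' @param index `reference_index` of kind `"ncrna"` or `"repeat"`.
#' @param max_mismatch allowed substitutions.
#' @return list with `kept` and `removed` tag tables.
#' @export
subtract_tags <- function(tags, index, max_mismatch = 1L) {
  check(inherits(index, "reference_index"), "index must be a reference_index")
  check(index$kind %in% c("ncrna", "repeat"),
        "subtraction index must be of kind ncrna or repeat")
  hit <- has_hit(tags$seq, index, max_mismatch)
  list(kept = tags[!hit, , drop = FALSE], removed = tags[hit, , drop = FALSE])
}

#' Extract the 7 nt seed of a mature miRNA
#'
#' The seed is base positions 2-8 from the 5' end (1-based, inclusive).
#'
#' @param mature sequence(s) of length >= 8.
#' @return character vector of 7 nt seeds.
#' @export
extract_seed <- function(mature) {
  mature <- canonical_dna(mature)
  check(all(nchar(mature) >= 8), "mature must be at least 8 nt for a 2-8 seed")
  substr(mature, 2L, 8L)
}

#' Classify a tag as conserved, semi-conserved, novel or unclassified
#'
#' Conserved: hits both the known-miRNA reference (mature or precursor
#' set) and the genome. Semi-conserved: hits exactly one of the two.
#' Novel: no known-miRNA hit but a genome hit whose flanking locus folds
#' into a hairpin passing [validate_hairpin()]. Anything else is
#' unclassified.
#'
#' @param tag tag sequence (>= 15 nt).
#' @param mirbase `reference_index` of known matures and/or precursors
#'   (kind `"mature"` or `"precursor"`).
#' @param genome `reference_index` of kind `"genome"`.
#' @param fold_check validate the hairpin at novel loci (default TRUE;
#'   when FALSE a genome-only tag is called novel without folding).
#' @param flank nt of genomic context tried on each side when folding
#'   candidate precursors (default 50).
#' @param ... thresholds passed to [validate_hairpin()].
#' @return list with `class`, `mirbase_hits`, `genome_hits`.
#' @export
classify_tag <- function(tag, mirbase, genome, fold_check = TRUE,
                         flank = 50L, ...) {
  mhits <- match_le1(tag, mirbase)
  ghits <- match_le1(tag, genome)
  cls <-
    if (nrow(mhits) && nrow(ghits)) "conserved"
    else if (nrow(mhits)) "semi-conserved"
    else if (nrow(ghits)) {
      # genome-only: a valid flanking hairpin makes it a novel miRNA;
      # without one it is still genome-anchored, hence semi-conserved
      if (!fold_check || novel_locus_valid(tag, ghits, genome, flank, ...))
        "novel"
      else "semi-conserved"
    }
    else "unclassified"
  list(class = cls, mirbase_hits = mhits, genome_hits = ghits)
}

# any genome hit of tag whose flanking locus folds into a valid hairpin
novel_locus_valid <- function(tag, ghits, genome, flank = 50L, ...) {
  L <- nchar(tag)
  for (h in seq_len(nrow(ghits))) {
    gseq <- genome$sequences[[ghits$ref[h]]]
    s <- ghits$start[h] + 1L                 # 1-based
    # try the mature on the 5' arm (extend 3') and on the 3' arm (extend 5')
    windows <- list(c(max(1L, s - 12L), min(nchar(gseq), s + L - 1L + flank)),
                    c(max(1L, s - flank), min(nchar(gseq), s + L - 1L + 12L)))
    for (wnd in windows) {
      pre <- substr(gseq, wnd[1], wnd[2])
      if (nchar(pre) < 40) next
      pre_use <- if (ghits$strand[h] == "+") pre else revcomp(pre)
      mpos <- if (ghits$strand[h] == "+") c(s - wnd[1] + 1L, s - wnd[1] + L)
              else c(wnd[2] - (s + L - 1L) + 1L, wnd[2] - s + 1L)
      fold <- fold_hairpin(pre_use)
      v <- validate_hairpin(fold, mpos, ...)
      if (v$pass) return(TRUE)
    }
  }
  FALSE
}

#' Classify and annotate a set of tags
#'
#' Applies [classify_tag()] to every tag and assembles an annotation
#' table with seeds (for tags >= 8 nt) and best-hit bookkeeping.
#'
#' @inheritParams classify_tag
#' @param tags CleanTag table.
#' @return data.frame with `seq`, per-library counts, `class`,
#'   `family_seed`, `mirbase_ref`, `mirbase_mismatches`, `genome_ref`,
#'   `genome_start` (1-based in reports), `genome_strand`.
#' @export
annotate_tags <- function(tags, mirbase, genome, fold_check = TRUE,
                          flank = 50L, ...) {
  n <- nrow(tags)
  cls <- character(n)
  mref <- mmm <- gref <- gstrand <- rep(NA_character_, n)
  gstart <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- classify_tag(tags$seq[i], mirbase, genome, fold_check, flank, ...)
    cls[i] <- r$class
    if (nrow(r$mirbase_hits)) {
      best <- r$mirbase_hits[order(r$mirbase_hits$mismatches), ][1, ]
      mref[i] <- best$ref; mmm[i] <- as.character(best$mismatches)
    }
    if (nrow(r$genome_hits)) {
      best <- r$genome_hits[order(r$genome_hits$mismatches), ][1, ]
      gref[i] <- best$ref; gstart[i] <- best$start + 1L
      gstrand[i] <- best$strand
    }
  }
  out <- tags
  out$class <- cls
  out$family_seed <- ifelse(nchar(tags$seq) >= 8, substr(tags$seq, 2L, 8L),
                            NA_character_)
  out$mirbase_ref <- mref
  out$mirbase_mismatches <- as.integer(mmm)
  out$genome_ref <- gref
  out$genome_start <- gstart
  out$genome_strand <- gstrand
  out
}

#' Group miRNAs into families by identical seed
#'
#' @param annotations data.frame with `id` (or `seq` used as id) and
#'   `family_seed` columns, e.g. from [annotate_tags()].
#' @return data.frame with `family` (named after the lexicographically
#'   smallest member id), `seed`, `size`, `members`
#'   (comma-separated ids), ordered by decreasing size then family name.
#' @export
assign_families <- function(annotations) {
  if (!nrow(annotations))
    return(data.frame(family = character(), seed = character(),
                      size = integer(), members = character(),
                      stringsAsFactors = FALSE))
  ids <- if ("id" %in% names(annotations)) annotations$id else annotations$seq
  seeds <- annotations$family_seed
  keep <- !is.na(seeds)
  ids <- ids[keep]; seeds <- seeds[keep]
  fam <- lapply(split(ids, seeds), sort)
  out <- data.frame(
    family = vapply(fam, `[`, "", 1L),
    seed = names(fam),
    size = lengths(fam),
    members = vapply(fam, paste, "", collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$size, out$family), , drop = FALSE]
}
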