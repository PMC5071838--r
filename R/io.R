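# File I/O: FASTA/FASTQ via Biostrings, tables as plain TSV.

#' Read a FASTQ file into a raw-read table
#'
#' @param path FASTQ file (Phred+33 qualities).
#' @return data.frame with columns `id`, `seq`, `qual` (quality as the raw
#'   ASCII string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id   = names(x),
    seq  = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a raw-read table to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector (uppercase DNA alphabet, U mapped to T).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(canonical_dna(as.character(x), allow_n = TRUE), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write collapsed tags as count-suffix FASTA
#'
#' Headers follow the `>tag{n}_x{count}` dialect, with the count being the
#' tag's total across libraries.
#'
#' @param tags CleanTag table from [collapse_tags()].
#' @param path output file.
#' @export
write_tag_fasta <- function(tags, path) {
  counts <- rowSums(as.matrix(tags[, setdiff(names(tags), "seq"), drop = FALSE]))
  seqs <- setNames(tags$seq, sprintf("tag%d_x%d", seq_len(nrow(tags)), counts))
  write_fasta(seqs, path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a qPCR CT table from TSV
#'
#' Expected columns: `target`, `condition`, `bio_rep`, `tech_rep`, `ct`.
#'
#' @param path TSV file.
#' @return validated CT table data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- read_tsv(path)
  need <- c("target", "condition", "bio_rep", "tech_rep", "ct")
  check(all(need %in% names(ct)),
        paste("CT table must have columns:", paste(need, collapse = ", ")))
  check(all(is.finite(ct$ct) & ct$ct > 0), "CT values must be finite and > 0")
  ct
}
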