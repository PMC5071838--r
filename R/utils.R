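# Shared internal helpers: alphabet checks, reverse complement, seeded RNG.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA/RNA character vector
#'
#' U is treated as T on input; output is DNA-sense (ACGT), the package's
#' internal canonical alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("ACGTUacgtu", "TGCAATGCAA", x)
  vapply(strsplit(out, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# Canonicalize to uppercase DNA alphabet; error on anything outside allow.
canonical_dna <- function(x, allow_n = FALSE, what = "sequence") {
  x <- chartr("u", "T", toupper(x))
  x <- chartr("U", "T", x)
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- grepl(pat, x)
  if (any(bad)) {
    stop(sprintf("%s contains non-nucleotide symbols (first offender: '%s')",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  x
}

# Evaluate expr under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

random_dna <- function(n, length, p = c(0.25, 0.25, 0.25, 0.25)) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
  }, "")
}

# stopifnot() with a readable message
check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
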