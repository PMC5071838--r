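# Precursor hairpin folding and validation.

#' Fold a miRNA precursor into its best single hairpin
#'
#' Computes a minimum-free-energy stem-loop structure under a
#' nearest-neighbor stacking model restricted to single-hairpin
#' topologies (no multiloops). Watson-Crick and GU pairs are allowed;
#' terminal-loop and interior-loop penalties are linear in loop size.
#' The backend is pluggable: any function taking a sequence and
#' returning the same fields can be passed as `backend`.
#'
#' @param precursor nucleotide string, 40-200 nt, ACGT/ACGU.
#' @param backend folding engine; the default is the in-package dynamic
#'   program. Must return a list with `structure`, `mfe`, `stem_pairs`,
#'   `loop_length`.
#' @return object of class `hairpin_fold`: list with `structure`
#'   (dot-bracket), `mfe` (kcal/mol, <= 0), `stem_pairs`, `loop_length`,
#'   and `seq`.
#' @examples
#' fold_hairpin(embed_hairpin("TGAGGTAGTAGGTTGTATAGTT", seed = 1))
#' @export
fold_hairpin <- function(precursor, backend = NULL) {
  check(length(precursor) == 1L, "fold one precursor at a time")
  seq <- canonical_dna(precursor, allow_n = FALSE, what = "precursor")
  check(nchar(seq) >= 40 && nchar(seq) <= 200,
        "precursor length must be in [40, 200] nt")
  res <- if (is.null(backend)) .fold_hairpin_cpp(seq) else backend(seq)
  res$mfe <- min(res$mfe, 0)
  res$seq <- seq
  class(res) <- "hairpin_fold"
  res
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat(sprintf("hairpin fold: %d nt, MFE %.2f kcal/mol, %d stem pairs, loop %s nt\n",
              nchar(x$seq), x$mfe, x$stem_pairs,
              ifelse(is.na(x$loop_length), "-", x$loop_length)))
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Validate a folded precursor as a plausible miRNA hairpin
#'
#' A fold passes when (i) its minimum free energy is at or below
#' `mfe_max` kcal/mol, (ii) the mature sequence lies on one arm of the
#' stem with at most `max_loop_overlap` nt protruding into the terminal
#' loop, (iii) the stem holds at least `min_stem_pairs` base pairs, and
#' (iv) at most half the mature's bases are unpaired.
#'
#' @param fold a `hairpin_fold` from [fold_hairpin()].
#' @param mature_position integer length-2 vector, 1-based inclusive
#'   interval of the mature within the precursor.
#' @param mfe_max energy threshold, kcal/mol (default -18).
#' @param min_stem_pairs minimum base pairs in the stem (default 16).
#' @param max_loop_overlap maximum mature overlap into the loop, nt
#'   (default 4).
#' @param max_unpaired_frac maximum unpaired fraction within the mature
#'   (default 0.5).
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing), plus `mature_arm`
#'   (`"5p"`, `"3p"` or `"spanning"`).
#' @export
validate_hairpin <- function(fold, mature_position,
                             mfe_max = -18, min_stem_pairs = 16,
                             max_loop_overlap = 4, max_unpaired_frac = 0.5) {
  check(inherits(fold, "hairpin_fold"), "fold must come from fold_hairpin()")
  m1 <- as.integer(mature_position[1]); m2 <- as.integer(mature_position[2])
  n <- nchar(fold$seq)
  if (m1 < 1 || m2 > n || m1 > m2)
    stop("mature interval outside precursor coordinates", call. = FALSE)

  reasons <- character()
  if (fold$mfe > mfe_max) reasons <- c(reasons, "mfe")
  if (fold$stem_pairs < min_stem_pairs) reasons <- c(reasons, "stem_pairs")

  db <- strsplit(fold$structure, "")[[1]]
  arm <- "spanning"
  if (!any(db != ".")) {
    reasons <- c(reasons, "arm", "unpaired_fraction")
  } else {
    il <- max(which(db == "("))   # innermost pair bounds the terminal loop
    jl <- min(which(db == ")"))
    in_loop <- sum(seq(m1, m2) > il & seq(m1, m2) < jl)
    if (m2 <= il + max_loop_overlap && m1 < il) arm <- "5p"
    else if (m1 >= jl - max_loop_overlap && m2 > jl) arm <- "3p"
    if (arm == "spanning" || in_loop > max_loop_overlap)
      reasons <- c(reasons, "arm")
    unpaired <- mean(db[m1:m2] == ".")
    if (unpaired > max_unpaired_frac) reasons <- c(reasons, "unpaired_fraction")
  }
  list(pass = length(reasons) == 0L, reasons = unique(reasons), mature_arm = arm)
}
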