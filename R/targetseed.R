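# Canonical seed-match target prediction and term over-representation.
#
# Site classes on the mRNA (5'->3'), for a miRNA with bases m1..mN:
#   7mer-m8: exact Watson-Crick complement of m2..m8
#   7mer-A1: complement of m2..m7 followed by an A on the mRNA
#   8mer:    both (complement of m2..m8 followed by A)
# Overlapping matches at one core position are reported once at the
# strongest class (8mer > 7mer-m8 > 7mer-A1). U and T are equivalent.

#' Scan a UTR for canonical seed-match sites
#'
#' @param mirna mature miRNA sequence (>= 8 nt, 5'->3').
#' @param utr UTR sequence (mRNA sense, 5'->3').
#' @param mirna_id,utr_id labels carried into the output.
#' @return data.frame with `mirna`, `transcript`, `start` (0-based on the
#'   UTR), `site_type`.
#' @export
site_scan <- function(mirna, utr, mirna_id = "mirna", utr_id = "utr") {
  mirna <- canonical_dna(mirna, what = "mirna")
  utr <- canonical_dna(utr, what = "utr")
  check(nchar(mirna) >= 8, "mature must be >= 8 nt")
  core6 <- revcomp(substr(mirna, 2L, 7L))     # complement of m2..m7
  m8c <- revcomp(substr(mirna, 8L, 8L))       # complement of m8

  hits <- gregexpr(core6, utr, fixed = TRUE)[[1]]
  empty <- data.frame(mirna = character(), transcript = character(),
                      start = integer(), site_type = character(),
                      stringsAsFactors = FALSE)
  if (hits[1] == -1) return(empty)

  out <- empty
  n <- nchar(utr)
  for (p in as.integer(hits)) {                  # 1-based core start
    has_m8 <- p > 1 && substr(utr, p - 1L, p - 1L) == m8c
    has_a1 <- p + 6L <= n && substr(utr, p + 6L, p + 6L) == "A"
    row <- if (has_m8 && has_a1) c(p - 2L, "8mer")
           else if (has_m8)      c(p - 2L, "7mer-m8")
           else if (has_a1)      c(p - 1L, "7mer-A1")
           else NULL
    if (!is.null(row))
      out <- rbind(out, data.frame(mirna = mirna_id, transcript = utr_id,
                                   start = as.integer(row[1]),
                                   site_type = row[2],
                                   stringsAsFactors = FALSE))
  }
  out
}

#' Scan many miRNAs against many UTRs
#'
#' @param mirnas named character vector of mature sequences.
#' @param utrs named character vector of UTR sequences.
#' @return combined [site_scan()] data.frame.
#' @export
scan_targets <- function(mirnas, utrs) {
  check(!is.null(names(mirnas)) && !is.null(names(utrs)),
        "mirnas and utrs must be named")
  out <- list()
  for (mi in names(mirnas))
    for (ui in names(utrs)) {
      s <- site_scan(mirnas[[mi]], utrs[[ui]], mi, ui)
      if (nrow(s)) out[[length(out) + 1L]] <- s
    }
  if (!length(out))
    return(data.frame(mirna = character(), transcript = character(),
                      start = integer(), site_type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Aggregate sites into a per-miRNA target table
#'
#' @param sites data.frame from [site_scan()]/[scan_targets()].
#' @return data.frame with one row per (mirna, transcript): `n_sites`,
#'   `n_8mer`, `n_7mer_m8`, `n_7mer_A1`; deterministic ordering by
#'   (mirna, transcript).
#' @export
aggregate_targets <- function(sites) {
  if (!nrow(sites))
    return(data.frame(mirna = character(), transcript = character(),
                      n_sites = integer(), n_8mer = integer(),
                      n_7mer_m8 = integer(), n_7mer_A1 = integer(),
                      stringsAsFactors = FALSE))
  key <- paste(sites$mirna, sites$transcript, sep = "\r")
  ks <- sort(unique(key))
  ord <- tapply(seq_len(nrow(sites)), key, `[`, 1L)[ks]
  cnt <- function(type) as.integer(tapply(sites$site_type == type, key, sum)[ks])
  out <- data.frame(
    mirna = sites$mirna[ord], transcript = sites$transcript[ord],
    n_sites = as.integer(tapply(rep(1L, nrow(sites)), key, sum)[ks]),
    n_8mer = cnt("8mer"), n_7mer_m8 = cnt("7mer-m8"), n_7mer_A1 = cnt("7mer-A1"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$mirna, out$transcript), , drop = FALSE]
}

#' Hypergeometric over-representation of annotation terms
#'
#' One-sided upper-tail hypergeometric p per term (probability of at
#' least the observed number of annotated genes in the target set), with
#' Bonferroni correction over tested terms by default (BH available).
#'
#' @param target_genes character vector, subset of `universe`.
#' @param universe character vector of all gene ids.
#' @param term_map data.frame with `term_id`, `gene_id` columns.
#' @param alpha significance threshold on the corrected p (default 0.001).
#' @param method `"bonferroni"` (default) or `"BH"`.
#' @return data.frame with `term_id`, `universe_count`, `target_count`,
#'   `p`, `p_adj`, `significant`.
#' @export
hypergeom_enrich <- function(target_genes, universe, term_map,
                             alpha = 0.001, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  target_genes <- unique(target_genes)
  universe <- unique(universe)
  if (!all(target_genes %in% universe))
    stop("target genes absent from universe: ",
         paste(utils::head(setdiff(target_genes, universe), 3), collapse = ", "),
         call. = FALSE)
  check(all(c("term_id", "gene_id") %in% names(term_map)),
        "term_map needs term_id and gene_id columns")
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- split(unique(term_map)$gene_id, unique(term_map)$term_id)
  N <- length(universe); n <- length(target_genes)
  K <- lengths(terms)
  k <- vapply(terms, function(g) sum(target_genes %in% g), 0L)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  p_adj <- if (method == "bonferroni") adjust_bonferroni(p)
           else stats::p.adjust(p, "BH")
  data.frame(term_id = names(terms), universe_count = as.integer(K),
             target_count = as.integer(k), p = p, p_adj = p_adj,
             significant = p_adj <= alpha & n > 0,
             stringsAsFactors = FALSE, row.names = NULL)
}
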