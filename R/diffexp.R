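# Digital differential expression: total-count normalization, per-miRNA
# 2x2 chi-squared on raw counts, Bonferroni correction, FC >= 1.5 calls.

#' Normalize counts by total library size
#'
#' Each library's counts are rescaled by mean(total) / total, putting all
#' libraries on the scale of the average sequencing depth. Values are kept
#' at full precision; flooring of zeros to 1 happens only inside ratio
#' computation (see [fold_change()]).
#'
#' @param counts matrix or data.frame of raw counts (miRNAs x libraries).
#' @param totals positive library totals, one per column; defaults to the
#'   column sums.
#' @return numeric matrix of normalized counts.
#' @export
normalize_counts <- function(counts, totals = NULL) {
  m <- as.matrix(counts)
  if (is.null(totals)) totals <- colSums(m)
  check(length(totals) == ncol(m), "one total per library required")
  check(all(totals > 0), "library totals must be > 0")
  sweep(m, 2, mean(totals) / totals, `*`)
}

#' Fold change and signed log2 fold change of two normalized counts
#'
#' `fc` is the magnitude ratio max/min (the convention of digital DE
#' tables); direction is carried by `log2fc = log2(wl / w)`. Inputs are
#' floored at 1 before ratios so zero counts stay finite. Vectorized.
#'
#' @param norm_wl,norm_w normalized counts in the two conditions
#'   (orientation: `log2fc` is log2(WL/W)).
#' @return data.frame with `fc` (>= 1) and `log2fc`.
#' @export
fold_change <- function(norm_wl, norm_w) {
  a <- pmax(norm_wl, 1)
  b <- pmax(norm_w, 1)
  data.frame(fc = pmax(a, b) / pmin(a, b), log2fc = log2(a / b))
}

#' Pearson 2x2 chi-squared test of two library counts
#'
#' Tests the table `[[a, total_a - a], [b, total_b - b]]` without
#' continuity correction, df = 1. Vectorized over `a` and `b`.
#'
#' @param a,b counts in libraries A and B.
#' @param total_a,total_b library totals (>= counts).
#' @return data.frame with `statistic`, `p`, and `low_expected` flagging
#'   tables with any expected cell below 5.
#' @export
chi2_2x2 <- function(a, b, total_a, total_b) {
  check(all(total_a > 0) && all(total_b > 0), "library totals must be > 0")
  if (any(a > total_a) || any(b > total_b))
    stop("count exceeds its library total", call. = FALSE)
  a <- as.numeric(a); b <- as.numeric(b)            # avoid integer overflow
  total_a <- as.numeric(total_a); total_b <- as.numeric(total_b)
  n <- total_a + total_b
  r1 <- a + b
  r2 <- n - r1
  # Pearson statistic in closed form: n (ad - bc)^2 / (r1 r2 c1 c2)
  stat <- n * (a * (total_b - b) - b * (total_a - a))^2 /
    (r1 * r2 * as.numeric(total_a) * as.numeric(total_b))
  stat[r1 == 0 | r2 == 0] <- 0
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  e_min <- pmin(r1 * total_a, r1 * total_b, r2 * total_a, r2 * total_b) / n
  data.frame(statistic = stat, p = p, low_expected = e_min < 5)
}

#' Bonferroni adjustment
#'
#' @param p p-values.
#' @param m number of tests (>= length(p); defaults to length(p)).
#' @return adjusted p-values, `min(1, p * m)`, order-preserving.
#' @export
adjust_bonferroni <- function(p, m = length(p)) {
  check(m >= length(p), "m must be at least the number of p-values")
  pmin(1, p * m)
}

#' Full digital differential expression table
#'
#' Chi-squared tests run on RAW counts against library totals (the
#' sampling model); fold changes are computed from NORMALIZED counts, so
#' the test stays exact under unequal depths while FC is depth-corrected.
#'
#' @param counts matrix/data.frame with two columns (WL then W
#'   orientation) and miRNA ids as rownames, or a data.frame with a
#'   `mirna_id` column followed by the two count columns.
#' @param totals length-2 library totals.
#' @param alpha adjusted-p threshold for calls (default 0.05).
#' @param fc_min fold-change threshold (default 1.5).
#' @return data.frame with `mirna_id`, `raw_wl`, `raw_w`, `norm_wl`,
#'   `norm_w`, `fc`, `log2fc`, `statistic`, `p`, `p_adj`, `call`
#'   (up/down/ns; up = higher in WL).
#' @export
de_table <- function(counts, totals, alpha = 0.05, fc_min = 1.5) {
  if (is.data.frame(counts) && "mirna_id" %in% names(counts)) {
    ids <- counts$mirna_id
    m <- as.matrix(counts[, setdiff(names(counts), "mirna_id")[1:2]])
  } else {
    m <- as.matrix(counts)
    ids <- rownames(m)
    if (is.null(ids)) ids <- sprintf("mir_%d", seq_len(nrow(m)))
  }
  check(ncol(m) == 2, "exactly two libraries required")
  norm <- normalize_counts(m, totals)
  fcs <- fold_change(norm[, 1], norm[, 2])
  chi <- chi2_2x2(m[, 1], m[, 2], totals[1], totals[2])
  out <- data.frame(
    mirna_id = ids, raw_wl = m[, 1], raw_w = m[, 2],
    norm_wl = norm[, 1], norm_w = norm[, 2],
    fc = fcs$fc, log2fc = fcs$log2fc,
    statistic = chi$statistic, p = chi$p,
    p_adj = adjust_bonferroni(chi$p),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$call <- call_de(out, alpha, fc_min)
  out
}

#' Call differential miRNAs
#'
#' Significant iff adjusted p <= `alpha` and fold change >= `fc_min`;
#' direction `up` means higher in the WL (first) condition.
#'
#' @param results data.frame with `fc`, `norm_wl`, `norm_w` and a
#'   p-value column (`p_adj` preferred, else `p`).
#' @param alpha significance threshold on the adjusted p.
#' @param fc_min minimum fold-change magnitude.
#' @return character vector `up` / `down` / `ns`.
#' @export
call_de <- function(results, alpha = 0.05, fc_min = 1.5) {
  p <- if ("p_adj" %in% names(results)) results$p_adj else results$p
  sig <- p <= alpha & results$fc >= fc_min
  ifelse(!sig, "ns", ifelse(results$norm_wl > results$norm_w, "up", "down"))
}

#' Published winged/wingless differential-expression reference table
#'
#' The 32-row reference table of normalized read counts, printed p-values
#' and printed fold changes for the S. avenae winged (W) vs wingless (WL)
#' comparison, used as a fixed arithmetic fixture. Two of the printed FC
#' values (PC-3p-40838_47, PC-3p-80125_21) are not exactly reproducible
#' from the printed integer-rounded normalized reads; see the package
#' vignette.
#'
#' @return data.frame with `mirna_id`, `norm_wl`, `norm_w`, `p_printed`,
#'   `fc_printed`, `log2fc_printed`, `call_printed`, `significant`.
#' @export
wing_de_reference <- function() {
  path <- system.file("extdata", "sav_wing_de_table.tsv", package = "savmir")
  df <- read_tsv(path)
  df$significant <- !grepl("\\*", df$call_printed)
  df$call_printed <- sub("\\*", "", df$call_printed)
  df
}
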