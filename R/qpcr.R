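# Relative quantification of qPCR CT tables by the comparative threshold
# (2^-ddCT) method against a small-RNA reference gene (default U6).

#' Relative expression by the 2^-ddCT method
#'
#' Technical replicates are averaged first; then per biological replicate
#' dCT = CT(target) - CT(reference); ddCT = dCT - mean calibrator-condition
#' dCT of the same target; RQ = 2^-ddCT. Adding a constant to every CT
#' value leaves all RQs unchanged, and the calibrator condition's mean
#' ddCT is 0 by construction.
#'
#' @param ct CT table data.frame with columns `target`, `condition`,
#'   `bio_rep`, `tech_rep`, `ct` (see [read_ct_table()]).
#' @param reference id of the endogenous reference gene (default "U6").
#' @param calibrator condition label used as calibrator (default
#'   "wingless").
#' @return data.frame with one row per target x condition x bio_rep:
#'   `target`, `condition`, `bio_rep`, `dct`, `ddct`, `rq`.
#' @export
ddct <- function(ct, reference = "U6", calibrator = "wingless") {
  check(all(c("target", "condition", "bio_rep", "ct") %in% names(ct)),
        "ct must have target, condition, bio_rep, tech_rep, ct columns")
  check(reference %in% ct$target,
        sprintf("reference '%s' absent from CT table", reference))
  check(calibrator %in% ct$condition,
        sprintf("calibrator condition '%s' absent from CT table", calibrator))

  # average technical replicates
  key <- interaction(ct$target, ct$condition, ct$bio_rep, drop = TRUE)
  avg <- data.frame(
    target = tapply(ct$target, key, `[`, 1L),
    condition = tapply(ct$condition, key, `[`, 1L),
    bio_rep = tapply(ct$bio_rep, key, `[`, 1L),
    ct = as.numeric(tapply(ct$ct, key, mean)),
    stringsAsFactors = FALSE, row.names = NULL
  )

  refrows <- avg[avg$target == reference, ]
  targets <- avg[avg$target != reference, ]
  ix <- match(paste(targets$condition, targets$bio_rep),
              paste(refrows$condition, refrows$bio_rep))
  if (anyNA(ix)) {
    gap <- targets[is.na(ix), c("condition", "bio_rep")][1, ]
    stop(sprintf("no reference CT for condition '%s', bio_rep %s",
                 gap$condition, gap$bio_rep), call. = FALSE)
  }
  targets$dct <- targets$ct - refrows$ct[ix]

  cal_mean <- tapply(targets$dct[targets$condition == calibrator],
                     targets$target[targets$condition == calibrator], mean)
  if (!all(unique(targets$target) %in% names(cal_mean)))
    stop("every target needs calibrator-condition replicates", call. = FALSE)
  targets$ddct <- targets$dct - as.numeric(cal_mean[targets$target])
  targets$rq <- 2^(-targets$ddct)
  targets[order(targets$target, targets$condition, targets$bio_rep),
          c("target", "condition", "bio_rep", "dct", "ddct", "rq")]
}

#' Summarize RQ values per target and condition
#'
#' Adds the two-sample t-test of each condition's per-bio-rep RQs against
#' the calibrator condition's.
#'
#' @param rq output of [ddct()].
#' @param calibrator calibrator condition label.
#' @param on test on `"rq"` (default) or `"ddct"` values.
#' @param var_equal pooled-variance t-test (default TRUE; FALSE = Welch).
#' @return data.frame with `target`, `condition`, `mean_rq`, `t`, `p`
#'   (NA for the calibrator row).
#' @export
rq_summary <- function(rq, calibrator = "wingless", on = c("rq", "ddct"),
                       var_equal = TRUE) {
  on <- match.arg(on)
  out <- list()
  for (tg in unique(rq$target)) {
    sub <- rq[rq$target == tg, ]
    cal <- sub[sub$condition == calibrator, ]
    for (cond in unique(sub$condition)) {
      grp <- sub[sub$condition == cond, ]
      tt <- if (cond == calibrator) list(t = NA_real_, p = NA_real_)
            else two_sample_t(grp[[on]], cal[[on]], var_equal)
      out[[length(out) + 1L]] <- data.frame(
        target = tg, condition = cond, mean_rq = mean(grp$rq),
        t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Two-sample t-test
#'
#' Two-sided test on per-replicate values; pooled variance by default
#' (Welch with `var_equal = FALSE`). Two identical constant groups return
#' t = 0, p = 1.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal pooled-variance (default TRUE).
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  check(nx >= 2 && ny >= 2, "each group needs at least 2 values")
  vx <- stats::var(x); vy <- stats::var(y)
  d <- mean(x) - mean(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  if (se == 0) {
    t <- if (d == 0) 0 else sign(d) * Inf
    return(list(t = t, p = if (d == 0) 1 else 0, df = df))
  }
  t <- d / se
  list(t = t, p = 2 * pt(-abs(t), df), df = df)
}
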