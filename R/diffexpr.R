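#' Median-of-ratios size factors
#'
#' Per-sample normalizers computed as the median, over genes with a finite
#' geometric mean across samples, of the ratio of the sample's count to that
#' geometric mean — the standard library-size estimator for count matrices.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns.
#' @return Positive numeric vector of length `ncol(counts)`.
#' @export
size_factors <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no gene has positive counts in all samples; cannot estimate size ",
         "factors", call. = FALSE)
  }
  sf <- apply(counts, 2, function(x) {
    exp(median(log(x[use]) - loggeo[use]))
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    stop("degenerate size factor estimate", call. = FALSE)
  }
  sf
}

#' Log2 fold change with pseudocount
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))`. The pseudocount
#' guards against zero means; with `pseudocount = 0` the raw ratio is used.
#'
#' @param mean_a,mean_b non-negative normalized abundances.
#' @param pseudocount non-negative stabilizer; default 0.5.
#' @return Numeric log2 ratio (vectorized).
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 0.5) {
  if (any(mean_a < 0, na.rm = TRUE) || any(mean_b < 0, na.rm = TRUE)) {
    stop("means must be non-negative", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A transparent stand-in for heavier differential-expression machinery:
#' counts are normalized by median-of-ratios size factors; each gene gets a
#' method-of-moments dispersion estimate (the larger of the two per-group
#' estimates `(s^2 - m) / m^2`, floored at `1e-8` — taking the maximum
#' guards against the downward bias of small-sample moment estimates); the
#' Wald statistic is the log fold change divided by its delta-method
#' standard error under the NB mean-variance relation
#' `Var = mu + phi * mu^2`, with a two-sided p-value from the normal
#' reference. No dispersion shrinkage, independent filtering, or fold-change
#' shrinkage is applied. Deterministic given its inputs.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames used
#'   as gene identifiers), samples in columns.
#' @param groups factor (or coercible) of length `ncol(counts)` with exactly
#'   two levels; the reported fold change is first level over second level.
#' @param pseudocount stabilizer for the fold change; default 0.5.
#' @param sf optional per-sample size factors; computed by [size_factors()]
#'   when `NULL`.
#' @return Data frame with one row per gene: `gene`, `base_mean`, `log2fc`,
#'   `se`, `stat`, `p`, `untestable`. An all-zero gene is flagged
#'   untestable with `p = 1` and `log2fc = 0`.
#' @export
nb_wald_test <- function(counts, groups, pseudocount = 0.5, sf = NULL) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (length(groups) != ncol(counts)) {
    stop("groups length must match sample count", call. = FALSE)
  }
  if (min(table(groups)) < 2) {
    stop("at least two samples per group required", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != trunc(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  ia <- groups == levels(groups)[1]
  ib <- !ia
  na <- sum(ia); nb <- sum(ib)
  xa <- norm[, ia, drop = FALSE]
  xb <- norm[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)

  mom_phi <- function(x, m) {
    s2 <- rowSums((x - m)^2) / (ncol(x) - 1)
    ifelse(m > 0, pmax((s2 - m) / m^2, 0), 0)
  }
  phi <- pmax(1e-8, mom_phi(xa, ma), mom_phi(xb, mb))

  lfc_ln <- log((ma + pseudocount) / (mb + pseudocount))
  va <- (ma + phi * ma^2) / na
  vb <- (mb + phi * mb^2) / nb
  se_ln <- sqrt(va / (ma + pseudocount)^2 + vb / (mb + pseudocount)^2)

  untestable <- (ma + mb) == 0 | se_ln == 0
  stat <- ifelse(untestable, 0, lfc_ln / se_ln)
  p <- ifelse(untestable, 1, 2 * pnorm(-abs(stat)))
  gene <- rownames(counts)
  if (is.null(gene)) gene <- sprintf("gene%05d", seq_len(nrow(counts)))
  data.frame(gene = gene,
             base_mean = (ma * na + mb * nb) / (na + nb),
             log2fc = ifelse(untestable, 0, lfc_ln / log(2)),
             se = se_ln / log(2),
             stat = stat,
             p = p,
             untestable = untestable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control. Adjusted values are at least the
#' raw values, capped at 1, and preserve the ordering of the input.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-value vector of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1] with no NA", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Count up- and down-regulated genes at volcano-plot thresholds
#'
#' @param results data frame with columns `log2fc` and `adj_p`.
#' @param fc_min absolute log2 fold-change threshold (exceeded strictly);
#'   default 1.0.
#' @param alpha adjusted-p threshold (strict); default 0.05.
#' @return List with `n_up` (`log2fc > fc_min` and `adj_p < alpha`) and
#'   `n_down` (symmetric, `log2fc < -fc_min`).
#' @export
volcano_summary <- function(results, fc_min = 1.0, alpha = 0.05) {
  sig <- !is.na(results$adj_p) & results$adj_p < alpha
  list(n_up = sum(sig & results$log2fc > fc_min),
       n_down = sum(sig & results$log2fc < -fc_min))
}

#' Two-group differential expression, start to finish
#'
#' Runs [nb_wald_test()], appends BH-adjusted p-values, and flags genes
#' passing the fold-change and FDR thresholds.
#'
#' @inheritParams nb_wald_test
#' @inheritParams volcano_summary
#' @return The [nb_wald_test()] table with `adj_p` and a `flag` column
#'   (`"up"`, `"down"`, or `""`).
#' @export
de_analysis <- function(counts, groups, pseudocount = 0.5, sf = NULL,
                        fc_min = 1.0, alpha = 0.05) {
  res <- nb_wald_test(counts, groups, pseudocount = pseudocount, sf = sf)
  res$adj_p <- bh_adjust(res$p)
  res$flag <- ifelse(res$adj_p < alpha & res$log2fc > fc_min, "up",
                     ifelse(res$adj_p < alpha & res$log2fc < -fc_min,
                            "down", ""))
  res
}
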