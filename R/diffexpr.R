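#' Median-of-ratios normalization
#'
#' Size factor per sample = median over features (restricted to rows
#' positive in all samples) of count / row geometric mean. When no row is
#' positive in all samples the function falls back to total-count scaling
#' with a warning.
#'
#' @param counts nonnegative integer matrix, features x samples.
#' @return list with `size_factors` and `normalized` (counts divided by the
#'   sample's size factor).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(counts < 0)) stop("negative counts")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    warning("no feature positive in all samples; using total-count scaling")
    tot <- colSums(counts)
    sf <- tot / exp(mean(log(pmax(tot, 1))))
  } else {
    lgeo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col)
      stats::median(exp(log(col) - lgeo)))
  }
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Negative-binomial Wald test for differential expression
#'
#' A self-contained NB Wald pipeline: per-feature dispersion by the method
#' of moments on normalized counts, shrunk in log space toward a fitted
#' mean-dispersion trend (`a0 + a1/mean`); Wald statistic on the log2 fold
#' change with the NB delta-method variance; two-sided normal p-values;
#' Benjamini-Hochberg FDR across the tested features. Features with all-zero
#' counts are excluded from testing and from the BH denominator. The
#' reported `log2FC` uses a 0.5 pseudocount on the normalized group means
#' for display; the Wald statistic uses the model fit.
#'
#' @param counts integer matrix, features x samples.
#' @param groups factor/character of length `ncol(counts)` with exactly two
#'   levels; the fold change is level2 / level1.
#' @param lfc_threshold,fdr_threshold the screening criterion: a feature is
#'   called when `|log2FC| > lfc_threshold` and `FDR < fdr_threshold`
#'   (defaults 1 and 0.05).
#' @param prior_weight weight of the trend in the log-space dispersion
#'   shrinkage (default 1: trend and moment estimate weighted equally).
#' @return data.frame `feature_id`, `baseMean`, `log2FC`, `lfcSE`, `stat`,
#'   `pvalue`, `padj`, `call`, `tested`.
#' @export
de_test <- function(counts, groups, lfc_threshold = 1, fdr_threshold = 0.05,
                    prior_weight = 1) {
  counts <- as.matrix(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2))
    stop("each group needs >= 2 replicates for a dispersion estimate")
  nn <- normalize_counts(counts)
  norm <- nn$normalized
  sf <- nn$size_factors
  gA <- groups == levels(groups)[1]
  gB <- !gA
  nA <- sum(gA); nB <- sum(gB)
  mA <- rowMeans(norm[, gA, drop = FALSE])
  mB <- rowMeans(norm[, gB, drop = FALSE])
  vA <- apply(norm[, gA, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, gB, drop = FALSE], 1, stats::var)
  sinvA <- mean(1 / sf[gA]); sinvB <- mean(1 / sf[gB])
  baseMean <- rowMeans(norm)
  tested <- rowSums(counts) > 0

  # method-of-moments dispersion, pooled over groups
  aA <- (vA - mA * sinvA) / mA^2
  aB <- (vB - mB * sinvB) / mB^2
  w <- function(m) ifelse(is.finite(m) & m > 0, 1, 0)
  amom <- (aA * (nA - 1) * w(mA) + aB * (nB - 1) * w(mB)) /
    pmax((nA - 1) * w(mA) + (nB - 1) * w(mB), 1)
  amom[!is.finite(amom)] <- NA
  amom <- pmin(pmax(amom, 1e-8), 10)

  # mean-dispersion trend alpha(mu) = a0 + a1/mu on moment estimates
  ok <- tested & !is.na(amom) & baseMean > 0
  a0 <- stats::median(amom[ok], na.rm = TRUE)
  a1 <- 0
  if (sum(ok) >= 10) {
    fit <- try(stats::lm(amom[ok] ~ I(1 / baseMean[ok])), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- stats::coef(fit)
      if (is.finite(cf[1]) && cf[1] > 0) a0 <- cf[1]
      if (is.finite(cf[2]) && cf[2] > 0) a1 <- cf[2]
    }
  }
  atr <- pmin(pmax(a0 + a1 / pmax(baseMean, 1e-8), 1e-8), 10)
  alpha <- exp((prior_weight * log(atr) +
                  ifelse(is.na(amom), log(atr), log(amom))) /
                 (prior_weight + 1))

  # Wald statistic on the log2 ratio of group means (delta method)
  c0 <- 0.5
  use_pseudo <- mA == 0 | mB == 0
  num <- ifelse(use_pseudo, mB + c0, mB)
  den <- ifelse(use_pseudo, mA + c0, mA)
  beta <- log2(num / den)
  varA <- sinvA / (nA * pmax(mA, c0)) + alpha / nA
  varB <- sinvB / (nB * pmax(mB, c0)) + alpha / nB
  se <- sqrt((varA + varB)) / log(2)
  stat <- beta / se
  p <- 2 * stats::pnorm(-abs(stat))
  p[!tested] <- NA
  padj <- rep(NA_real_, length(p))
  padj[tested] <- stats::p.adjust(p[tested], "BH")
  lfc_disp <- log2((mB + c0) / (mA + c0))
  call <- !is.na(padj) & abs(lfc_disp) > lfc_threshold & padj < fdr_threshold
  data.frame(feature_id = rownames(counts), baseMean = baseMean,
             log2FC = lfc_disp, lfcSE = se, stat = stat, pvalue = p,
             padj = padj, call = call, tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate transcript counts to gene level
#'
#' Gene counts are the per-sample sums of the member transcripts' counts.
#'
#' @param counts transcript count matrix (rownames = transcript ids).
#' @param tx2gene data.frame `tx_id`, `gene_id` covering every transcript.
#' @return gene count matrix.
#' @export
gene_counts <- function(counts, tx2gene) {
  counts <- as.matrix(counts)
  g <- tx2gene$gene_id[match(rownames(counts), tx2gene$tx_id)]
  if (anyNA(g))
    stop("transcript(s) with no gene mapping: ",
         paste(utils::head(rownames(counts)[is.na(g)], 5), collapse = ", "))
  rowsum(counts, g)
}

#' Overlap between transcript-level and gene-level DE calls
#'
#' DETG = distinct genes owning at least one called differentially
#' expressed transcript; the intersection with the DEG set is reported as a
#' percentage of both denominators (2 decimals, round-half-up).
#'
#' @param det transcript-level result from [de_test()].
#' @param deg gene-level result from [de_test()] (on [gene_counts()]).
#' @param tx2gene data.frame `tx_id`, `gene_id`.
#' @return list with `n_det`, `n_detg`, `n_deg`, `n_overlap`,
#'   `pct_of_detg`, `pct_of_deg`.
#' @export
overlap_report <- function(det, deg, tx2gene) {
  det_ids <- det$feature_id[det$call]
  detg <- unique(tx2gene$gene_id[match(det_ids, tx2gene$tx_id)])
  detg <- detg[!is.na(detg)]
  degs <- deg$feature_id[deg$call]
  ov <- intersect(detg, degs)
  list(n_det = length(det_ids), n_detg = length(detg), n_deg = length(degs),
       n_overlap = length(ov),
       pct_of_detg = if (length(detg)) pct2(length(ov), length(detg)) else 0,
       pct_of_deg = if (length(degs)) pct2(length(ov), length(degs)) else 0)
}
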