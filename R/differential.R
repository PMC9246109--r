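#' Simplified negative-binomial Wald test for differential expression
#'
#' Tests each feature for differential expression between two sample groups
#' on size-factor-normalized counts. Group means are floored at 0.5 to keep
#' fold changes finite on sparse features; the per-feature dispersion is a
#' method-of-moments estimate pooled within groups (variance =
#' mu + dispersion * mu^2, floored at 1e-8); the Wald standard error of the
#' log2 fold change follows from the NB variance of the two group means by
#' the delta method; p-values are two-sided normal and q-values are
#' Benjamini-Hochberg over the tested features. Features with zero counts in
#' every tested sample are excluded and reported in the `"excluded"`
#' attribute. A feature is flagged `is_de` when `|log2fc| >=
#' fc_threshold_log2` and `q <= q_threshold` (the 4-fold / 0.01 rule by
#' default).
#'
#' @param m A raw-layer `expr_matrix`.
#' @param groupA,groupB Disjoint character vectors of sample ids (>= 2 each);
#'   fold changes are reported as B over A.
#' @param sf Optional size factors covering the tested samples; computed on
#'   the tested samples when `NULL`.
#' @param fc_threshold_log2 Absolute log2 fold-change threshold (default 2,
#'   i.e. 4-fold).
#' @param q_threshold BH q-value threshold (default 0.01).
#' @return A data.frame with one row per tested feature: `feature_id`,
#'   `base_mean`, `log2fc`, `lfc_se`, `stat`, `p`, `q`, `is_de`, `direction`.
#' @export
nb_wald_de <- function(m, groupA, groupB, sf = NULL,
                       fc_threshold_log2 = 2, q_threshold = 0.01) {
  require_layer(m, "raw")
  if (length(intersect(groupA, groupB)) > 0) {
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  }
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs at least 2 samples")
  }
  ids <- c(groupA, groupB)
  if (!all(ids %in% sample_ids(m))) {
    stop("unknown sample id(s): ", paste(setdiff(ids, sample_ids(m)), collapse = ", "))
  }
  sub <- subset_matrix(m, samples = ids)
  if (is.null(sf)) sf <- size_factors_median_of_ratios(sub)
  sf <- sf[ids]
  k <- sweep(em_values(sub), 2, sf, "/")

  keep <- rowSums(k) > 0
  excluded <- feature_ids(m)[!keep]
  k <- k[keep, , drop = FALSE]
  a <- k[, groupA, drop = FALSE]
  b <- k[, groupB, drop = FALSE]
  nA <- length(groupA); nB <- length(groupB)

  muA_raw <- rowMeans(a); muB_raw <- rowMeans(b)
  muA <- pmax(muA_raw, 0.5); muB <- pmax(muB_raw, 0.5)
  log2fc <- log2(muB / muA)

  # pooled within-group method-of-moments dispersion
  vA <- apply(a, 1, stats::var)
  vB <- apply(b, 1, stats::var)
  s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mu_pool <- pmax((nA * muA_raw + nB * muB_raw) / (nA + nB), 0.5)
  disp <- pmax((s2 - mu_pool) / mu_pool^2, 1e-8)

  ln2sq <- log(2)^2
  varA <- (muA + disp * muA^2) / (nA * muA^2 * ln2sq)
  varB <- (muB + disp * muB^2) / (nB * muB^2 * ln2sq)
  se <- sqrt(varA + varB)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  q <- bh_adjust(p)

  is_de <- abs(log2fc) >= fc_threshold_log2 & q <= q_threshold
  direction <- ifelse(!is_de, "none", ifelse(log2fc > 0, "up", "down"))
  out <- data.frame(
    feature_id = rownames(k), base_mean = (muA_raw + muB_raw) / 2,
    log2fc = log2fc, lfc_se = se, stat = stat, p = p, q = q,
    is_de = is_de, direction = direction,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "contrast") <- list(groupA = groupA, groupB = groupB,
                                fc_threshold_log2 = fc_threshold_log2,
                                q_threshold = q_threshold)
  out
}

#' Welch's two-sample t test
#'
#' Two-sided Welch statistic with Welch-Satterthwaite degrees of freedom.
#' The degenerate case of two zero-variance samples returns t = 0, p = 1
#' when the means agree (and t = +-Inf, p = 0 otherwise).
#'
#' @param valuesA,valuesB Numeric vectors (>= 2 values each).
#' @return A list with elements `t`, `df` and `p`.
#' @export
welch_t <- function(valuesA, valuesB) {
  if (length(valuesA) < 2 || length(valuesB) < 2) {
    stop("Welch's t test needs at least 2 values per side")
  }
  if (stats::var(valuesA) == 0 && stats::var(valuesB) == 0) {
    d <- mean(valuesB) - mean(valuesA)
    if (d == 0) return(list(t = 0, df = length(valuesA) + length(valuesB) - 2, p = 1))
    return(list(t = -sign(d) * Inf, df = length(valuesA) + length(valuesB) - 2, p = 0))
  }
  ht <- stats::t.test(valuesA, valuesB, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction with monotonicity enforcement.
#'
#' @param p_values Numeric vector of p-values in \[0,1\].
#' @return Vector of q-values in \[0,1\].
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Number of differentially expressed features between two groups
#'
#' Convenience wrapper around [nb_wald_de()] returning the count of features
#' passing the fold-change and q-value rule.
#'
#' @inheritParams nb_wald_de
#' @return Integer count of `is_de` features.
#' @export
de_count <- function(m, groupA, groupB, sf = NULL,
                     fc_threshold_log2 = 2, q_threshold = 0.01) {
  de <- nb_wald_de(m, groupA, groupB, sf = sf,
                   fc_threshold_log2 = fc_threshold_log2,
                   q_threshold = q_threshold)
  sum(de$is_de)
}
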