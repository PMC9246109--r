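#' Median-of-ratios size factors
#'
#' Computes per-sample depth factors with the median-of-ratios estimator:
#' for each sample, the median over genes positive in all samples of
#' count / geometric-mean-of-that-gene, then rescaled so the factors have
#' geometric mean 1.
#'
#' @param m A raw-layer `expr_matrix`.
#' @return Named numeric vector of size factors (geometric mean 1).
#' @export
size_factors_median_of_ratios <- function(m) {
  require_layer(m, "raw")
  v <- em_values(m)
  ref <- rowSums(v > 0) == ncol(v)
  if (!any(ref)) {
    stop("no gene is positive in all samples; consider a pseudo-reference fallback")
  }
  lg <- rowMeans(log(v[ref, , drop = FALSE]))
  sf <- apply(v[ref, , drop = FALSE], 2, function(col) {
    stats::median(exp(log(col) - lg))
  })
  sf <- sf / .geomean(sf)
  ea_log("size factors: %d samples, %d reference genes", length(sf), sum(ref))
  sf
}

#' Apply size factors
#'
#' Divides each sample's counts by its size factor, giving the
#' depth-normalized layer.
#'
#' @param m A raw-layer `expr_matrix`.
#' @param sf Size factors from [size_factors_median_of_ratios()]; computed
#'   from `m` when `NULL`.
#' @return An `expr_matrix` with layer `"size_normalized"`.
#' @export
apply_size_factors <- function(m, sf = NULL) {
  require_layer(m, "raw")
  sf <- sf %||% size_factors_median_of_ratios(m)
  sf <- sf[sample_ids(m)]
  if (anyNA(sf) || any(sf <= 0)) stop("size factors must cover all samples and be positive")
  expression_matrix(sweep(em_values(m), 2, sf, "/"), "size_normalized")
}

#' GC-content normalization by within-sample full-quantile mapping
#'
#' Genes are split into `n_bins` equal-occupancy bins of GC fraction; within
#' each sample, every bin's expression distribution is quantile-mapped onto
#' the pooled distribution of all binned genes in that sample (rank-preserving
#' within bins), and the sample is rescaled so the binned genes' total signal
#' is unchanged. Features without a GC fraction (e.g. aggregated TE types)
#' pass through untouched and keep their depth-normalized values.
#'
#' @param m A size-normalized `expr_matrix`.
#' @param annotation Feature annotation with `gc_fraction`; required for at
#'   least 90% of gene features.
#' @param n_bins Number of GC bins (default 10).
#' @return An `expr_matrix` with layer `"gc_normalized"`.
#' @export
gc_normalize <- function(m, annotation, n_bins = 10) {
  require_layer(m, "size_normalized")
  if (n_bins < 2) stop("n_bins must be at least 2; got ", n_bins)
  v <- em_values(m)
  ann <- annotation[match(feature_ids(m), annotation$feature_id), ]
  is_gene <- !is.na(ann$kind) & ann$kind == "gene"
  has_gc <- is_gene & !is.na(ann$gc_fraction)
  if (sum(has_gc) < 0.9 * sum(is_gene)) {
    stop("gc_fraction available for fewer than 90% of gene features")
  }
  rows <- which(has_gc)
  gc <- ann$gc_fraction[rows]
  bin <- cut(rank(gc, ties.method = "first"), n_bins, labels = FALSE)
  occ <- tabulate(bin, n_bins)
  if (any(occ < 10)) {
    stop(sprintf("GC bin with %d feature(s) (< 10); use fewer bins", min(occ)))
  }
  bin_rows <- split(seq_along(rows), bin)

  out <- v
  for (j in seq_len(ncol(v))) {
    x <- v[rows, j]
    pooled <- sort(x)
    mapped <- x
    for (b in bin_rows) {
      r <- rank(x[b], ties.method = "average")
      mapped[b] <- stats::quantile(pooled, probs = (r - 0.5) / length(b),
                                   names = FALSE, type = 7)
    }
    tot <- sum(x)
    if (tot > 0) mapped <- mapped * (tot / sum(mapped))
    out[rows, j] <- mapped
  }
  ea_log("gc_normalize: %d binned genes, %d bins, %d pass-through features",
         length(rows), n_bins, nrow(v) - length(rows))
  expression_matrix(out, "gc_normalized")
}

#' Log2 normalized tag counts
#'
#' Elementwise `log2(x + pseudocount)`; with the default pseudocount of 1,
#' zeros stay at 0.
#'
#' @param m A size- or GC-normalized `expr_matrix`.
#' @param pseudocount Positive pseudocount (default 1).
#' @return An `expr_matrix` with layer `"log2ntc"`.
#' @export
log2_ntc <- function(m, pseudocount = 1) {
  require_layer(m, c("size_normalized", "gc_normalized"))
  if (pseudocount <= 0) stop("pseudocount must be positive")
  if (any(em_values(m) < 0)) stop("negative value in normalized matrix")
  expression_matrix(log2(em_values(m) + pseudocount), "log2ntc")
}

#' Per-feature Z-scores
#'
#' Centers and scales each feature by the mean and population standard
#' deviation (denominator n) over the reference samples; features with zero
#' reference variance are set to all-zero Z-scores with a logged warning.
#'
#' @param m A log2-NTC `expr_matrix`.
#' @param reference_samples Sample ids defining the reference distribution;
#'   defaults to all samples.
#' @return An `expr_matrix` with layer `"zscore"`.
#' @export
zscore_by_feature <- function(m, reference_samples = NULL) {
  require_layer(m, "log2ntc")
  v <- em_values(m)
  ref <- reference_samples %||% colnames(v)
  if (!all(ref %in% colnames(v))) stop("unknown reference sample id(s)")
  if (length(ref) < 2) stop("Z-scoring needs at least 2 reference samples")
  r <- v[, ref, drop = FALSE]
  mu <- rowMeans(r)
  sd_pop <- sqrt(rowMeans((r - mu)^2))
  z <- (v - mu) / sd_pop
  flat <- sd_pop == 0
  if (any(flat)) {
    z[flat, ] <- 0
    ea_log("zscore_by_feature: %d zero-variance feature(s) set to Z = 0", sum(flat))
  }
  expression_matrix(z, "zscore")
}
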