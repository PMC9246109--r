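#' Gene-set activity scores from Z-scores
#'
#' Per sample and per set, the sum or mean of the feature Z-scores over the
#' set members present in the matrix. Sets with fewer than 50% of their
#' members present are an error; individually missing members are dropped
#' with a logged note.
#'
#' @param z A zscore-layer `expr_matrix`.
#' @param sets Named list of feature-id vectors (e.g. from [read_gmt()]).
#' @param reduction `"sum"` or `"mean"`.
#' @return A long data frame (`sample_id`, `set`, `score`, `n_present`) with
#'   the reduction recorded in the `"reduction"` attribute.
#' @export
set_score <- function(z, sets, reduction = c("sum", "mean")) {
  require_layer(z, "zscore")
  reduction <- match.arg(reduction)
  v <- em_values(z)
  out <- lapply(names(sets), function(nm) {
    members <- unique(sets[[nm]])
    present <- intersect(members, rownames(v))
    if (length(present) < 0.5 * length(members)) {
      stop(sprintf("set '%s': fewer than 50%% of members present", nm))
    }
    if (length(present) < length(members)) {
      ea_log("set_score: set '%s' missing %d member(s)", nm,
             length(members) - length(present))
    }
    s <- colSums(v[present, , drop = FALSE])
    if (reduction == "mean") s <- s / length(present)
    data.frame(sample_id = colnames(v), set = nm, score = unname(s),
               n_present = length(present), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  attr(out, "reduction") <- reduction
  out
}

#' Rank samples by a set score
#'
#' Descending score order with ties broken by sample id, as used to rank
#' embryos by ribosome/nucleosome expression (arrested embryos fall to the
#' bottom) or by p53-target expression (arrested embryos rise to the top).
#'
#' @param scores Output of [set_score()].
#' @param set_name Which set to rank on.
#' @return Character vector of sample ids, highest score first.
#' @export
rank_samples <- function(scores, set_name) {
  sub <- scores[scores$set == set_name, ]
  if (nrow(sub) == 0) stop("unknown set: ", set_name)
  sub$sample_id[order(-sub$score, sub$sample_id)]
}

#' Percent of normalized signal mapping to transposable elements
#'
#' 100 x (sum of TE-feature signal) / (total signal) per sample. Elevated TE
#' fractions read out a deregulated chromatin state, the hallmark of Type I
#' arrest.
#'
#' @param m A gc- or size-normalized `expr_matrix`.
#' @param annotation Feature annotation (needs >= 1 TE feature).
#' @param samples Optional sample ids (default all).
#' @return Named numeric vector of percentages.
#' @export
te_fraction <- function(m, annotation, samples = NULL) {
  require_layer(m, c("gc_normalized", "size_normalized"))
  samples <- samples %||% sample_ids(m)
  ann <- annotation[match(feature_ids(m), annotation$feature_id), ]
  is_te <- !is.na(ann$kind) & ann$kind == "TE"
  if (!any(is_te)) stop("annotation contains no TE features")
  v <- em_values(m)[, samples, drop = FALSE]
  tot <- colSums(v)
  if (any(tot == 0)) {
    stop("zero total signal for sample(s): ",
         paste(samples[tot == 0], collapse = ", "))
  }
  100 * colSums(v[is_te, , drop = FALSE]) / tot
}

#' Metabolic state coordinates
#'
#' Places each sample in a 2D metabolic plane from two set scores (e.g.
#' glycolysis/gluconeogenesis on x and oxidative phosphorylation on y, both
#' as Z-score sums). Coordinates are exactly the underlying set scores.
#'
#' @param scores Output of [set_score()] with `sum` reduction.
#' @param x_set,y_set Set names for the axes.
#' @return Data frame with `sample_id`, `x`, `y`.
#' @export
metabolic_coordinates <- function(scores, x_set, y_set) {
  for (s in c(x_set, y_set)) {
    if (!s %in% scores$set) stop("set not scored: ", s)
  }
  xs <- scores[scores$set == x_set, ]
  ys <- scores[scores$set == y_set, ]
  ys <- ys[match(xs$sample_id, ys$sample_id), ]
  data.frame(sample_id = xs$sample_id, x = xs$score, y = ys$score,
             stringsAsFactors = FALSE)
}

# Enrichment score of one set in a ranked list from the hit positions alone:
# weighted running sum with hit increments |metric|^weight_p (normalized by
# the set total) and miss increments 1/(N - n). Returns the signed maximal
# deviation and the position at which it is attained.
.gsea_es <- function(pos, metric_sorted, N, weight_p) {
  pos <- sort(pos)
  n <- length(pos)
  w <- abs(metric_sorted[pos])^weight_p
  tw <- sum(w)
  if (tw == 0) w[] <- 1 / n else w <- w / tw
  cw <- cumsum(w)
  miss <- 1 / (N - n)
  after <- cw - (pos - seq_len(n)) * miss          # running sum just after each hit
  before <- c(0, cw[-n]) - (pos - 1 - (seq_len(n) - 1)) * miss  # just before
  up <- max(after)
  dn <- min(before)
  if (up >= -dn) list(es = up, at = pos[which.max(after)])
  else list(es = dn, at = pos[which.min(before)])
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov enrichment on a ranked feature list:
#' the enrichment score (ES) is the maximal deviation of the running sum
#' with hit increments `|metric|^weight_p` (normalized to the set total) and
#' miss increments `1/(N - n)`. Significance uses gene-label permutations
#' (random same-size sets): NES is the ES divided by the mean `|ES|` of the
#' same-sign permutation scores, the p-value is the same-sign permutation
#' tail fraction with a +1 correction, and q-values are Benjamini-Hochberg
#' over the tested sets. The leading edge contains the set members at or
#' before the ES extremum. Ties in the metric are broken lexicographically
#' by feature id so results are deterministic.
#'
#' @param metric Named numeric vector (feature -> ranking metric, e.g. a
#'   signed Wald statistic); higher means more up-regulated.
#' @param sets Named list of feature-id vectors; every set must be smaller
#'   than the ranking and have at least one member in it.
#' @param n_perm Number of gene-label permutations (default 1000; a warning
#'   below 100).
#' @param weight_p Weighting exponent (default 1; 0 gives the unweighted
#'   statistic).
#' @param seed Optional seed for the permutations.
#' @return Data frame with `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (list column) and `n_permutations`.
#' @export
gsea_preranked <- function(metric, sets, n_perm = 1000, weight_p = 1,
                           seed = NULL) {
  if (is.null(names(metric)) || anyDuplicated(names(metric))) {
    stop("metric must be named with unique feature ids")
  }
  if (!all(is.finite(metric))) stop("metric must be finite")
  if (n_perm < 100) warning("fewer than 100 permutations; p-values will be coarse")
  if (!is.null(seed)) set.seed(seed)

  ord <- order(-metric, names(metric))
  metric_sorted <- metric[ord]
  ranked_ids <- names(metric_sorted)
  N <- length(metric_sorted)

  sizes <- integer(0)
  prepared <- lapply(names(sets), function(nm) {
    pos <- sort(match(intersect(sets[[nm]], ranked_ids), ranked_ids))
    if (length(pos) == 0) stop("set '", nm, "' has no members in the ranking")
    if (length(pos) >= N) stop("set '", nm, "' spans the whole ranking")
    pos
  })
  names(prepared) <- names(sets)

  # share permutation ES distributions across sets of equal size
  perm_es <- list()
  for (n in unique(vapply(prepared, length, integer(1)))) {
    perm_es[[as.character(n)]] <- vapply(seq_len(n_perm), function(i) {
      .gsea_es(sample.int(N, n), metric_sorted, N, weight_p)$es
    }, numeric(1))
  }

  rows <- lapply(names(prepared), function(nm) {
    pos <- prepared[[nm]]
    est <- .gsea_es(pos, metric_sorted, N, weight_p)
    perms <- perm_es[[as.character(length(pos))]]
    same <- perms[sign(perms) == sign(est$es)]
    if (est$es == 0 || length(same) == 0) {
      nes <- 0
      p <- 1
    } else {
      nes <- est$es / mean(abs(same))
      p <- (1 + sum(abs(same) >= abs(est$es))) / (1 + length(same))
    }
    lead <- if (est$es >= 0) ranked_ids[pos[pos <= est$at]] else
      ranked_ids[pos[pos >= est$at]]
    data.frame(set = nm, size = length(pos), es = est$es, nes = nes, p = p,
               n_permutations = n_perm, stringsAsFactors = FALSE,
               leading_edge = I(list(lead)))
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[, c("set", "size", "es", "nes", "p", "q", "leading_edge",
          "n_permutations")]
}
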