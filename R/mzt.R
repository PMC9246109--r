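#' Derive major-ZGA and maternal-clearance gene sets
#'
#' Runs the 2-cell versus 8-cell contrast on the normal embryos and defines
#' major-ZGA genes as those significantly up-regulated more than 4-fold from
#' the 2-cell to the 8-cell stage, and maternal-clearance genes as those
#' significantly down-regulated, under the `|log2fc| >= 2` and `q <= 0.01`
#' rule. TE features are excluded (their dynamics are analysed separately).
#' The derivation uses only the 2-cell and 8-cell normal samples, so adding
#' or removing other samples cannot change the sets.
#'
#' @param m A raw-layer `expr_matrix`.
#' @param sample_table Sample metadata (needs `sample_id`, `stage`, `group`).
#' @param annotation Optional feature annotation used to drop TE features.
#' @param fc_threshold_log2,q_threshold DE rule thresholds.
#' @return A list of class `mzt_sets` with `zga_genes`, `maternal_genes` and
#'   `contrast` (the DE run parameters).
#' @export
derive_mzt_sets <- function(m, sample_table, annotation = NULL,
                            fc_threshold_log2 = 2, q_threshold = 0.01) {
  c2 <- sample_table$sample_id[sample_table$stage == "c2" &
                                 sample_table$group == "normal"]
  c8 <- sample_table$sample_id[sample_table$stage == "c8" &
                                 sample_table$group == "normal"]
  if (length(c2) < 2 || length(c8) < 2) {
    stop("need at least 2 normal samples at each of stages c2 and c8")
  }
  sub <- subset_matrix(m, samples = c(c2, c8))
  de <- nb_wald_de(sub, groupA = c2, groupB = c8,
                   fc_threshold_log2 = fc_threshold_log2,
                   q_threshold = q_threshold)
  if (!is.null(annotation)) {
    te <- annotation$feature_id[annotation$kind == "TE"]
    de <- de[!de$feature_id %in% te, , drop = FALSE]
  }
  zga <- de$feature_id[de$is_de & de$direction == "up"]
  maternal <- de$feature_id[de$is_de & de$direction == "down"]
  ea_log("derive_mzt_sets: %d ZGA genes, %d maternal-clearance genes",
         length(zga), length(maternal))
  structure(list(zga_genes = zga, maternal_genes = maternal,
                 contrast = list(groupA = c2, groupB = c8,
                                 fc_threshold_log2 = fc_threshold_log2,
                                 q_threshold = q_threshold)),
            class = "mzt_sets")
}

#' Per-embryo MZT completion scores
#'
#' For each sample, the mean Z-score across the ZGA set and across the
#' maternal-clearance set, and the completion index
#' `zga_score - maternal_score`. An embryo that has traversed the MZT has
#' activated the ZGA genes (high ZGA Z) and cleared the maternal transcripts
#' (low maternal Z), so a large completion index.
#'
#' @param z A zscore-layer `expr_matrix`.
#' @param sets An `mzt_sets` object (or list with `zga_genes`,
#'   `maternal_genes`). At least 50% of each set must be present in the
#'   matrix; missing members are dropped with a logged note.
#' @param samples Optional sample ids to score (default all).
#' @return Data frame with `sample_id`, `zga_score`, `maternal_score`,
#'   `completion_index`.
#' @export
mzt_scores <- function(z, sets, samples = NULL) {
  require_layer(z, "zscore")
  samples <- samples %||% sample_ids(z)
  v <- em_values(z)[, samples, drop = FALSE]
  pick <- function(ids, what) {
    present <- intersect(ids, rownames(v))
    if (length(present) < 0.5 * length(ids)) {
      stop(sprintf("fewer than 50%% of %s genes present in the matrix", what))
    }
    if (length(present) < length(ids)) {
      ea_log("mzt_scores: dropped %d absent %s gene(s)",
             length(ids) - length(present), what)
    }
    present
  }
  zga <- pick(sets$zga_genes, "ZGA")
  mat <- pick(sets$maternal_genes, "maternal-clearance")
  zs <- colMeans(v[zga, , drop = FALSE])
  ms <- colMeans(v[mat, , drop = FALSE])
  data.frame(sample_id = samples, zga_score = unname(zs),
             maternal_score = unname(ms),
             completion_index = unname(zs - ms),
             stringsAsFactors = FALSE)
}

#' Flag embryos that failed the maternal-to-zygotic transition
#'
#' The completion cutoff is the midpoint between the median completion index
#' of normal 4-cell embryos and that of normal 8-cell embryos. A sample is
#' eligible for flagging if it should have traversed the MZT: all arrested
#' and treated embryos (which are by definition sampled past the time a
#' normal embryo completes the MZT) and normal samples at the 8-cell stage or
#' beyond. Eligible samples with a completion index below the cutoff are
#' flagged `mzt_failed`; pre-MZT normal cells are never flagged.
#'
#' @param scores Output of [mzt_scores()].
#' @param sample_table Sample metadata.
#' @param cutoff Optional explicit cutoff overriding the c4/c8 midpoint.
#' @return The `scores` data frame with added `eligible` and `mzt_failed`
#'   columns; the cutoff is stored in the `"cutoff"` attribute.
#' @export
classify_mzt_failure <- function(scores, sample_table, cutoff = NULL) {
  st <- sample_table[match(scores$sample_id, sample_table$sample_id), ]
  if (anyNA(st$sample_id)) stop("scores contain samples missing from the sample table")
  if (is.null(cutoff)) {
    med_of <- function(stage) {
      ids <- sample_table$sample_id[sample_table$stage == stage &
                                      sample_table$group == "normal"]
      ids <- intersect(ids, scores$sample_id)
      if (length(ids) == 0) {
        stop("reference stage '", stage, "' has no scored normal samples")
      }
      stats::median(scores$completion_index[scores$sample_id %in% ids])
    }
    cutoff <- (med_of("c4") + med_of("c8")) / 2
  }
  eligible <- st$group != "normal" | stage_index(st$stage) >= stage_index("c8")
  out <- scores
  out$eligible <- eligible
  out$mzt_failed <- eligible & scores$completion_index < cutoff
  attr(out, "cutoff") <- cutoff
  ea_log("classify_mzt_failure: cutoff %.3f, %d of %d eligible samples flagged",
         cutoff, sum(out$mzt_failed), sum(eligible))
  out
}
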