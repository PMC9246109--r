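#' Chromosome share of each sample's expression
#'
#' For every sample, the proportion of total gene signal assigned to each
#' chromosome. TE features and features without a chromosome assignment are
#' excluded. A whole-chromosome gain or loss changes the affected
#' chromosome's share of the transcriptome, which is what the dosage
#' Z-scores test.
#'
#' @param m A gc- or size-normalized `expr_matrix`.
#' @param annotation Feature annotation with `chromosome` and `kind`.
#' @param samples Optional sample ids (default all).
#' @return Samples-by-chromosomes matrix of proportions (rows sum to 1).
#' @export
chromosome_proportions <- function(m, annotation, samples = NULL) {
  require_layer(m, c("gc_normalized", "size_normalized"))
  samples <- samples %||% sample_ids(m)
  ann <- annotation[match(feature_ids(m), annotation$feature_id), ]
  keep <- !is.na(ann$kind) & ann$kind == "gene" &
    !is.na(ann$chromosome) & ann$chromosome != "NA"
  if (!any(keep)) stop("no chromosome-annotated gene features")
  v <- em_values(m)[keep, samples, drop = FALSE]
  chr <- ann$chromosome[keep]
  sums <- t(rowsum(v, chr))
  tot <- rowSums(sums)
  if (any(tot == 0)) {
    stop("zero total signal for sample(s): ",
         paste(rownames(sums)[tot == 0], collapse = ", "))
  }
  sums / tot
}

#' Dosage Z-scores against stage-matched references
#'
#' Per chromosome within a reference group, the center is the median
#' proportion and the scale 1.4826 x the median absolute deviation (falling
#' back to the standard deviation when the MAD is zero); each sample's
#' Z-score is its deviation from its reference group's center in units of
#' that scale. Normal samples are referenced against their own stage;
#' non-normal samples against the stage given in `placement` (typically the
#' nearest stage from arrest typing).
#'
#' @param props Proportion matrix from [chromosome_proportions()].
#' @param sample_table Sample metadata.
#' @param placement Named character vector mapping non-normal sample ids to
#'   a reference stage.
#' @param pool_stages If `TRUE`, all normal samples form a single reference
#'   group regardless of stage (fallback for small stage groups).
#' @param min_reference Minimum reference group size (default 5).
#' @return Samples-by-chromosomes matrix of Z-scores.
#' @export
dosage_zscores <- function(props, sample_table, placement = NULL,
                           pool_stages = FALSE, min_reference = 5) {
  st <- sample_table[match(rownames(props), sample_table$sample_id), ]
  if (anyNA(st$sample_id)) stop("proportion matrix contains unknown samples")
  ref_stage <- ifelse(st$group == "normal", st$stage, NA)
  if (!is.null(placement)) {
    hit <- st$sample_id %in% names(placement)
    ref_stage[hit] <- placement[st$sample_id[hit]]
  }
  if (anyNA(ref_stage)) {
    stop("no reference stage for sample(s): ",
         paste(st$sample_id[is.na(ref_stage)], collapse = ", "))
  }
  if (pool_stages) ref_stage[] <- "pooled"

  is_norm <- st$group == "normal"
  z <- props * NA_real_
  for (g in unique(ref_stage)) {
    members <- which(ref_stage == g)
    ref <- if (pool_stages) which(is_norm) else which(is_norm & st$stage == g)
    if (length(ref) < min_reference) {
      stop(sprintf("reference group '%s' has %d normal samples (< %d); consider pool_stages = TRUE",
                   g, length(ref), min_reference))
    }
    center <- apply(props[ref, , drop = FALSE], 2, stats::median)
    scale <- apply(props[ref, , drop = FALSE], 2, function(x) {
      s <- stats::mad(x)  # 1.4826 * median absolute deviation
      if (s == 0) stats::sd(x) else s
    })
    z[members, ] <- sweep(sweep(props[members, , drop = FALSE], 2, center), 2, scale, "/")
  }
  z
}

#' Call whole-chromosome gains and losses
#'
#' A (sample, chromosome) pair is called a gain when its dosage Z-score
#' exceeds the threshold, a loss when below the negated threshold, and
#' neutral otherwise; a sample is predicted aneuploid when at least one
#' chromosome is non-neutral.
#'
#' @param z Z-score matrix from [dosage_zscores()].
#' @param threshold Z-score threshold (default 3).
#' @param props Optional proportion matrix to carry through to the calls.
#' @return A list with `calls` (long data frame: sample_id, chromosome,
#'   proportion, z, call) and `samples` (sample_id, n_gain, n_loss,
#'   aneuploid).
#' @export
call_aneuploidy <- function(z, threshold = 3, props = NULL) {
  stopifnot(all(is.finite(z)))
  call <- matrix("neutral", nrow(z), ncol(z), dimnames = dimnames(z))
  call[z > threshold] <- "gain"
  call[z < -threshold] <- "loss"
  calls <- data.frame(
    sample_id = rep(rownames(z), times = ncol(z)),
    chromosome = rep(colnames(z), each = nrow(z)),
    proportion = if (is.null(props)) NA_real_ else as.vector(props),
    z = as.vector(z),
    call = as.vector(call),
    stringsAsFactors = FALSE)
  per_sample <- data.frame(
    sample_id = rownames(z),
    n_gain = rowSums(call == "gain"),
    n_loss = rowSums(call == "loss"),
    stringsAsFactors = FALSE, row.names = NULL)
  per_sample$aneuploid <- per_sample$n_gain + per_sample$n_loss > 0
  ea_log("call_aneuploidy: %d of %d samples with >= 1 chromosome beyond |z| > %g",
         sum(per_sample$aneuploid), nrow(per_sample), threshold)
  list(calls = calls, samples = per_sample)
}

#' Aneuploidy rates by developmental stage
#'
#' Tabulates predicted aneuploid samples per normal developmental stage
#' (arrested and treated samples are tallied as their own groups), plus
#' chromosome-wise gain/loss counts.
#'
#' @param an Output of [call_aneuploidy()].
#' @param sample_table Sample metadata.
#' @return A list with `stages` (stage, n_samples, n_aneuploid, fraction) and
#'   `chromosomes` (chromosome, n_gain, n_loss).
#' @export
summarize_by_stage <- function(an, sample_table) {
  st <- sample_table[match(an$samples$sample_id, sample_table$sample_id), ]
  grp <- ifelse(st$group == "normal", st$stage, st$group)
  lev <- c(embryo_stages(), "arrested", "treated")
  grp <- factor(grp, levels = lev)
  n <- table(grp)
  na <- tapply(an$samples$aneuploid, grp, sum)
  na[is.na(na)] <- 0
  stages <- data.frame(
    stage = lev, n_samples = as.integer(n),
    n_aneuploid = as.integer(na),
    fraction = ifelse(n > 0, as.numeric(na) / as.numeric(n), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  stages <- stages[stages$n_samples > 0, ]
  chromosomes <- data.frame(
    chromosome = unique(an$calls$chromosome),
    n_gain = as.integer(tapply(an$calls$call == "gain", an$calls$chromosome, sum)[unique(an$calls$chromosome)]),
    n_loss = as.integer(tapply(an$calls$call == "loss", an$calls$chromosome, sum)[unique(an$calls$chromosome)]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(stages = stages, chromosomes = chromosomes)
}
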