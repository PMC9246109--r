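#' Analysis configuration
#'
#' Collects the tunable thresholds of the pipeline: the 4-fold / q <= 0.01
#' DE rule, GSEA permutations and significance, the aneuploidy Z threshold,
#' the variable-feature count and cluster number for typing, GC bins, the
#' log2-NTC pseudocount and the seed for stochastic steps.
#'
#' @param fc_threshold_log2 Absolute log2 fold-change threshold (default 2).
#' @param q_threshold BH q threshold for DE (default 0.01).
#' @param gsea_permutations Gene-label permutations for GSEA (default 1000).
#' @param gsea_q_threshold GSEA significance threshold (default 0.05).
#' @param aneuploidy_z_threshold Dosage Z threshold (default 3).
#' @param n_variable_features Variable genes used for typing (default 2000).
#' @param k_types Number of arrest types (default 3).
#' @param gc_bins GC bins for normalization (default 10).
#' @param pseudocount Pseudocount for log2 NTC (default 1).
#' @param candidate_stages Stages considered in nearest-stage assignment.
#' @param pool_stages Pool all normal samples into one aneuploidy reference
#'   group (fallback for datasets with few embryos per stage).
#' @param seed Seed for stochastic operations (default 1).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(fc_threshold_log2 = 2, q_threshold = 0.01,
                            gsea_permutations = 1000, gsea_q_threshold = 0.05,
                            aneuploidy_z_threshold = 3,
                            n_variable_features = 2000, k_types = 3,
                            gc_bins = 10, pseudocount = 1,
                            candidate_stages = c("c2", "c4", "c8", "morula",
                                                 "E3", "E4"),
                            pool_stages = FALSE,
                            seed = 1) {
  stopifnot(fc_threshold_log2 > 0, q_threshold > 0, gsea_q_threshold > 0,
            aneuploidy_z_threshold > 0, k_types >= 2, gc_bins >= 2,
            pseudocount > 0)
  structure(list(fc_threshold_log2 = fc_threshold_log2,
                 q_threshold = q_threshold,
                 gsea_permutations = gsea_permutations,
                 gsea_q_threshold = gsea_q_threshold,
                 aneuploidy_z_threshold = aneuploidy_z_threshold,
                 n_variable_features = n_variable_features,
                 k_types = k_types, gc_bins = gc_bins,
                 pseudocount = pseudocount,
                 candidate_stages = candidate_stages,
                 pool_stages = pool_stages,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full arrested-embryo analysis
#'
#' Normalizes the counts (median-of-ratios depth factors, then within-sample
#' full-quantile GC normalization), types the arrested embryos, derives the
#' MZT gene sets from the 2-cell/8-cell contrast and flags MZT failures,
#' calls expression aneuploidies against stage-matched references (arrested
#' and treated embryos are referenced against their nearest stage), computes
#' TE expression fractions, and - when gene sets are supplied - set scores
#' and metabolic coordinates.
#'
#' @param m A raw-layer `expr_matrix`.
#' @param annotation Feature annotation.
#' @param sample_table Sample metadata.
#' @param gene_sets Optional named list of gene sets for scoring; sets named
#'   `glycolysis` and `oxphos` additionally yield metabolic coordinates.
#' @param config An [analysis_config()].
#' @param out_dir Optional directory; when given, result tables are written
#'   as TSV plus a JSON run manifest.
#' @return A list of class `arrest_analysis` with elements `size_factors`,
#'   `normalized`, `typing`, `mzt_sets`, `mzt`, `aneuploidy`,
#'   `stage_summary`, `te_percent`, and (with gene sets) `set_scores`,
#'   `metabolic`.
#' @export
run_arrest_pipeline <- function(m, annotation, sample_table, gene_sets = NULL,
                                config = analysis_config(), out_dir = NULL) {
  report <- validate_dataset(m, annotation, sample_table)
  if (nrow(report) > 0) {
    stop("dataset failed validation with ", nrow(report),
         " issue(s); run validate_dataset() for details")
  }
  ea_log("pipeline: %d features x %d samples, seed %d",
         nrow(em_values(m)), ncol(em_values(m)), config$seed)

  sf <- size_factors_median_of_ratios(m)
  norm <- gc_normalize(apply_size_factors(m, sf), annotation,
                       n_bins = config$gc_bins)
  lg <- log2_ntc(norm, pseudocount = config$pseudocount)
  z <- zscore_by_feature(lg)

  typing <- type_arrested_embryos(
    m, annotation, sample_table,
    n_variable = config$n_variable_features, k = config$k_types,
    candidate_stages = config$candidate_stages, gc_bins = config$gc_bins,
    fc_threshold_log2 = config$fc_threshold_log2,
    q_threshold = config$q_threshold)

  sets <- derive_mzt_sets(m, sample_table, annotation,
                          fc_threshold_log2 = config$fc_threshold_log2,
                          q_threshold = config$q_threshold)
  mzt <- classify_mzt_failure(mzt_scores(z, sets), sample_table)

  # place non-normal samples on the developmental axis for dosage references
  placement <- stats::setNames(typing$assignments$nearest_stage,
                               typing$assignments$sample_id)
  treated <- sample_table$sample_id[sample_table$group == "treated"]
  if (length(treated) > 0) {
    near_t <- assign_nearest_stage(
      m, sample_table, treated,
      candidate_stages = unique(c(config$candidate_stages, "E5")),
      fc_threshold_log2 = config$fc_threshold_log2,
      q_threshold = config$q_threshold)
    placement <- c(placement, stats::setNames(rep(near_t$stage, length(treated)),
                                              treated))
  }
  props <- chromosome_proportions(norm, annotation)
  zd <- dosage_zscores(props, sample_table, placement = placement,
                       pool_stages = isTRUE(config$pool_stages))
  an <- call_aneuploidy(zd, threshold = config$aneuploidy_z_threshold,
                        props = props)
  stage_summary <- summarize_by_stage(an, sample_table)

  te_pct <- te_fraction(norm, annotation)

  out <- list(size_factors = sf, normalized = norm, typing = typing,
              mzt_sets = sets, mzt = mzt, aneuploidy = an,
              stage_summary = stage_summary, te_percent = te_pct,
              config = config)
  if (!is.null(gene_sets)) {
    out$set_scores <- set_score(z, gene_sets, reduction = "sum")
    if (all(c("glycolysis", "oxphos") %in% names(gene_sets))) {
      out$metabolic <- metabolic_coordinates(out$set_scores,
                                             "glycolysis", "oxphos")
    }
  }
  class(out) <- "arrest_analysis"
  if (!is.null(out_dir)) write_analysis(out, out_dir, sample_table)
  out
}

#' Write pipeline result tables
#'
#' One TSV per result (typing, MZT scores, aneuploidy calls, stage summary,
#' TE fractions, set scores) plus a JSON run manifest with the parameters
#' and seed.
#'
#' @param x An `arrest_analysis` object.
#' @param out_dir Output directory (created if needed).
#' @param sample_table Sample metadata echoed into the manifest sizes.
#' @return Invisibly, the output directory.
#' @export
write_analysis <- function(x, out_dir, sample_table = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(x$typing$assignments, "typing.tsv")
  wt(x$mzt, "mzt_scores.tsv")
  write_gmt(list(zga = x$mzt_sets$zga_genes,
                 maternal_clearance = x$mzt_sets$maternal_genes),
            file.path(out_dir, "mzt_sets.gmt"))
  wt(x$aneuploidy$calls, "aneuploidy_calls.tsv")
  wt(x$aneuploidy$samples, "aneuploidy_samples.tsv")
  wt(x$stage_summary$stages, "stage_summary.tsv")
  wt(data.frame(sample_id = names(x$te_percent),
                te_percent = unname(x$te_percent)), "te_fraction.tsv")
  wt(data.frame(sample_id = names(x$size_factors),
                size_factor = unname(x$size_factors)), "size_factors.tsv")
  if (!is.null(x$set_scores)) wt(x$set_scores, "set_scores.tsv")
  if (!is.null(x$metabolic)) wt(x$metabolic, "metabolic_coordinates.tsv")
  manifest <- list(
    package = "embryoArrest",
    version = as.character(utils::packageVersion("embryoArrest")),
    r_version = as.character(getRversion()),
    config = unclass(x$config),
    n_samples = if (!is.null(sample_table)) nrow(sample_table) else NA)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.arrest_analysis <- function(x, ...) {
  cat("Arrested-embryo analysis\n")
  print(x$typing)
  cat(sprintf("MZT failures: %d of %d eligible samples (cutoff %.3f)\n",
              sum(x$mzt$mzt_failed), sum(x$mzt$eligible),
              attr(x$mzt, "cutoff")))
  cat(sprintf("Predicted aneuploid: %d of %d samples\n",
              sum(x$aneuploidy$samples$aneuploid),
              nrow(x$aneuploidy$samples)))
  invisible(x)
}
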