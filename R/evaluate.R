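#' Planted-truth recovery study on one simulated dataset
#'
#' Simulates a dataset under `params`, runs the full analysis pipeline on it
#' and measures how well every stage recovers the planted ground truth:
#' typing agreement (adjusted Rand index) and nearest stages, MZT flagging
#' sensitivity and specificity, ZGA/maternal set recovery, aneuploidy call
#' sensitivity and false-call rate, TE-fraction separation, GC-trend removal
#' and GSEA recovery of a planted up-regulated set. This is the package's
#' simulation-study harness: all quantities are computed from the pipeline's
#' outputs, never from the truth directly.
#'
#' @param seed Integer seed for the simulation and GSEA permutations.
#' @param params Generator parameters (default: full defaults at `seed`).
#' @param config Analysis configuration.
#' @param gsea If `FALSE`, skip the GSEA recovery block (saves time).
#' @return A list with `metrics` (named numeric vector) and `details`
#'   (typing table, nearest stages, the full analysis object).
#' @export
evaluate_recovery <- function(seed = 1,
                              params = generator_params(seed = seed),
                              config = analysis_config(seed = seed),
                              gsea = TRUE) {
  sim <- simulate_dataset(params)
  res <- run_arrest_pipeline(sim$matrix, sim$annotation, sim$samples,
                             config = config)
  truth <- sim$truth$samples
  met <- c()

  ## typing
  asg <- res$typing$assignments
  planted_type <- truth$arrest_type[match(asg$sample_id, truth$sample_id)]
  met["typing_ari"] <- .adjusted_rand(asg$type, planted_type)
  stages <- vapply(split(asg$nearest_stage, asg$type), function(s) s[1],
                   character(1))
  nearest_ok <- identical(unname(stages[c("I", "II", "III")]),
                          c("c4", "morula", "E4"))
  met["nearest_stages_expected"] <- as.numeric(nearest_ok)
  met["pct_type1_of_arrested"] <- 100 * mean(asg$type == "I")

  ## MZT
  sets <- res$mzt_sets
  tzga <- sim$truth$sets$zga
  met["zga_recovery"] <- mean(tzga %in% sets$zga_genes)
  met["zga_contamination"] <- if (length(sets$zga_genes) > 0) {
    mean(!sets$zga_genes %in% tzga)
  } else 0
  met["maternal_recovery"] <- mean(sim$truth$sets$maternal %in%
                                     sets$maternal_genes)
  at <- truth$arrest_type[match(res$mzt$sample_id, truth$sample_id)]
  met["mzt_type1_sensitivity"] <- mean(res$mzt$mzt_failed[at == "I"])
  met["mzt_false_flag_rate"] <- mean(res$mzt$mzt_failed[at %in% c("II", "III")])

  ## aneuploidy
  calls <- res$aneuploidy$calls
  tr <- sim$truth$aneuploid
  key <- paste(calls$sample_id, calls$chromosome)
  tkey <- paste(tr$sample, tr$chromosome)
  met["aneuploidy_sensitivity"] <- mean(calls$call[key %in% tkey] != "neutral")
  met["aneuploidy_false_call_rate"] <- mean(calls$call[!key %in% tkey] != "neutral")
  arrested <- truth$sample_id[truth$group == "arrested"]
  met["n_aneuploid_arrested"] <-
    sum(res$aneuploidy$samples$aneuploid[res$aneuploidy$samples$sample_id %in%
                                           arrested])

  ## TE fraction
  t1 <- truth$sample_id[truth$arrest_type == "I"]
  c4n <- truth$sample_id[truth$stage == "c4" & truth$group == "normal"]
  met["te_percent_type1"] <- mean(res$te_percent[t1])
  met["te_percent_c4_normal"] <- mean(res$te_percent[c4n])
  met["te_welch_p"] <- welch_t(res$te_percent[c4n], res$te_percent[t1])$p

  ## GC-trend removal (depth-normalized before vs after GC correction)
  gene <- sim$annotation$kind == "gene"
  gc <- sim$annotation$gc_fraction[gene]
  sn <- apply_size_factors(sim$matrix, res$size_factors)
  rho0 <- stats::cor(gc, rowMeans(log2(em_values(sn)[gene, ] + 1)),
                     method = "spearman")
  rho1 <- stats::cor(gc, rowMeans(log2(em_values(res$normalized)[gene, ] + 1)),
                     method = "spearman")
  met["gc_spearman_before"] <- rho0
  met["gc_spearman_after"] <- rho1
  met["gc_spearman_reduction"] <- 1 - abs(rho1) / abs(rho0)

  ## GSEA recovery: planted p53-target set in the recovered Type II versus
  ## morula Wald ranking, against a random same-size set
  if (gsea) {
    typeII <- asg$sample_id[asg$type == "II"]
    morula <- truth$sample_id[truth$stage == "morula" & truth$group == "normal"]
    de <- nb_wald_de(sim$matrix, groupA = morula, groupB = typeII,
                     fc_threshold_log2 = config$fc_threshold_log2,
                     q_threshold = config$q_threshold)
    metric <- stats::setNames(de$stat, de$feature_id)
    p53 <- intersect(sim$truth$sets$p53_targets, de$feature_id)
    set.seed(seed + 10000L)
    rnd <- sample(setdiff(de$feature_id, p53), length(p53))
    g <- gsea_preranked(metric, list(planted = p53, random = rnd),
                        n_perm = config$gsea_permutations, seed = seed)
    met["gsea_planted_nes"] <- g$nes[g$set == "planted"]
    met["gsea_planted_q"] <- g$q[g$set == "planted"]
    met["gsea_random_q"] <- g$q[g$set == "random"]
  }

  list(metrics = met,
       details = list(assignments = asg, nearest_stages = stages,
                      analysis = res, truth = sim$truth))
}

#' Sample-level aneuploidy call rate on an all-euploid dataset
#'
#' Simulates a dataset with no planted dosage events and measures the
#' fraction of normal samples with at least one chromosome beyond the
#' Z threshold against stage-matched references (the specificity of the
#' expression karyotype).
#'
#' @param seed Integer seed.
#' @param threshold Z threshold (default 3).
#' @param params Generator parameters; the default removes all planted
#'   aneuploidies from the standard settings.
#' @return Named numeric vector with the per-sample and per-chromosome
#'   false-call rates.
#' @export
euploid_call_rate <- function(seed = 1, threshold = 3,
                              params = NULL) {
  if (is.null(params)) {
    params <- generator_params(
      seed = seed,
      aneuploid_samples = data.frame(sample = character(0),
                                     chromosome = character(0),
                                     dosage = numeric(0)))
  }
  sim <- simulate_dataset(params)
  normals <- sim$samples$sample_id[sim$samples$group == "normal"]
  m <- expression_matrix(em_values(sim$matrix)[, normals], "raw")
  st <- sim$samples[sim$samples$group == "normal", ]
  norm <- gc_normalize(apply_size_factors(m), sim$annotation)
  props <- chromosome_proportions(norm, sim$annotation)
  z <- dosage_zscores(props, st)
  an <- call_aneuploidy(z, threshold = threshold)
  c(sample_rate = mean(an$samples$aneuploid),
    chromosome_rate = mean(an$calls$call != "neutral"))
}

# chance-corrected partition agreement
.adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  (sij - expected) / ((sa + sb) / 2 - expected)
}
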