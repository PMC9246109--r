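#' Parameters for the staged single-embryo count simulator
#'
#' Builds the parameter set for [simulate_dataset()]. The defaults describe a
#' reduced-scale version of a combined normal/arrested preimplantation
#' dataset: 11 developmental stages (oocyte to E7) with 8 embryos each, 23
#' arrested embryos planted as Types I/II/III (10/7/6), 4 treated embryos,
#' negative-binomial counts with log-normal library depths and a smooth
#' logistic GC bias, maternal-decay and major-ZGA programs spanning at least
#' 4-fold, per-stage marker programs, eight signature gene sets with
#' arrest-type-specific effects, and single whole-chromosome dosage events
#' (gain 1.5x / loss 0.5x) in roughly 30% of post-8-cell normal embryos and
#' 26% of arrested embryos.
#'
#' @param n_genes Number of gene features.
#' @param n_te_features Number of aggregated transposable-element features.
#' @param genes_per_chromosome Named integer vector giving the number of genes
#'   per chromosome; default near-equal split over chr1..chr22, chrX, chrY.
#' @param embryos_per_stage Normal embryos simulated per stage.
#' @param n_arrested Named vector with planted counts of arrest Types I, II, III.
#' @param n_treated Number of treated (rescued) embryos.
#' @param base_log2_mean,base_log2_sd Log2-normal baseline mean expression of
#'   genes (counts at unit depth).
#' @param te_log2_mean,te_log2_sd Baseline for TE features.
#' @param stage_profile_sd Total drift (log2 sd) of the smooth per-gene random
#'   walk across the whole developmental axis.
#' @param marker_fraction Fraction of genes assigned to each stage-marker
#'   program (transient 4-cell program plus persistent morula..E7 programs).
#' @param marker_log2_range Range of marker activation effects (log2).
#' @param mzt_log2_range Range of the planted maternal-decay and ZGA step
#'   sizes (log2); the lower bound exceeds 2 so every planted gene clears the
#'   4-fold rule by construction.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param libsize_sigma Log-normal sd of per-sample sequencing depth.
#' @param gc_bias_amplitude Amplitude of the logistic GC bias (natural-log
#'   scale); 0 disables the bias.
#' @param maternal_fraction,zga_fraction Fractions of genes assigned to the
#'   maternal-clearance and major-ZGA programs.
#' @param signature_fractions Named fractions of genes per signature set.
#' @param effect_log2 Named log2 effect sizes applied to arrested/treated
#'   embryos (see Details).
#' @param aneuploid_samples Data frame with columns `sample`, `chromosome`,
#'   `dosage` (0.5 or 1.5); `NULL` builds the default plan described above;
#'   pass a zero-row data frame for an all-euploid dataset.
#' @param seed Integer seed; all simulator randomness derives from it.
#'
#' @details All three arrest types share a senescent core: ribosomes and
#' nucleosomes down, p53 targets up, MYC targets down, CDKN1A (p21) up and
#' CCNA2 down. On top of that, Type I embryos transcribe from the 4-cell
#' profile (ZGA and maternal programs frozen at their 4-cell level) with TEs
#' up-regulated; Type II embryos use the morula profile with glycolysis down
#' and oxidative phosphorylation up; Type III embryos use the E4 profile with
#' both glycolysis and oxidative phosphorylation down (and no nucleosome
#' effect). Treated embryos use the E5 profile with glycolysis restored and
#' fatty-acid genes up, but ribosomes/nucleosomes still low and CDKN1A still
#' high. CDKN1A and CCNA2 are named singleton members of the p53-target and
#' MYC-target sets so single-gene checks are possible.
#'
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_genes = 6000,
                             n_te_features = 400,
                             genes_per_chromosome = NULL,
                             embryos_per_stage = 8,
                             n_arrested = c(I = 10, II = 7, III = 6),
                             n_treated = 4,
                             base_log2_mean = 4.5,
                             base_log2_sd = 1.8,
                             te_log2_mean = 3,
                             te_log2_sd = 1.5,
                             stage_profile_sd = 1.0,
                             marker_fraction = 0.03,
                             marker_log2_range = c(2.5, 4),
                             mzt_log2_range = c(2.5, 5),
                             nb_dispersion = 0.1,
                             libsize_sigma = 0.3,
                             gc_bias_amplitude = 0.3,
                             maternal_fraction = 0.10,
                             zga_fraction = 0.10,
                             signature_fractions = NULL,
                             effect_log2 = NULL,
                             aneuploid_samples = NULL,
                             seed = 1) {
  sig_default <- c(ribosome_small = 0.01, ribosome_large = 0.01,
                   nucleosome = 0.01, p53_targets = 0.01, myc_targets = 0.01,
                   glycolysis = 0.01, oxphos = 0.01, fatty_acid = 0.01)
  signature_fractions <- signature_fractions %||% sig_default
  eff_default <- c(te_up_typeI = 2.0, ribosome_down = -1.5,
                   nucleosome_down = -1.5, p53_up = 1.5, myc_down = -1.0,
                   glycolysis_down = -1.0, oxphos_up_typeII = 1.0,
                   oxphos_down_typeIII = -1.0, cdkn1a_up = 2.0,
                   ccna2_down = -2.0, fatty_acid_up_treated = 1.0)
  effect_log2 <- utils::modifyList(as.list(eff_default), as.list(effect_log2 %||% list()))
  effect_log2 <- unlist(effect_log2)

  chroms <- paste0("chr", c(1:22, "X", "Y"))
  if (is.null(genes_per_chromosome)) {
    per <- rep(n_genes %/% 24, 24)
    per[seq_len(n_genes %% 24)] <- per[seq_len(n_genes %% 24)] + 1
    genes_per_chromosome <- stats::setNames(per, chroms)
  }
  if (sum(genes_per_chromosome) != n_genes) {
    stop("genes_per_chromosome must sum to n_genes")
  }
  stopifnot(embryos_per_stage >= 1, n_treated >= 0, all(n_arrested >= 1))
  # marker programs: transient c4 plus persistent morula..E7
  n_marker_programs <- 7
  frac_total <- maternal_fraction + zga_fraction + sum(signature_fractions) +
    marker_fraction * n_marker_programs
  if (frac_total >= 1) {
    stop("disjoint program fractions sum to >= 1; reduce maternal/zga/signature/marker fractions")
  }
  stopifnot(nb_dispersion >= 0, libsize_sigma >= 0, gc_bias_amplitude >= 0,
            mzt_log2_range[1] > 2, marker_log2_range[1] > 0)

  p <- list(n_genes = n_genes, n_te_features = n_te_features,
            genes_per_chromosome = genes_per_chromosome,
            embryos_per_stage = embryos_per_stage,
            n_arrested = n_arrested, n_treated = n_treated,
            base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
            te_log2_mean = te_log2_mean, te_log2_sd = te_log2_sd,
            stage_profile_sd = stage_profile_sd,
            marker_fraction = marker_fraction,
            marker_log2_range = marker_log2_range,
            mzt_log2_range = mzt_log2_range,
            nb_dispersion = nb_dispersion, libsize_sigma = libsize_sigma,
            gc_bias_amplitude = gc_bias_amplitude,
            maternal_fraction = maternal_fraction, zga_fraction = zga_fraction,
            signature_fractions = signature_fractions,
            effect_log2 = effect_log2, seed = as.integer(seed))
  p$aneuploid_samples <- aneuploid_samples %||% .default_aneuploidy_plan(p)
  if (nrow(p$aneuploid_samples) > 0) {
    stopifnot(all(p$aneuploid_samples$dosage %in% c(0.5, 1.5)))
  }
  class(p) <- "generator_params"
  p
}

# sample naming scheme shared by the simulator and the default aneuploidy plan
.sample_names <- function(p) {
  stages <- embryo_stages()
  normals <- unlist(lapply(stages, function(s) {
    paste0(s, "_", seq_len(p$embryos_per_stage))
  }))
  arrested <- c(paste0("arrI_", seq_len(p$n_arrested[["I"]])),
                paste0("arrII_", seq_len(p$n_arrested[["II"]])),
                paste0("arrIII_", seq_len(p$n_arrested[["III"]])))
  treated <- if (p$n_treated > 0) paste0("trt_", seq_len(p$n_treated)) else character(0)
  list(normals = normals, arrested = arrested, treated = treated)
}

# Deterministic default plan: one whole-chromosome event in ~30% of normal
# embryos at c8 and beyond and ~26% of arrested embryos, alternating gains
# and losses over a fixed chromosome cycle.
.default_aneuploidy_plan <- function(p) {
  nm <- .sample_names(p)
  chrom_cycle <- paste0("chr", c(4, 16, 7, 19, 2, 11, 22, 6, 13, 9, 18, "X",
                                 3, 15, 8, 20, 10, 5, 14, 12, 21, 17, 1))
  late <- c("c8", "morula", "E3", "E4", "E5", "E6", "E7")
  k <- max(1L, round(0.3 * p$embryos_per_stage))
  picks <- character(0)
  for (s in late) {
    idx <- unique(round(seq(1, p$embryos_per_stage, length.out = k)))
    picks <- c(picks, paste0(s, "_", idx))
  }
  n_arr <- length(nm$arrested)
  k_arr <- max(1L, round(0.26 * n_arr))
  picks <- c(picks, nm$arrested[unique(round(seq(2, n_arr, length.out = k_arr)))])
  data.frame(
    sample = picks,
    chromosome = rep_len(chrom_cycle, length(picks)),
    dosage = rep_len(c(1.5, 0.5), length(picks)),
    stringsAsFactors = FALSE)
}

# smooth monotone logistic GC bias; amplitude 0 gives a flat multiplier
.gc_bias <- function(gc, amplitude) {
  exp(amplitude * (2 * stats::plogis(10 * (gc - 0.5)) - 1))
}

# Draws everything structural (annotation, set memberships, stage profiles).
# Assumes the RNG has already been seeded; both build_reference_profiles()
# and simulate_dataset() call this first so their profiles agree.
.generator_setup <- function(p) {
  stages <- embryo_stages()
  n_stage <- length(stages)
  ng <- p$n_genes
  nt <- p$n_te_features

  gene_ids <- sprintf("G%05d", seq_len(ng))
  chrom <- rep(names(p$genes_per_chromosome), p$genes_per_chromosome)
  gc <- stats::rbeta(ng, 10, 10)
  base_gene <- 2^stats::rnorm(ng, p$base_log2_mean, p$base_log2_sd)

  te_families <- c("ERV1", "ERVK", "ERVL", "L1", "L2", "Alu", "MIR", "SVA")
  te_family <- sample(te_families, nt, replace = TRUE)
  te_ids <- sprintf("TE_%s_%03d", te_family, seq_len(nt))
  base_te <- 2^stats::rnorm(nt, p$te_log2_mean, p$te_log2_sd)

  # smooth random walk for every feature; total drift sd = stage_profile_sd
  step_sd <- p$stage_profile_sd / sqrt(n_stage - 1)
  steps <- matrix(stats::rnorm((ng + nt) * (n_stage - 1), 0, step_sd), ng + nt)
  offs <- cbind(0, t(apply(steps, 1, cumsum)))

  # disjoint program assignment over a single permutation of the genes
  idx <- sample(ng)
  take <- function(n) {
    if (n == 0) return(integer(0))
    out <- idx[seq_len(n)]
    idx <<- idx[-seq_len(n)]
    out
  }
  n_mat <- round(p$maternal_fraction * ng)
  n_zga <- round(p$zga_fraction * ng)
  maternal <- take(n_mat)
  zga <- take(n_zga)
  signatures <- lapply(p$signature_fractions, function(f) take(round(f * ng)))
  marker_stage_idx <- c(4, 6:11)  # c4 (transient), morula..E7 (persistent)
  n_mark <- round(p$marker_fraction * ng)
  markers <- lapply(marker_stage_idx, function(s) take(n_mark))
  names(markers) <- stages[marker_stage_idx]

  # maternal decay: near-flat to c2, main clearance from c2 to c8, >= 4-fold total
  dec <- stats::runif(n_mat, p$mzt_log2_range[1], p$mzt_log2_range[2])
  offs[maternal, ] <- t(vapply(dec, function(d) {
    c(0, -0.1, -0.2, -0.2 - d / 2, rep(-0.2 - d, n_stage - 4))
  }, numeric(n_stage)))
  # major ZGA: step of >= 4-fold at the 8-cell stage, persistent afterwards
  zst <- stats::runif(n_zga, p$mzt_log2_range[1], p$mzt_log2_range[2])
  offs[zga, ] <- cbind(matrix(0, n_zga, 4),
                       matrix(rep(zst, n_stage - 4), n_zga))
  # stage-marker programs on top of the walk
  for (k in seq_along(marker_stage_idx)) {
    s0 <- marker_stage_idx[k]
    u <- stats::runif(n_mark, p$marker_log2_range[1], p$marker_log2_range[2])
    cols <- if (s0 == 4) 4 else s0:n_stage
    offs[markers[[k]], cols] <- offs[markers[[k]], cols] + u
  }

  # CDKN1A / CCNA2 as named members of the p53- and MYC-target sets
  feature_id <- c(gene_ids, te_ids)
  if (length(signatures$p53_targets)) {
    feature_id[signatures$p53_targets[1]] <- "CDKN1A"
  }
  if (length(signatures$myc_targets)) {
    feature_id[signatures$myc_targets[1]] <- "CCNA2"
  }

  base <- c(base_gene, base_te)
  profiles <- base * 2^offs
  dimnames(profiles) <- list(feature_id, stages)

  annotation <- data.frame(
    feature_id = feature_id,
    kind = c(rep("gene", ng), rep("TE", nt)),
    chromosome = c(chrom, rep("NA", nt)),
    gc_fraction = c(gc, rep(NA_real_, nt)),
    te_family = c(rep(NA_character_, ng), te_family),
    symbol = NA_character_,
    stringsAsFactors = FALSE)
  annotation$symbol[annotation$feature_id %in% c("CDKN1A", "CCNA2")] <-
    annotation$feature_id[annotation$feature_id %in% c("CDKN1A", "CCNA2")]

  id_of <- function(i) feature_id[i]
  sets <- c(list(maternal = id_of(maternal), zga = id_of(zga)),
            lapply(signatures, id_of),
            list(markers = lapply(markers, id_of)))

  list(profiles = profiles, annotation = annotation, sets = sets,
       te_rows = ng + seq_len(nt))
}

#' Stage reference expression profiles
#'
#' Deterministically (given the seed in `p`) draws the per-feature mean
#' expression for each developmental stage: maternal genes decay at least
#' 4-fold from oocyte to 8-cell (clearance concentrated between 2-cell and
#' 8-cell), ZGA genes step up at least 4-fold at the 8-cell stage, stage
#' markers activate at their stage, and all other features follow a smooth
#' random walk.
#'
#' @param p A `generator_params` object.
#' @return A list of class `stage_profiles` with elements `profiles`
#'   (features x stages matrix of strictly positive means at unit depth),
#'   `annotation` and `sets`.
#' @export
build_reference_profiles <- function(p) {
  stopifnot(inherits(p, "generator_params"))
  set.seed(p$seed)
  s <- .generator_setup(p)
  structure(list(profiles = s$profiles, annotation = s$annotation,
                 sets = s$sets), class = "stage_profiles")
}

#' Simulate a staged single-embryo count dataset with planted ground truth
#'
#' Draws negative-binomial counts with mean
#' `profile x depth x GC-bias x arrest-effect x aneuploidy-dosage` for each
#' sample. Normal embryos transcribe from their own stage profile; arrested
#' embryos from the profile nearest their arrest placement (Type I: 4-cell,
#' Type II: morula, Type III: E4) with the planted effects of
#' [generator_params()]; treated embryos from the E5 profile with glycolysis
#' restored.
#'
#' @param p A `generator_params` object.
#' @return A list with elements `matrix` (raw `expr_matrix`), `annotation`,
#'   `samples` (sample table) and `truth` (planted ground truth).
#' @export
simulate_dataset <- function(p) {
  stopifnot(inherits(p, "generator_params"))
  set.seed(p$seed)
  s <- .generator_setup(p)
  stages <- embryo_stages()
  nm <- .sample_names(p)

  samples <- data.frame(
    sample_id = c(nm$normals, nm$arrested, nm$treated),
    stage = c(rep(stages, each = p$embryos_per_stage),
              rep("c4", length(nm$arrested)),   # morphological 2-5 cell stage
              rep("E5", length(nm$treated))),
    group = c(rep("normal", length(nm$normals)),
              rep("arrested", length(nm$arrested)),
              rep("treated", length(nm$treated))),
    arrest_type = c(rep("none", length(nm$normals)),
                    rep("I", p$n_arrested[["I"]]),
                    rep("II", p$n_arrested[["II"]]),
                    rep("III", p$n_arrested[["III"]]),
                    rep("none", length(nm$treated))),
    stringsAsFactors = FALSE)
  profile_stage <- c(rep(stages, each = p$embryos_per_stage),
                     rep("c4", p$n_arrested[["I"]]),
                     rep("morula", p$n_arrested[["II"]]),
                     rep("E4", p$n_arrested[["III"]]),
                     rep("E5", length(nm$treated)))

  eff <- p$effect_log2
  fid <- rownames(s$profiles)
  nf <- length(fid)
  set_rows <- lapply(s$sets[names(s$sets) != "markers"], function(ids) match(ids, fid))
  class_effect <- list(
    normal = numeric(nf), none = numeric(nf),
    I = {
      # senescent core (shared by all arrest types) plus the TE de-repression
      e <- numeric(nf)
      e[c(set_rows$ribosome_small, set_rows$ribosome_large)] <- eff[["ribosome_down"]]
      e[set_rows$nucleosome] <- eff[["nucleosome_down"]]
      e[set_rows$p53_targets] <- eff[["p53_up"]]
      e[set_rows$myc_targets] <- eff[["myc_down"]]
      e[match("CDKN1A", fid)] <- eff[["cdkn1a_up"]]
      e[match("CCNA2", fid)] <- eff[["ccna2_down"]]
      e[s$te_rows] <- eff[["te_up_typeI"]]
      e
    },
    II = {
      e <- numeric(nf)
      e[c(set_rows$ribosome_small, set_rows$ribosome_large)] <- eff[["ribosome_down"]]
      e[set_rows$nucleosome] <- eff[["nucleosome_down"]]
      e[set_rows$glycolysis] <- eff[["glycolysis_down"]]
      e[set_rows$oxphos] <- eff[["oxphos_up_typeII"]]
      e[set_rows$p53_targets] <- eff[["p53_up"]]
      e[set_rows$myc_targets] <- eff[["myc_down"]]
      e[match("CDKN1A", fid)] <- eff[["cdkn1a_up"]]
      e[match("CCNA2", fid)] <- eff[["ccna2_down"]]
      e
    },
    III = {
      e <- numeric(nf)
      e[c(set_rows$ribosome_small, set_rows$ribosome_large)] <- eff[["ribosome_down"]]
      e[set_rows$glycolysis] <- eff[["glycolysis_down"]]
      e[set_rows$oxphos] <- eff[["oxphos_down_typeIII"]]
      e[set_rows$p53_targets] <- eff[["p53_up"]]
      e[set_rows$myc_targets] <- eff[["myc_down"]]
      e[match("CDKN1A", fid)] <- eff[["cdkn1a_up"]]
      e[match("CCNA2", fid)] <- eff[["ccna2_down"]]
      e
    },
    treated = {
      e <- numeric(nf)
      e[c(set_rows$ribosome_small, set_rows$ribosome_large)] <- eff[["ribosome_down"]]
      e[set_rows$nucleosome] <- eff[["nucleosome_down"]]
      e[set_rows$fatty_acid] <- eff[["fatty_acid_up_treated"]]
      e[match("CDKN1A", fid)] <- eff[["cdkn1a_up"]]
      e
    })
  effect_key <- ifelse(samples$group == "treated", "treated",
                       ifelse(samples$group == "arrested",
                              samples$arrest_type, "normal"))

  gcb <- rep(1, nf)
  gidx <- which(s$annotation$kind == "gene" & !is.na(s$annotation$gc_fraction))
  gcb[gidx] <- .gc_bias(s$annotation$gc_fraction[gidx], p$gc_bias_amplitude)

  an <- p$aneuploid_samples
  an <- an[an$sample %in% samples$sample_id, , drop = FALSE]

  depth <- exp(stats::rnorm(nrow(samples), 0, p$libsize_sigma))
  counts <- matrix(0L, nf, nrow(samples),
                   dimnames = list(fid, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    mu <- s$profiles[, profile_stage[j]] *
      2^class_effect[[effect_key[j]]] * gcb * depth[j]
    rows <- which(an$sample == samples$sample_id[j])
    for (r in rows) {
      on_chr <- s$annotation$chromosome == an$chromosome[r]
      mu[on_chr] <- mu[on_chr] * an$dosage[r]
    }
    counts[, j] <- if (p$nb_dispersion > 0) {
      stats::rnbinom(nf, mu = mu, size = 1 / p$nb_dispersion)
    } else {
      stats::rpois(nf, mu)
    }
  }
  ea_log("simulate_dataset: %d features x %d samples (seed %d)",
         nf, nrow(samples), p$seed)

  truth <- list(
    samples = cbind(samples, profile_stage = profile_stage, depth = depth),
    sets = s$sets,
    aneuploid = an,
    effect_log2 = as.list(p$effect_log2),
    seed = p$seed)

  list(matrix = expression_matrix(counts, "raw"),
       annotation = s$annotation, samples = samples, truth = truth)
}

#' Write a complete simulated fixture to disk
#'
#' Emits the count matrix (MatrixMarket plus id sidecars), feature annotation,
#' sample table, the signature gene sets as GMT, the planted ground truth as
#' JSON and a small run manifest. Re-running with the same seed reproduces
#' byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param params Generator parameters; defaults to `generator_params(seed = seed)`.
#' @return Invisibly, a named character vector of the file paths written.
#' @export
emit_default_fixture <- function(out_dir, seed = 1,
                                 params = generator_params(seed = seed)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(params)
  paths <- c(
    matrix = file.path(out_dir, "matrix.mtx"),
    features = file.path(out_dir, "features.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    annotation = file.path(out_dir, "feature_annotation.tsv"),
    sample_table = file.path(out_dir, "sample_table.tsv"),
    gene_sets = file.path(out_dir, "signature_sets.gmt"),
    truth = file.path(out_dir, "ground_truth.json"),
    manifest = file.path(out_dir, "manifest.json"))
  write_counts(sim$matrix, paths[["matrix"]], paths[["features"]],
               paths[["samples"]], dialect = "mtx")
  utils::write.table(sim$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$samples, paths[["sample_table"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sig <- sim$truth$sets[setdiff(names(sim$truth$sets), c("markers", "maternal", "zga"))]
  write_gmt(sig, paths[["gene_sets"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  manifest <- list(package = "embryoArrest",
                   version = as.character(utils::packageVersion("embryoArrest")),
                   seed = params$seed,
                   n_features = nrow(em_values(sim$matrix)),
                   n_samples = ncol(em_values(sim$matrix)))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE)
  ea_log("emit_default_fixture: wrote %d files to %s", length(paths), out_dir)
  invisible(paths)
}
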