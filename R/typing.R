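#' Select the most variable gene features
#'
#' Top-n gene features by variance of log2 NTC across the samples of the
#' matrix, with a deterministic lexicographic tie-break on feature id.
#'
#' @param m A log2ntc-layer `expr_matrix`.
#' @param n Number of features to keep.
#' @param annotation Optional feature annotation; when given, TE features are
#'   excluded before ranking.
#' @return Character vector of n feature ids.
#' @export
select_variable_features <- function(m, n, annotation = NULL) {
  require_layer(m, "log2ntc")
  if (n <= 0) stop("n must be positive")
  v <- em_values(m)
  if (!is.null(annotation)) {
    genes <- annotation$feature_id[annotation$kind == "gene"]
    v <- v[rownames(v) %in% genes, , drop = FALSE]
  }
  if (n > nrow(v)) stop("n exceeds the number of available gene features")
  vars <- apply(v, 1, stats::var)
  ord <- order(-vars, rownames(v))
  rownames(v)[ord[seq_len(n)]]
}

#' Pairwise co-correlation matrix
#'
#' Pearson correlation between samples over the selected features.
#'
#' @param m A log2ntc-layer `expr_matrix`.
#' @param samples Sample ids (>= 3).
#' @param features Feature ids (>= 10).
#' @return Symmetric samples-by-samples matrix of Pearson r with unit
#'   diagonal.
#' @export
cocorrelation_matrix <- function(m, samples, features) {
  require_layer(m, "log2ntc")
  if (length(samples) < 3) stop("need at least 3 samples")
  if (length(features) < 10) stop("need at least 10 features")
  v <- em_values(m)[features, samples, drop = FALSE]
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance sample(s): ", paste(samples[sds == 0], collapse = ", "))
  }
  stats::cor(v)
}

# Optimal leaf ordering (Bar-Joseph dynamic program): among the 2^(n-1)
# orderings reachable by flipping dendrogram branches, find one minimizing
# the sum of distances between adjacent leaves. M[u, w] is the minimal cost
# of laying out a subtree with leaf u leftmost and leaf w rightmost.
.optimal_leaf_order <- function(hc, dmat) {
  n <- nrow(dmat)
  leaf_sets <- vector("list", nrow(hc$merge))
  tabs <- vector("list", nrow(hc$merge))

  node_info <- function(id) {
    if (id < 0) {
      list(leaves = -id, M = matrix(0, 1, 1, dimnames = list(-id, -id)))
    } else {
      list(leaves = leaf_sets[[id]], M = tabs[[id]])
    }
  }
  for (v in seq_len(nrow(hc$merge))) {
    L <- node_info(hc$merge[v, 1])
    R <- node_info(hc$merge[v, 2])
    lv <- c(L$leaves, R$leaves)
    M <- matrix(Inf, length(lv), length(lv), dimnames = list(lv, lv))
    # T[u, l] = min over r of M_L[u, r] + d[r, l]
    Tm <- matrix(Inf, length(L$leaves), length(R$leaves))
    for (li in seq_along(R$leaves)) {
      add <- dmat[L$leaves, R$leaves[li]]
      Tm[, li] <- apply(L$M + rep(add, each = nrow(L$M)), 1, min)
    }
    for (ui in seq_along(L$leaves)) {
      for (wi in seq_along(R$leaves)) {
        best <- min(Tm[ui, ] + R$M[, wi])
        M[ui, length(L$leaves) + wi] <- best
        M[length(L$leaves) + wi, ui] <- best
      }
    }
    leaf_sets[[v]] <- lv
    tabs[[v]] <- M
  }

  backtrack <- function(id, u, w) {
    if (id < 0) return(-id)
    idL <- hc$merge[id, 1]; idR <- hc$merge[id, 2]
    L <- node_info(idL); R <- node_info(idR)
    if (u %in% R$leaves) {
      tmp <- L; L <- R; R <- tmp
      tmpid <- idL; idL <- idR; idR <- tmpid
    }
    target <- tabs[[id]][as.character(u), as.character(w)]
    for (r in L$leaves) {
      lcost <- L$M[as.character(u), as.character(r)]
      if (!is.finite(lcost)) next
      for (l in R$leaves) {
        if (abs(lcost + dmat[r, l] + R$M[as.character(l), as.character(w)] -
                target) < 1e-9) {
          return(c(backtrack(idL, u, r), backtrack(idR, l, w)))
        }
      }
    }
    stop("internal error: optimal leaf ordering backtrack failed")
  }

  root <- nrow(hc$merge)
  M <- tabs[[root]]
  pick <- which(M == min(M), arr.ind = TRUE)[1, ]
  u <- as.integer(rownames(M)[pick[1]])
  w <- as.integer(colnames(M)[pick[2]])
  backtrack(root, u, w)
}

#' Cluster samples on the co-correlation matrix
#'
#' Rows of the co-correlation matrix are clustered by Euclidean distance with
#' complete linkage; leaves are arranged by optimal leaf ordering (minimal
#' sum of adjacent-leaf distances among dendrogram-compatible orders) and the
#' tree is cut into `k` clusters.
#'
#' @param corr Symmetric correlation matrix with sample ids as dimnames.
#' @param k Number of clusters (<= number of samples).
#' @return A list of class `typing_clust`: `cluster` (named membership
#'   vector), `hclust`, `order` (optimal leaf order, sample ids) and `dist`.
#' @export
hierarchical_types <- function(corr, k) {
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-8))) {
    stop("correlation matrix must be symmetric")
  }
  n <- nrow(corr)
  if (k > n) stop("k exceeds the number of samples")
  d <- stats::dist(corr)
  hc <- stats::hclust(d, method = "complete")
  dmat <- as.matrix(d)
  ord <- .optimal_leaf_order(hc, dmat)
  cl <- stats::cutree(hc, k = k)
  structure(list(cluster = cl, hclust = hc,
                 order = rownames(corr)[ord], dist = d),
            class = "typing_clust")
}

#' Nearest developmental stage of a sample cluster
#'
#' Runs the DE count of the cluster against the normal samples of each
#' candidate stage and returns the stage with the smallest number of
#' significantly DE features; ties are broken toward the earlier stage in
#' developmental order.
#'
#' @param m A raw-layer `expr_matrix`.
#' @param sample_table Sample metadata.
#' @param cluster_samples Sample ids in the cluster.
#' @param candidate_stages Candidate stage labels (each needs >= 2 normal
#'   samples).
#' @param fc_threshold_log2,q_threshold DE rule thresholds.
#' @return A list with `stage` (the argmin) and `de_counts` (named vector).
#' @export
assign_nearest_stage <- function(m, sample_table, cluster_samples,
                                 candidate_stages,
                                 fc_threshold_log2 = 2, q_threshold = 0.01) {
  if (length(candidate_stages) == 0) stop("no candidate stages given")
  counts <- vapply(candidate_stages, function(s) {
    ref <- sample_table$sample_id[sample_table$stage == s &
                                    sample_table$group == "normal"]
    if (length(ref) < 2) {
      stop("candidate stage '", s, "' has fewer than 2 normal samples")
    }
    de_count(m, groupA = cluster_samples, groupB = ref,
             fc_threshold_log2 = fc_threshold_log2, q_threshold = q_threshold)
  }, numeric(1))
  ord <- order(counts, stage_index(candidate_stages))
  list(stage = candidate_stages[ord[1]], de_counts = counts)
}

#' Label three clusters as arrest Types I-III from their nearest stages
#'
#' The cluster whose nearest stage is earliest in developmental order becomes
#' Type I; of the remaining two, the earlier becomes Type II and the later
#' Type III. Stage ties are broken by cluster size (larger cluster gets the
#' lower type number), then by cluster id.
#'
#' @param clusters Named membership vector (sample id -> cluster id).
#' @param nearest_stages Named character vector (cluster id -> stage).
#' @return Named character vector (cluster id -> "I"/"II"/"III").
#' @export
label_types_by_stage <- function(clusters, nearest_stages) {
  ids <- sort(unique(clusters))
  if (length(ids) != 3) {
    stop("type labels I-III require exactly 3 clusters; got ", length(ids))
  }
  if (!all(as.character(ids) %in% names(nearest_stages))) {
    stop("every cluster needs a nearest stage")
  }
  sizes <- table(clusters)[as.character(ids)]
  sidx <- stage_index(nearest_stages[as.character(ids)])
  ord <- order(sidx, -as.numeric(sizes), ids)
  stats::setNames(c("I", "II", "III")[order(ord)], as.character(ids))
}

#' Type arrested embryos by co-correlation clustering
#'
#' End-to-end typing: normalizes the counts (depth, then GC), selects the
#' most variable gene features over all samples, computes the pairwise
#' co-correlation of the arrested embryos, clusters it (Euclidean distance,
#' complete linkage, optimal leaf ordering, cut at `k`), assigns each cluster
#' its nearest developmental stage by minimal DE count and labels the
#' clusters as Types I-III.
#'
#' @param m A raw-layer `expr_matrix`.
#' @param annotation Feature annotation.
#' @param sample_table Sample metadata.
#' @param n_variable Number of variable gene features (default 2000).
#' @param k Number of clusters (default 3).
#' @param candidate_stages Stages considered for nearest-stage assignment.
#' @param gc_bins GC bins for normalization.
#' @param fc_threshold_log2,q_threshold DE rule thresholds.
#' @return A list of class `arrest_typing`: `assignments` (data frame with
#'   sample_id, cluster, type, nearest_stage), `nearest` (per-cluster DE
#'   counts), `corr`, `clustering`, `features`.
#' @export
type_arrested_embryos <- function(m, annotation, sample_table,
                                  n_variable = 2000, k = 3,
                                  candidate_stages = c("c2", "c4", "c8",
                                                       "morula", "E3", "E4"),
                                  gc_bins = 10,
                                  fc_threshold_log2 = 2, q_threshold = 0.01) {
  arrested <- sample_table$sample_id[sample_table$group == "arrested"]
  if (length(arrested) < k) stop("fewer arrested samples than clusters")
  norm <- gc_normalize(apply_size_factors(m), annotation, n_bins = gc_bins)
  lg <- log2_ntc(norm)
  feats <- select_variable_features(lg, n_variable, annotation = annotation)
  corr <- cocorrelation_matrix(lg, arrested, feats)
  clust <- hierarchical_types(corr, k)
  nearest <- lapply(split(names(clust$cluster), clust$cluster), function(ids) {
    assign_nearest_stage(m, sample_table, ids, candidate_stages,
                         fc_threshold_log2 = fc_threshold_log2,
                         q_threshold = q_threshold)
  })
  stages <- vapply(nearest, `[[`, character(1), "stage")
  types <- if (k == 3) label_types_by_stage(clust$cluster, stages) else
    stats::setNames(as.character(seq_len(k)), as.character(seq_len(k)))
  assignments <- data.frame(
    sample_id = names(clust$cluster),
    cluster = unname(clust$cluster),
    type = unname(types[as.character(clust$cluster)]),
    nearest_stage = unname(stages[as.character(clust$cluster)]),
    stringsAsFactors = FALSE)
  ea_log("type_arrested_embryos: %s",
         paste(sprintf("Type %s -> %s (n=%d)", types[as.character(sort(unique(clust$cluster)))],
                       stages[as.character(sort(unique(clust$cluster)))],
                       as.integer(table(clust$cluster))), collapse = "; "))
  structure(list(assignments = assignments, nearest = nearest, corr = corr,
                 clustering = clust, features = feats),
            class = "arrest_typing")
}

#' @export
print.arrest_typing <- function(x, ...) {
  cat("Arrest typing of", nrow(x$assignments), "embryos\n")
  tab <- table(x$assignments$type)
  for (tp in names(tab)) {
    st <- unique(x$assignments$nearest_stage[x$assignments$type == tp])
    cat(sprintf("  Type %s: %d embryos, nearest stage %s\n", tp, tab[[tp]], st))
  }
  invisible(x)
}
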