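test_that("set scores reduce Z-scores with the documented algebra", {
  v <- matrix(c(0, 0, 0, 1, 2, 4, -1, 0.5, 2), 3, 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  sets <- list(pair = c("g1", "g2"), solo = "g3")
  sums <- set_score(zmat(v), sets, reduction = "sum")
  means <- set_score(zmat(v), sets, reduction = "mean")
  expect_equal(sums$score[sums$set == "pair"], c(0, 3, -0.5))
  # singleton set equals the gene's Z
  expect_equal(sums$score[sums$set == "solo"], v["g3", ], ignore_attr = TRUE)
  # sum = mean * n_present exactly
  expect_equal(sums$score, means$score * means$n_present)
  # linear in Z
  tw <- set_score(zmat(2 * v), sets, reduction = "sum")
  expect_equal(tw$score, 2 * sums$score)
  # all-zero matrix scores zero
  z0 <- set_score(zmat(v * 0), sets, reduction = "sum")
  expect_true(all(z0$score == 0))
  expect_error(set_score(zmat(v), list(bad = c("g1", "x", "y")), "sum"), "bad")
})

test_that("sample ranking is descending with deterministic ties and reverses cleanly", {
  sc <- data.frame(sample_id = c("b", "a", "c"), set = "s",
                   score = c(2, 5, 2), stringsAsFactors = FALSE)
  expect_equal(rank_samples(sc, "s"), c("a", "b", "c"))
  neg <- sc; neg$score <- -neg$score
  expect_equal(rank_samples(neg, "s"), c("b", "c", "a"))
  expect_error(rank_samples(sc, "nope"), "unknown set")
})

test_that("arrested embryos sink on ribosome scores and rise on p53 scores", {
  sim <- small_sim()
  z <- zscore_by_feature(log2_ntc(apply_size_factors(sim$matrix)))
  sets <- sim$truth$sets
  sc <- set_score(z, list(
    rib_nuc = c(sets$ribosome_small, sets$ribosome_large, sets$nucleosome),
    p53 = sets$p53_targets), reduction = "sum")
  truth <- sim$truth$samples
  arrested <- truth$sample_id[truth$group == "arrested"]
  quarter <- ceiling(nrow(truth) / 4)
  expect_gte(mean(arrested %in% tail(rank_samples(sc, "rib_nuc"), quarter)), 0.8)
  expect_gte(mean(arrested %in% head(rank_samples(sc, "p53"), quarter)), 0.8)
})

test_that("TE fractions are percentages of total signal", {
  v <- matrix(c(5, 5, 0, 10), 2, 2,
              dimnames = list(c("TE_1", "g1"), c("s1", "s2")))
  ann <- data.frame(feature_id = c("TE_1", "g1"), kind = c("TE", "gene"),
                    chromosome = c("NA", "chr1"), gc_fraction = c(NA, 0.5),
                    stringsAsFactors = FALSE)
  m <- expression_matrix(v, "size_normalized")
  expect_equal(unname(te_fraction(m, ann)), c(50, 0))

  all_te <- expression_matrix(v, "size_normalized")
  ann2 <- ann; ann2$kind <- "TE"
  expect_equal(unname(te_fraction(all_te, ann2)), c(100, 100))
})

test_that("Type I embryos carry an elevated TE expression fraction", {
  sim <- small_sim()
  norm <- apply_size_factors(sim$matrix)
  truth <- sim$truth$samples
  tf <- te_fraction(norm, sim$annotation)
  t1 <- tf[truth$sample_id[truth$arrest_type == "I"]]
  c4 <- tf[truth$sample_id[truth$stage == "c4" & truth$group == "normal"]]
  expect_lt(welch_t(c4, t1)$p, 0.05)
  expect_gt(mean(t1), mean(c4))
})

test_that("metabolic coordinates are the set scores and separate the types", {
  sim <- small_sim()
  z <- zscore_by_feature(log2_ntc(apply_size_factors(sim$matrix)))
  sets <- sim$truth$sets
  sc <- set_score(z, list(glycolysis = sets$glycolysis, oxphos = sets$oxphos),
                  reduction = "sum")
  xy <- metabolic_coordinates(sc, "glycolysis", "oxphos")
  expect_equal(xy$x, sc$score[sc$set == "glycolysis"])
  expect_equal(xy$y, sc$score[sc$set == "oxphos"])
  expect_error(metabolic_coordinates(sc, "glycolysis", "missing"), "missing")

  truth <- sim$truth$samples
  centroid <- function(ids) colMeans(xy[xy$sample_id %in% ids, c("x", "y")])
  typeII <- centroid(truth$sample_id[truth$arrest_type == "II"])
  typeIII <- centroid(truth$sample_id[truth$arrest_type == "III"])
  morula <- centroid(truth$sample_id[truth$stage == "morula" &
                                       truth$group == "normal"])
  treated <- centroid(truth$sample_id[truth$group == "treated"])
  expect_lt(typeII[["x"]], morula[["x"]])   # glycolysis planted down
  expect_gt(typeII[["y"]], morula[["y"]])   # oxphos planted up
  expect_gt(treated[["x"]], typeIII[["x"]]) # glycolysis restored by treatment
})

test_that("the enrichment score matches brute-force running sums", {
  # tiny hand-checked case: 10 genes, hits at ranks 1 and 4, unweighted
  metric <- setNames(seq(10, 1), sprintf("g%02d", 1:10))
  res <- gsea_preranked(metric, list(s = c("g01", "g04")), n_perm = 100,
                        weight_p = 0, seed = 1)
  expect_equal(res$es, 0.75)

  set.seed(71)
  for (i in 1:10) {
    metric <- setNames(rnorm(100), sprintf("g%03d", 1:100))
    set <- sample(names(metric), sample(3:20, 1))
    for (w in c(0, 1)) {
      r <- suppressWarnings(
        gsea_preranked(metric, list(s = set), n_perm = 100, weight_p = w))
      expect_equal(r$es, es_brute(metric, set, w), tolerance = 1e-12)
      expect_gte(r$es, -1)
      expect_lte(r$es, 1)
      expect_true(all(r$leading_edge[[1]] %in% set))
    }
  }
})

test_that("the enrichment score agrees with an external GSEA implementation", {
  set.seed(72)
  metric <- sort(rnorm(200), decreasing = TRUE)
  names(metric) <- sprintf("g%03d", 1:200)
  pos <- sort(sample(200, 15))
  ours <- suppressWarnings(
    gsea_preranked(metric, list(s = names(metric)[pos]), n_perm = 100))
  ext <- fgsea::calcGseaStat(metric, selectedStats = pos, gseaParam = 1)
  expect_equal(ours$es, ext, tolerance = 1e-10)
})

test_that("GSEA is seed-reproducible, sign-symmetric and guards degenerate sets", {
  metric <- setNames(seq(5, -5, length.out = 120) + (1:120) * 1e-4,
                     sprintf("g%03d", 1:120))
  sets <- list(top = sprintf("g%03d", 1:10), mid = sprintf("g%03d", 55:70))
  a <- gsea_preranked(metric, sets, n_perm = 200, seed = 9)
  b <- gsea_preranked(metric, sets, n_perm = 200, seed = 9)
  expect_identical(a, b)
  neg <- gsea_preranked(-metric, sets, n_perm = 200, seed = 9)
  expect_equal(neg$es, -a$es, tolerance = 1e-12)
  expect_true(all(sign(a$nes) == sign(a$es) | a$es == 0))
  expect_error(gsea_preranked(metric, list(all = names(metric)), n_perm = 200),
               "whole ranking")
  expect_warning(gsea_preranked(metric, sets["top"], n_perm = 50), "100")
})

test_that("a planted up-regulated set reaches significance in the Wald ranking", {
  sim <- small_sim()
  truth <- sim$truth$samples
  de <- nb_wald_de(sim$matrix,
                   groupA = truth$sample_id[truth$stage == "morula" &
                                              truth$group == "normal"],
                   groupB = truth$sample_id[truth$arrest_type == "II"])
  metric <- setNames(de$stat, de$feature_id)
  sets <- list(p53 = intersect(sim$truth$sets$p53_targets, de$feature_id))
  res <- gsea_preranked(metric, sets, n_perm = 500, seed = 5)
  expect_gt(res$nes, 0)
  expect_lt(res$q, 0.05)
})
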