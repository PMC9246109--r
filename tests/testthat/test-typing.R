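test_that("variable-feature selection ranks by variance with lexicographic ties", {
  v <- matrix(1, 5, 4, dimnames = list(c("d", "b", "a", "c", "e"),
                                       paste0("s", 1:4)))
  m <- expression_matrix(v, "log2ntc")
  expect_equal(select_variable_features(m, 3), c("a", "b", "c"))
  v2 <- v
  v2["c", ] <- c(0, 5, 0, 5)
  expect_equal(select_variable_features(expression_matrix(v2, "log2ntc"), 2),
               c("c", "a"))
  expect_error(select_variable_features(m, 0), "positive")
  expect_error(select_variable_features(m, 99), "exceeds")
  expect_identical(select_variable_features(m, 4),
                   select_variable_features(m, 4))
})

test_that("co-correlation matches a brute-force Pearson implementation", {
  set.seed(31)
  v <- matrix(rnorm(250), 50, 5,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:5)))
  m <- expression_matrix(v, "log2ntc")
  cc <- cocorrelation_matrix(m, sprintf("s%d", 1:5), sprintf("g%02d", 1:50))
  expect_equal(unname(diag(cc)), rep(1, 5))
  expect_equal(cc, t(cc), tolerance = 1e-12)
  brute <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  for (i in 1:5) for (j in 1:5) {
    expect_equal(cc[i, j], brute(v[, i], v[, j]), tolerance = 1e-12)
  }
})

test_that("duplicated and anti-correlated samples hit the Pearson extremes", {
  set.seed(32)
  x <- rnorm(30)
  v <- cbind(s1 = x, s2 = x, s3 = -x + mean(x) * 2, s4 = rnorm(30))
  rownames(v) <- sprintf("g%02d", 1:30)
  cc <- cocorrelation_matrix(expression_matrix(v, "log2ntc"),
                             colnames(v), rownames(v))
  expect_equal(cc["s1", "s2"], 1, tolerance = 1e-12)
  expect_equal(cc["s1", "s3"], -1, tolerance = 1e-12)
  flat <- cbind(v, s5 = rep(2, 30))
  expect_error(cocorrelation_matrix(expression_matrix(flat, "log2ntc"),
                                    colnames(flat), rownames(flat)), "s5")
})

# block-structured correlation matrix with three planted clades
block_corr <- function(sizes = c(4, 3, 3), within = 0.95, between = 0.2,
                       jitter = 0, seed = 1) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  cc <- matrix(between, n, n)
  for (k in seq_along(sizes)) cc[lab == k, lab == k] <- within
  diag(cc) <- 1
  if (jitter > 0) {
    noise <- matrix(rnorm(n * n, 0, jitter), n)
    noise <- (noise + t(noise)) / 2
    cc <- cc + noise
    diag(cc) <- 1
  }
  dimnames(cc) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  list(corr = cc, labels = lab)
}

test_that("three well-separated blocks are recovered exactly", {
  bx <- block_corr(jitter = 0.02)
  res <- hierarchical_types(bx$corr, 3)
  expect_equal(adjusted_rand_index(res$cluster, bx$labels), 1)
  # k = n gives singletons
  singletons <- hierarchical_types(bx$corr, nrow(bx$corr))
  expect_equal(sort(unname(singletons$cluster)), 1:nrow(bx$corr))
  expect_error(hierarchical_types(bx$corr, nrow(bx$corr) + 1), "exceeds")
})

test_that("clustering is invariant to sample input order", {
  bx <- block_corr(jitter = 0.03, seed = 5)
  perm <- sample(nrow(bx$corr))
  res1 <- hierarchical_types(bx$corr, 3)
  res2 <- hierarchical_types(bx$corr[perm, perm], 3)
  common <- rownames(bx$corr)
  expect_equal(adjusted_rand_index(res1$cluster[common], res2$cluster[common]), 1)
})

test_that("removing one sample leaves the other block memberships intact", {
  bx <- block_corr(jitter = 0.02, seed = 6)
  res <- hierarchical_types(bx$corr, 3)
  drop <- "s01"
  keep <- setdiff(rownames(bx$corr), drop)
  res2 <- hierarchical_types(bx$corr[keep, keep], 3)
  expect_equal(adjusted_rand_index(res$cluster[keep], res2$cluster[keep]), 1)
})

test_that("complete-linkage merge heights match a hand agglomeration oracle", {
  set.seed(41)
  pts <- matrix(rnorm(10), 5, 2)
  cc <- cor(t(cbind(pts, matrix(rnorm(40), 5, 8))))
  dimnames(cc) <- list(paste0("s", 1:5), paste0("s", 1:5))
  res <- hierarchical_types(cc, 2)

  # brute-force complete-linkage agglomeration on the same distances
  d <- as.matrix(dist(cc))
  clusters <- as.list(1:5)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(res$hclust$height, heights, tolerance = 1e-12)
})

test_that("optimal leaf ordering minimizes the adjacent-leaf distance sum", {
  set.seed(51)
  n <- 6
  x <- matrix(rnorm(n * 4), n)
  cc <- cor(t(x))
  dimnames(cc) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- hierarchical_types(cc, 2)
  d <- as.matrix(dist(cc))
  ord <- match(res$order, rownames(cc))
  path_cost <- function(o) sum(d[cbind(o[-length(o)], o[-1])])

  # enumerate every dendrogram-compatible ordering by flipping branches
  hc <- res$hclust
  orders_of <- function(id) {
    if (id < 0) return(list(-id))
    L <- orders_of(hc$merge[id, 1])
    R <- orders_of(hc$merge[id, 2])
    out <- list()
    for (l in L) for (r in R) {
      out <- c(out, list(c(l, r)), list(c(r, l)))
    }
    out
  }
  all_orders <- orders_of(nrow(hc$merge))
  best <- min(vapply(all_orders, path_cost, numeric(1)))
  expect_equal(path_cost(ord), best, tolerance = 1e-12)
  # ordering is cosmetic: memberships equal cutree on the same tree
  expect_equal(res$cluster, cutree(hc, 2))
})

test_that("nearest-stage assignment picks the profile of origin", {
  sim <- small_sim()
  truth <- sim$truth$samples
  typeII <- truth$sample_id[truth$arrest_type == "II"]
  near <- assign_nearest_stage(sim$matrix, sim$samples, typeII,
                               c("c2", "c4", "c8", "morula", "E3", "E4"))
  expect_equal(near$stage, "morula")
  # invariant to candidate ordering
  near2 <- assign_nearest_stage(sim$matrix, sim$samples, typeII,
                                c("E4", "morula", "c8", "c4", "c2", "E3"))
  expect_equal(near2$stage, "morula")

  # a cluster that duplicates one stage's samples lands on it with 0 DE
  c8 <- truth$sample_id[truth$stage == "c8" & truth$group == "normal"]
  v <- em_values(sim$matrix)
  dup <- v[, c8]
  colnames(dup) <- paste0("dup", seq_along(c8))
  m2 <- expression_matrix(cbind(v, dup), "raw")
  near3 <- assign_nearest_stage(m2, sim$samples, colnames(dup),
                                c("c4", "c8", "morula"))
  expect_equal(near3$stage, "c8")
  expect_equal(unname(near3$de_counts[["c8"]]), 0)
})

test_that("type labels follow developmental order with size tie-breaks", {
  cl <- setNames(rep(1:3, c(10, 7, 6)), sprintf("s%02d", 1:23))
  lab <- label_types_by_stage(cl, c(`1` = "c4", `2` = "morula", `3` = "E4"))
  expect_equal(unname(lab[c("1", "2", "3")]), c("I", "II", "III"))

  lab2 <- label_types_by_stage(cl, c(`1` = "E4", `2` = "c4", `3` = "morula"))
  expect_equal(unname(lab2[c("1", "2", "3")]), c("III", "I", "II"))

  # two clusters tied at morula: the larger gets the lower type number
  cl3 <- setNames(rep(1:3, c(4, 9, 6)), sprintf("s%02d", 1:19))
  lab3 <- label_types_by_stage(cl3, c(`1` = "morula", `2` = "morula", `3` = "c4"))
  expect_equal(unname(lab3[c("3", "2", "1")]), c("I", "II", "III"))

  expect_error(label_types_by_stage(setNames(rep(1:2, 3), paste0("s", 1:6)),
                                    c(`1` = "c4", `2` = "morula")),
               "exactly 3")
})

test_that("end-to-end typing recovers the planted arrest types", {
  sim <- small_sim()
  res <- type_arrested_embryos(sim$matrix, sim$annotation, sim$samples,
                               n_variable = 300)
  truth <- sim$truth$samples
  planted <- truth$arrest_type[match(res$assignments$sample_id,
                                     truth$sample_id)]
  expect_equal(adjusted_rand_index(res$assignments$type, planted), 1)
  stages <- sapply(res$nearest, `[[`, "stage")
  expect_setequal(unname(stages), c("c4", "morula", "E4"))
  expect_equal(res$assignments$type, planted)
})
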