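test_that("size factors recover depth ratios and have geometric mean 1", {
  v <- matrix(c(10, 20, 4, 20, 40, 8), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  sf <- size_factors_median_of_ratios(expression_matrix(v, "raw"))
  expect_equal(unname(sf[["s2"]] / sf[["s1"]]), 2)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-6)

  same <- matrix(rep(c(5, 9, 2), 4), nrow = 3,
                 dimnames = list(letters[1:3], paste0("s", 1:4)))
  expect_equal(unname(size_factors_median_of_ratios(expression_matrix(same, "raw"))),
               rep(1, 4))
})

test_that("size factors match a brute-force median-of-ratios oracle", {
  set.seed(11)
  v <- matrix(rnbinom(100, mu = 30, size = 1), 20, 5,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:5)))
  v[v == 0] <- 1  # keep every gene usable so the oracle covers all rows
  sf <- size_factors_median_of_ratios(expression_matrix(v, "raw"))

  # independent, loop-based restatement of the definition
  ok <- apply(v > 0, 1, all)
  oracle <- numeric(ncol(v))
  for (j in seq_len(ncol(v))) {
    ratios <- numeric(0)
    for (i in which(ok)) {
      gm <- prod(v[i, ])^(1 / ncol(v))
      ratios <- c(ratios, v[i, j] / gm)
    }
    oracle[j] <- median(ratios)
  }
  oracle <- oracle / prod(oracle)^(1 / length(oracle))
  expect_equal(unname(sf), oracle, tolerance = 1e-12)
})

test_that("depth normalization shrinks the spread of sample totals", {
  sim <- small_sim()
  raw_tot <- colSums(em_values(sim$matrix))
  norm_tot <- colSums(em_values(apply_size_factors(sim$matrix)))
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(norm_tot), cv(raw_tot))
})

# direct construction with a known multiplicative GC bias: lognormal baseline
# times a smooth monotone function of GC, so the true signal is GC-free
biased_fixture <- function(n = 2000, s = 6, amp = 0.3, noise = 0.2,
                           spread = 1.8, seed = 1) {
  set.seed(seed)
  gc <- rbeta(n, 10, 10)
  base <- 2^rnorm(n, 5, spread)
  bias <- exp(amp * (2 * plogis(10 * (gc - 0.5)) - 1))
  v <- outer(base * bias, rep(1, s)) *
    matrix(exp(rnorm(n * s, 0, noise)), n, s)
  dimnames(v) <- list(sprintf("g%04d", 1:n), sprintf("s%d", 1:s))
  ann <- data.frame(feature_id = rownames(v), kind = "gene",
                    chromosome = "chr1", gc_fraction = gc,
                    stringsAsFactors = FALSE)
  list(m = expression_matrix(v, "size_normalized"), ann = ann, gc = gc)
}

test_that("GC normalization removes a planted GC trend and little else", {
  fx <- biased_fixture(amp = 0.3)
  out <- gc_normalize(fx$m, fx$ann, n_bins = 10)
  rho_before <- cor(fx$gc, rowMeans(log2(em_values(fx$m) + 1)), method = "spearman")
  rho_after <- cor(fx$gc, rowMeans(log2(em_values(out) + 1)), method = "spearman")
  expect_lt(abs(rho_after), 0.1 * abs(rho_before))
  # per-sample totals preserved
  expect_equal(colSums(em_values(out)), colSums(em_values(fx$m)),
               tolerance = 1e-8)

  # Without bias the mapping approaches the identity. The residual per-gene
  # distortion is order-statistic noise, which scales with the expression
  # spread over the bin size, so it is tight for a narrow distribution and
  # stays bounded (but a few percent) at a realistic 1.8-log2 spread.
  fx0 <- biased_fixture(amp = 0, noise = 0.02, spread = 0.3)
  out0 <- gc_normalize(fx0$m, fx0$ann, n_bins = 10)
  rel <- abs(em_values(out0) - em_values(fx0$m)) / em_values(fx0$m)
  expect_lt(median(rel), 0.02)

  fxn <- biased_fixture(amp = 0, noise = 0.3, seed = 9)
  outn <- gc_normalize(fxn$m, fxn$ann, n_bins = 10)
  reln <- abs(em_values(outn) - em_values(fxn$m)) / em_values(fxn$m)
  expect_lt(median(reln), 0.1)
})

test_that("GC normalization is idempotent to within tolerance", {
  fx <- biased_fixture(amp = 0.3, seed = 2)
  once <- gc_normalize(fx$m, fx$ann, n_bins = 10)
  again <- gc_normalize(expression_matrix(em_values(once), "size_normalized"),
                        fx$ann, n_bins = 10)
  rel <- abs(em_values(again) - em_values(once)) / (em_values(once) + 1e-9)
  expect_lt(median(rel), 0.01)
})

test_that("GC normalization guards its preconditions", {
  fx <- biased_fixture(n = 50, s = 3)
  expect_error(gc_normalize(fx$m, fx$ann, n_bins = 1), "at least 2")
  expect_error(gc_normalize(fx$m, fx$ann, n_bins = 20), "fewer bins")
  ann_nogc <- fx$ann
  ann_nogc$gc_fraction[1:20] <- NA
  expect_error(gc_normalize(fx$m, ann_nogc, n_bins = 2), "90%")
})

test_that("features without GC pass through unchanged", {
  fx <- biased_fixture(n = 400, s = 4, seed = 3)
  ann <- fx$ann
  ann$kind[1:30] <- "TE"
  ann$gc_fraction[1:30] <- NA
  out <- gc_normalize(fx$m, ann, n_bins = 5)
  expect_identical(em_values(out)[1:30, ], em_values(fx$m)[1:30, ])
})

test_that("log2 NTC is the textbook transform", {
  v <- matrix(c(0, 3, 15, 1), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  lg <- log2_ntc(expression_matrix(v, "size_normalized"))
  expect_equal(unname(em_values(lg)), matrix(c(0, 2, 4, 1), 2, 2))
  expect_error(log2_ntc(expression_matrix(v, "size_normalized"),
                        pseudocount = 0), "positive")
})

test_that("feature Z-scores center and scale against the reference", {
  v <- matrix(c(1, 5, 3, 5, 2, 5, 6, 5), 2, 4,
              dimnames = list(c("g1", "flat"), paste0("s", 1:4)))
  z <- zscore_by_feature(expression_matrix(v, "log2ntc"))
  expect_equal(rowMeans(em_values(z)), c(g1 = 0, flat = 0))
  expect_equal(unname(sqrt(rowMeans(em_values(z)^2))), c(1, 0))

  two <- matrix(c(1, 3), 1, 2, dimnames = list("g", c("a", "b")))
  z2 <- zscore_by_feature(expression_matrix(two, "log2ntc"))
  expect_equal(unname(em_values(z2)), matrix(c(-1, 1), 1, 2))

  expect_error(zscore_by_feature(expression_matrix(two, "log2ntc"),
                                 reference_samples = "a"), "at least 2")

  # population sd over an explicit reference, tolerance 1e-9
  set.seed(4)
  big <- matrix(rnorm(300), 30, 10,
                dimnames = list(sprintf("g%d", 1:30), sprintf("s%d", 1:10)))
  ref <- sprintf("s%d", 1:6)
  zb <- em_values(zscore_by_feature(expression_matrix(big, "log2ntc"), ref))
  expect_lt(max(abs(rowMeans(zb[, ref]))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(zb[, ref]^2)) - 1)), 1e-9)
})
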