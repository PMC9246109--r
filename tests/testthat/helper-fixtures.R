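options(embryoArrest.quiet = TRUE)

# scaled-down generator settings for fast unit tests; acceptance tests use
# the full defaults
small_params <- function(seed = 42, ...) {
  generator_params(n_genes = 600, n_te_features = 60, embryos_per_stage = 4,
                   n_arrested = c(I = 4, II = 3, III = 3), n_treated = 2,
                   seed = seed, ...)
}

small_config <- function(...) {
  analysis_config(n_variable_features = 300, pool_stages = TRUE, ...)
}

# memoised small simulation so several test files can share one draw
small_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) cache[[key]] <- simulate_dataset(small_params(seed))
    cache[[key]]
  }
})

# memoised full-size simulation (default generator settings)
default_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_dataset(generator_params(seed = seed))
    }
    cache[[key]]
  }
})

# chance-corrected agreement between two partitions
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# small helper to build a zscore-layer matrix directly in tests
zmat <- function(values) {
  expression_matrix(values, layer = "zscore")
}

# independent full-running-sum enrichment-score oracle, used against the
# package's hit-position implementation
es_brute <- function(metric, set, weight = 1) {
  ord <- order(-metric, names(metric))
  r <- metric[ord]
  hit <- names(r) %in% set
  n <- sum(hit)
  N <- length(r)
  inc <- numeric(N)
  w <- abs(r[hit])^weight
  if (sum(w) == 0) w <- rep(1 / n, n) else w <- w / sum(w)
  inc[hit] <- w
  inc[!hit] <- -1 / (N - n)
  path <- cumsum(inc)
  up <- max(path)
  dn <- min(path)
  if (up >= -dn) up else dn
}
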