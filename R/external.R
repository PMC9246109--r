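#' Load a manually downloaded deposited expression matrix
#'
#' The deposited normalized matrix for the study this pipeline targets is a
#' dense table (features in rows, samples in columns) that must be obtained
#' manually (no downloads are performed here). This loader reads such a
#' table, reports its dimensions, and returns it as an `expr_matrix` on the
#' requested layer so the typing/aneuploidy stages can be re-run on it.
#' Feature naming (symbols versus stable ids) is reconciled through the
#' user-supplied annotation table rather than assumed.
#'
#' @param path Path to the tab-separated matrix (header = sample ids, first
#'   column = feature ids).
#' @param layer Layer tag of the stored values (deposited matrices are
#'   usually already normalized).
#' @return An `expr_matrix`.
#' @export
load_deposited_matrix <- function(path, layer = "gc_normalized") {
  if (!file.exists(path)) {
    stop("deposited matrix not found at '", path,
         "'; it must be downloaded manually and placed there")
  }
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- as.character(tab[[1]])
  ea_log("load_deposited_matrix: %d features x %d samples", nrow(v), ncol(v))
  expression_matrix(v, layer = layer)
}

#' Tabulate embryo outcome tables
#'
#' Counts and fractions of embryos per outcome within each group, for
#' reproducing bar-chart tallies from per-embryo outcome tables (e.g.
#' untreated versus drug-treated arrest/reactivation outcomes).
#'
#' @param outcomes Data frame with columns `group` and `outcome`, one row
#'   per embryo.
#' @return Data frame with `group`, `outcome`, `n`, `n_group`, `fraction`.
#' @export
tabulate_embryo_outcomes <- function(outcomes) {
  stopifnot(all(c("group", "outcome") %in% names(outcomes)))
  tab <- as.data.frame(table(group = outcomes$group,
                             outcome = outcomes$outcome),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "n"
  tot <- table(outcomes$group)
  tab$n_group <- as.integer(tot[tab$group])
  tab$fraction <- tab$n / tab$n_group
  tab[tab$n > 0 | TRUE, , drop = FALSE]
}
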