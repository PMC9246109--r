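#' Expression matrix container
#'
#' A light container for a features-by-samples expression matrix carrying a
#' `layer` tag that records what the values are: raw counts, depth-normalized
#' ("size_normalized"), GC-corrected normalized tag counts ("gc_normalized"),
#' log2 NTC ("log2ntc") or per-feature Z-scores ("zscore"). Downstream
#' operations check the tag and refuse matrices on the wrong scale.
#'
#' Invariants enforced at construction: row and column names present and
#' unique; non-negative values for the count-scale layers; integer values for
#' the raw layer.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique `rownames` (feature ids) and `colnames` (sample ids).
#' @param layer One of `"raw"`, `"size_normalized"`, `"gc_normalized"`,
#'   `"log2ntc"`, `"zscore"`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values,
                              layer = c("raw", "size_normalized",
                                        "gc_normalized", "log2ntc", "zscore")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stop("`values` must carry feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(fid)) {
    stop("duplicated feature id(s): ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop("duplicated sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  if (anyNA(values)) stop("expression values must not contain NA")
  if (layer %in% c("raw", "size_normalized", "gc_normalized") &&
      any(values < 0)) {
    stop("layer '", layer, "' requires non-negative values")
  }
  if (layer == "raw") {
    bad <- which(abs(values - round(values)) > 1e-8, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf("raw counts must be integers; first offender: feature '%s', sample '%s'",
                   fid[bad[1, 1]], sid[bad[1, 2]]))
    }
  }
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Feature ids of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(m) rownames(m$values)

#' Sample ids of an expression matrix
#' @param m An `expr_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(m) colnames(m$values)

#' Layer tag of an expression matrix
#' @param m An `expr_matrix`.
#' @return The layer tag string.
#' @export
em_layer <- function(m) m$layer

#' Numeric values of an expression matrix
#' @param m An `expr_matrix`.
#' @return The underlying numeric matrix.
#' @export
em_values <- function(m) m$values

# guard: operations declare the layer(s) they accept
require_layer <- function(m, layers) {
  if (!inherits(m, "expr_matrix")) stop("expected an `expr_matrix`")
  if (!m$layer %in% layers) {
    stop(sprintf("expected layer %s but got '%s'",
                 paste(sQuote(layers), collapse = " or "), m$layer))
  }
  invisible(m)
}

# subset while keeping the layer tag; drop = FALSE semantics throughout
subset_matrix <- function(m, features = NULL, samples = NULL) {
  v <- m$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  structure(list(values = v, layer = m$layer), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, layer '%s'\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}
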