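#' Read a count matrix
#'
#' Reads a raw feature-by-sample count matrix either from MatrixMarket
#' coordinate format with feature/sample id sidecar files (`dialect = "mtx"`,
#' 1-based indices per the MatrixMarket standard) or from a dense
#' tab-separated file whose header row holds the sample ids and whose first
#' column holds the feature ids (`dialect = "tsv"`).
#'
#' @param matrix_path Path to the `.mtx` file or the dense TSV.
#' @param features_path For `mtx`, path to a one-id-per-line feature sidecar.
#' @param samples_path For `mtx`, path to a one-id-per-line sample sidecar.
#' @param dialect `"mtx"` or `"tsv"`.
#' @return An `expr_matrix` with layer `"raw"`.
#' @export
read_counts <- function(matrix_path, features_path = NULL, samples_path = NULL,
                        dialect = c("mtx", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(matrix_path)) stop("no such file: ", matrix_path)
  if (dialect == "mtx") {
    for (p in c(features_path, samples_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("mtx dialect requires existing feature and sample sidecar files")
      }
    }
    mm <- as.matrix(Matrix::readMM(matrix_path))
    fid <- readLines(features_path)
    sid <- readLines(samples_path)
    fid <- fid[nzchar(fid)]
    sid <- sid[nzchar(sid)]
    if (length(fid) != nrow(mm)) {
      stop(sprintf("dimension mismatch: %s has %d rows but %s lists %d features",
                   matrix_path, nrow(mm), features_path, length(fid)))
    }
    if (length(sid) != ncol(mm)) {
      stop(sprintf("dimension mismatch: %s has %d columns but %s lists %d samples",
                   matrix_path, ncol(mm), samples_path, length(sid)))
    }
    dimnames(mm) <- list(fid, sid)
  } else {
    tab <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    fid <- as.character(tab[[1]])
    mm <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(mm) <- "double"
    rownames(mm) <- fid
  }
  ea_log("read_counts: %d features x %d samples from %s (%s)",
         nrow(mm), ncol(mm), matrix_path, dialect)
  expression_matrix(mm, layer = "raw")
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]; round-trips are exact for integer raw counts.
#'
#' @param m An `expr_matrix` (any layer; raw for exact round trips).
#' @param matrix_path Output `.mtx` or TSV path.
#' @param features_path,samples_path Sidecar paths (mtx dialect).
#' @param dialect `"mtx"` or `"tsv"`.
#' @return Invisibly, the matrix path.
#' @export
write_counts <- function(m, matrix_path, features_path = NULL,
                         samples_path = NULL, dialect = c("mtx", "tsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "expr_matrix"))
  if (dialect == "mtx") {
    if (is.null(features_path) || is.null(samples_path)) {
      stop("mtx dialect requires feature and sample sidecar paths")
    }
    Matrix::writeMM(methods::as(Matrix::Matrix(m$values, sparse = TRUE),
                                "generalMatrix"), matrix_path)
    writeLines(feature_ids(m), features_path)
    writeLines(sample_ids(m), samples_path)
  } else {
    tab <- data.frame(feature_id = feature_ids(m), m$values,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(matrix_path)
}

#' Read a feature annotation table
#'
#' Tab-separated with columns `feature_id`, `kind` (gene/TE), `chromosome`
#' (`"chr1"`..`"chrY"`, or `"NA"` for genome-wide aggregated TE types),
#' `gc_fraction` (in \[0,1\], may be missing), and optional `te_family`,
#' `symbol`.
#'
#' @param path Path to the TSV.
#' @return A data.frame of feature annotation.
#' @export
read_feature_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("feature_id", "kind", "chromosome", "gc_fraction")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$feature_id)) stop("duplicated feature_id in annotation")
  if (!all(ann$kind %in% c("gene", "TE"))) {
    stop("annotation kind must be 'gene' or 'TE'")
  }
  bad <- !is.na(ann$gc_fraction) & (ann$gc_fraction < 0 | ann$gc_fraction > 1)
  if (any(bad)) stop("gc_fraction outside [0,1] for: ",
                     paste(ann$feature_id[bad][1:min(3, sum(bad))], collapse = ", "))
  ann$chromosome[is.na(ann$chromosome)] <- "NA"
  ann
}

#' Read a sample table
#'
#' Tab-separated with columns `sample_id`, `stage` (see [embryo_stages()]),
#' `group` (normal/arrested/treated) and `arrest_type` (none/I/II/III/unknown).
#' Enforces the invariant that normal samples have arrest type `none` and
#' arrested samples have a non-`none` arrest type.
#'
#' @param path Path to the TSV.
#' @return A data.frame of sample metadata.
#' @export
read_sample_table <- function(path) {
  st <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "group", "arrest_type")
  miss <- setdiff(need, names(st))
  if (length(miss)) stop("sample table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(st$sample_id)) stop("duplicated sample_id in sample table")
  stage_index(st$stage)  # validates the vocabulary
  if (!all(st$group %in% .SAMPLE_GROUPS)) stop("unknown sample group label")
  if (!all(st$arrest_type %in% .ARREST_TYPES)) stop("unknown arrest_type label")
  viol <- .sample_table_violations(st)
  if (length(viol)) stop(viol[1])
  st
}

.sample_table_violations <- function(st) {
  out <- character(0)
  bad <- st$group == "normal" & st$arrest_type != "none"
  if (any(bad)) {
    out <- c(out, paste0("normal sample with arrest_type != none: ",
                         paste(st$sample_id[bad], collapse = ", ")))
  }
  bad <- st$group == "arrested" & !st$arrest_type %in% c("I", "II", "III", "unknown")
  if (any(bad)) {
    out <- c(out, paste0("arrested sample with arrest_type none: ",
                         paste(st$sample_id[bad], collapse = ", ")))
  }
  out
}

#' Read gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate
#' members within a set are collapsed, keeping first-seen order; input set
#' order is preserved.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 member",
                   i, length(parts)))
    }
    nm <- parts[1]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop(sprintf("GMT line %d: set '%s' has no members", i, nm))
    sets[[nm]] <- members
    desc[nm] <- parts[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional named character vector of per-set descriptions.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  description <- description %||% attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && nm %in% names(description)) description[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Cross-check a dataset for consistency
#'
#' Report-only validation: lists features absent from the annotation, samples
#' absent from the sample table (and vice versa), and sample-table invariant
#' violations. Pipeline entry points require an empty violation list.
#'
#' @param m An `expr_matrix`.
#' @param annotation Feature annotation data.frame.
#' @param sample_table Sample metadata data.frame.
#' @return A data.frame with columns `kind`, `item`, `message`
#'   (class `validation_report`); zero rows means a clean dataset.
#' @export
validate_dataset <- function(m, annotation, sample_table) {
  stopifnot(inherits(m, "expr_matrix"))
  issues <- list()
  add <- function(kind, item, msg) {
    issues[[length(issues) + 1]] <<- data.frame(
      kind = kind, item = item, message = msg, stringsAsFactors = FALSE)
  }
  for (f in setdiff(feature_ids(m), annotation$feature_id)) {
    add("missing_annotation", f, "feature has no annotation row")
  }
  for (s in setdiff(sample_ids(m), sample_table$sample_id)) {
    add("missing_sample", s, "sample has no sample-table row")
  }
  for (s in setdiff(sample_table$sample_id, sample_ids(m))) {
    add("extra_sample", s, "sample-table row with no matrix column")
  }
  for (v in .sample_table_violations(sample_table)) {
    add("invariant", "sample_table", v)
  }
  bad <- !is.na(annotation$gc_fraction) &
    (annotation$gc_fraction < 0 | annotation$gc_fraction > 1)
  for (f in annotation$feature_id[bad]) {
    add("invariant", f, "gc_fraction outside [0,1]")
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(kind = character(0), item = character(0), message = character(0))
  class(out) <- c("validation_report", "data.frame")
  out
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("validation: clean (0 issues)\n")
  } else {
    cat(sprintf("validation: %d issue(s)\n", nrow(x)))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
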