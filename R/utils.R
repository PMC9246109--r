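#' Developmental stage vocabulary
#'
#' The eleven developmental stages recognised by the pipeline, in
#' developmental order: oocyte, zygote, 2-cell (`c2`), 4-cell (`c4`),
#' 8-cell (`c8`), morula, and the embryonic-day stages `E3` to `E7`
#' (early morula through late blastocyst).
#'
#' @return Character vector of stage labels in developmental order.
#' @export
embryo_stages <- function() {
  c("oocyte", "zygote", "c2", "c4", "c8", "morula",
    "E3", "E4", "E5", "E6", "E7")
}

#' Position of a stage on the developmental axis
#'
#' @param stage Character vector of stage labels.
#' @return Integer vector of positions (1 = oocyte, 11 = E7).
#' @export
stage_index <- function(stage) {
  idx <- match(stage, embryo_stages())
  if (anyNA(idx)) {
    stop("unknown stage label(s): ",
         paste(unique(stage[is.na(idx)]), collapse = ", "))
  }
  idx
}

.SAMPLE_GROUPS <- c("normal", "arrested", "treated")
.ARREST_TYPES <- c("none", "I", "II", "III", "unknown")

# stderr logging for pipeline stages; silenced via options(embryoArrest.quiet = TRUE)
ea_log <- function(...) {
  if (!isTRUE(getOption("embryoArrest.quiet", FALSE))) {
    message("[embryoArrest] ", sprintf(...))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# geometric mean of strictly positive values
.geomean <- function(x) exp(mean(log(x)))
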