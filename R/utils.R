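#' @keywords internal
"_PACKAGE"

#' @importFrom GenomicRanges GRanges findOverlaps reduce coverage
#' @importFrom IRanges IRanges subsetByOverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits runValue
#' @importFrom stats pt phyper p.adjust rnorm runif sd cor setNames
#' @importFrom utils read.delim write.table head
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All generators funnel through this so they are pure in
# (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# scalar checks used throughout the validators
is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

log_msg <- function(..., level = "INFO") {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...)))
}
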