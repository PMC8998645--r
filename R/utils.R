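#' @useDynLib rlrkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim optimize pchisq p.adjust dbinom dnbinom qbeta
#'   rnbinom rpois runif rbinom rnorm setNames median var
#' @importFrom utils read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Derive a reproducible child seed below 2^31 from a parent seed and a tag.
derive_seed <- function(seed, tag) {
  x <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + x) %% 2147483587) + 1L
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

## Uniform integer draws on [lo, hi]; safe when lo == hi (unlike sample()).
runif_int <- function(n, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(hi >= lo)
  lo + floor(runif(n) * (hi - lo + 1L))
}

## Accept either a file path or literal text; return a path (temp file for text).
as_input_file <- function(x, ext = ".txt") {
  stopifnot(is.character(x), any(nzchar(x)))
  if (length(x) == 1L && !grepl("[\n\t]", x) && file.exists(x)) return(x)
  tf <- tempfile(fileext = ext)
  writeLines(x, tf)
  tf
}
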