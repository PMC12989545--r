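#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif setNames aggregate plogis qnorm
#' @importFrom utils read.delim write.table URLdecode URLencode
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run an expression under a fixed RNG seed, restoring global RNG state
#'
#' All synthetic-data generators route their randomness through this helper so
#' that they are pure functions of (parameters, seed) and never perturb the
#' caller's random-number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## reverse complement of an ACGTN string, kept as plain character so the
## primer/in-silico-PCR hot paths avoid XString construction overhead
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

assert_acgt <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop(what, " must be a non-empty string", call. = FALSE)
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L)
    stop(what, " contains non-ACGT character at position ", bad, call. = FALSE)
  invisible(seq)
}

## uniform random DNA with a target GC fraction
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

## fixed-precision float formatting used by all report writers
fmt_num <- function(x, digits = 4L) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
                formatC(x, digits = digits, format = "f")))
}
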